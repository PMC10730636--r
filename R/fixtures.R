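# Synthetic crystal-structure fixtures: idealized gas-phase-like geometries
# placed in large P1 boxes (plus deliberately defective structures) standing
# in for real database entries. Geometry is seedless and fully deterministic.

.fixture_desc <- function(sites, a, b = a, c = a, alpha = 90, beta = 90,
                          gamma = 90, operators = list(identity_symop()),
                          space_group_number = 1L, name = "fixture",
                          declared_formula = NULL, provenance = list(),
                          markup_flags = character(0)) {
  crystal_description(
    cell = unit_cell(a, b, c, alpha, beta, gamma),
    operators = operators, sites = sites,
    declared_formula = declared_formula,
    space_group_number = space_group_number,
    provenance = provenance, markup_flags = markup_flags, name = name)
}

# Centre a block of Cartesian coordinates in a cubic P1 box with the given
# gap to the nearest periodic image, returning fractional coordinates.
.boxed_sites <- function(labels, elements, xyz, padding,
                         occupancy = 1, attached_hydrogens = 0L,
                         disorder_assembly = NA_character_,
                         disorder_group = NA_character_) {
  xyz <- as.matrix(xyz)
  extent <- max(apply(xyz, 2, function(v) diff(range(v))))
  a <- extent + 2 * padding
  centre <- colMeans(apply(xyz, 2, range))
  frac <- sweep(xyz, 2, centre) / a + 0.5
  list(sites = data.frame(
    label = labels, element = elements,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    occupancy = occupancy, attached_hydrogens = as.integer(attached_hydrogens),
    disorder_assembly = disorder_assembly, disorder_group = disorder_group,
    stringsAsFactors = FALSE), a = a)
}

#' Idealized benzene fixture
#'
#' Planar C6H6 with C-C 1.39 A and C-H 1.08 A, isolated in a cubic P1 cell
#' so that the nearest intermolecular image is at least `2 * cell_padding`
#' away.
#'
#' @param cell_padding Gap to the cell boundary in angstroms.
#' @return A [crystal_description()].
#' @export
make_benzene <- function(cell_padding = 4) {
  ang <- (0:5) * pi / 3
  rc <- 1.39
  rh <- rc + 1.08
  xyz <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
               cbind(rh * cos(ang), rh * sin(ang), 0))
  bs <- .boxed_sites(c(paste0("C", 1:6), paste0("H", 1:6)),
                     c(rep("C", 6), rep("H", 6)), xyz, cell_padding)
  .fixture_desc(bs$sites, a = bs$a, name = "benzene",
                declared_formula = c(C = 6L, H = 6L),
                provenance = list(doi = "10.0000/synthetic-benzene",
                                  journal = "Synthetic Fixtures", year = 2024))
}

#' Idealized eclipsed ferrocene fixture
#'
#' Two parallel eclipsed C5H5 rings (C-C 1.43 A, in-plane C-H 1.08 A) with
#' the iron atom midway, ring centroids at 1.66 A from Fe, isolated in P1.
#' All ten Fe-C contacts are equal (about 2.06 A), so connectivity places an
#' iron-carbon contact to every ring atom and perception renders the
#' eta5-coordination as ten zero-order bonds with Fe 2+ and one ring carbon
#' 1- per ring.
#'
#' @param cell_padding Gap to the cell boundary in angstroms.
#' @return A [crystal_description()].
#' @export
make_ferrocene <- function(cell_padding = 4) {
  rr <- 1.43 / (2 * sin(pi / 5))
  rh <- rr + 1.08
  ang <- (0:4) * 2 * pi / 5
  ring <- function(zoff) {
    rbind(cbind(rr * cos(ang), rr * sin(ang), zoff),
          cbind(rh * cos(ang), rh * sin(ang), zoff))
  }
  xyz <- rbind(c(0, 0, 0), ring(1.66), ring(-1.66))
  labels <- c("Fe1", paste0("C", 1:5), paste0("H", 1:5),
              paste0("C", 6:10), paste0("H", 6:10))
  elements <- c("Fe", rep(c(rep("C", 5), rep("H", 5)), 2))
  bs <- .boxed_sites(labels, elements, xyz, cell_padding)
  .fixture_desc(bs$sites, a = bs$a, name = "ferrocene",
                declared_formula = c(C = 10L, H = 10L, Fe = 1L),
                provenance = list(doi = "10.0000/synthetic-ferrocene",
                                  journal = "Synthetic Fixtures", year = 2024))
}

#' Azide salt fixture
#'
#' A linear azide anion with configurable N-N distances plus a metal
#' counterion at coordination distance from the first nitrogen. The two
#' printed distance regimes select the two-double-bond and the single+triple
#' azide representations respectively.
#'
#' @param d1 First N-N distance (N1-N2) in angstroms.
#' @param d2 Second N-N distance (N2-N3) in angstroms.
#' @param counterion Metal element symbol.
#' @param cell_padding Gap to the cell boundary in angstroms.
#' @return A [crystal_description()].
#' @export
make_azide <- function(d1 = 1.24, d2 = 1.24, counterion = "Na",
                       cell_padding = 5) {
  dm <- covalent_radius(counterion) + covalent_radius("N") + 0.2
  xyz <- rbind(c(-dm, 0, 0), c(0, 0, 0), c(d1, 0, 0), c(d1 + d2, 0, 0))
  bs <- .boxed_sites(c(paste0(counterion, 1), "N1", "N2", "N3"),
                     c(counterion, "N", "N", "N"), xyz, cell_padding)
  .fixture_desc(bs$sites, a = bs$a, name = "azide",
                declared_formula = stats::setNames(c(1L, 3L),
                                                   c(counterion, "N")),
                provenance = list(doi = "10.0000/synthetic-azide",
                                  journal = "Synthetic Fixtures", year = 2024))
}

#' Rock-salt-like ion pair fixture
#'
#' One Na-Cl contact pair (2.8 A) isolated in a large P1 box: a minimal
#' stoichiometric 1:1 ionic ensemble without the infinite network of the
#' true rock-salt lattice.
#'
#' @param cell_padding Gap to the cell boundary in angstroms.
#' @return A [crystal_description()].
#' @export
make_nacl <- function(cell_padding = 5) {
  bs <- .boxed_sites(c("Na1", "Cl1"), c("Na", "Cl"),
                     rbind(c(0, 0, 0), c(2.8, 0, 0)), cell_padding)
  .fixture_desc(bs$sites, a = bs$a, name = "nacl",
                declared_formula = c(Cl = 1L, Na = 1L),
                provenance = list(doi = "10.0000/synthetic-nacl",
                                  journal = "Synthetic Fixtures", year = 2024))
}

#' Two crystallographically independent waters
#'
#' Two oxygen sites (each with two attached hydrogens) far apart in one P1
#' cell: chemically identical entities that stay distinct because they are
#' crystallographically independent.
#'
#' @return A [crystal_description()].
#' @export
make_two_waters <- function() {
  sites <- data.frame(
    label = c("O1", "O2"), element = c("O", "O"),
    fx = c(0.25, 0.75), fy = c(0.25, 0.75), fz = c(0.25, 0.75),
    occupancy = 1, attached_hydrogens = 2L,
    disorder_assembly = NA_character_, disorder_group = NA_character_,
    stringsAsFactors = FALSE)
  .fixture_desc(sites, a = 12, name = "two_waters",
                declared_formula = c(H = 4L, O = 2L))
}

#' Ethane-like dimer completed by an inversion centre
#'
#' One carbon site with three attached hydrogens at a general position of a
#' P-1-like cell; the inversion image completes the C2H6 entity across the
#' origin. Exercises symmetry expansion and entity growth through operators.
#'
#' @return A [crystal_description()].
#' @export
make_inversion_dimer <- function() {
  a <- 14
  sites <- data.frame(
    label = "C1", element = "C",
    fx = 0.77 / a, fy = 0.0, fz = 0.0,  # half the C-C bond of 1.54 A
    occupancy = 1, attached_hydrogens = 3L,
    disorder_assembly = NA_character_, disorder_group = NA_character_,
    stringsAsFactors = FALSE)
  .fixture_desc(sites, a = a,
                operators = list(identity_symop(), parse_symop("-x,-y,-z")),
                space_group_number = 2L, name = "inversion_dimer",
                declared_formula = c(C = 2L, H = 6L))
}

#' Deliberately defective fixtures
#'
#' @param kind One of:
#'   `"clash"` (two carbons 0.5 A apart),
#'   `"overvalence"` (a carbon with five bonded neighbours),
#'   `"polymer"` (a 1-D carbon chain continuous across the cell),
#'   `"disorder"` (one assembly with two positional disorder groups),
#'   `"compositional"` (an Fe/Co 1:1 shared metal site).
#' @param groups,occupancies Disorder group names and occupancies for
#'   `kind = "disorder"`.
#' @return A [crystal_description()].
#' @export
make_defect <- function(kind = c("clash", "overvalence", "polymer",
                                 "disorder", "compositional"),
                        groups = c("1", "2"), occupancies = c(0.5, 0.5)) {
  kind <- match.arg(kind)
  if (kind == "clash") {
    bs <- .boxed_sites(c("C1", "C2"), c("C", "C"),
                       rbind(c(0, 0, 0), c(0.5, 0, 0)), padding = 5,
                       attached_hydrogens = 3L)
    return(.fixture_desc(bs$sites, a = bs$a, name = "defect_clash"))
  }
  if (kind == "overvalence") {
    # trigonal-bipyramidal CC5 core, outer carbons methyl-like
    d <- 1.54
    xyz <- rbind(c(0, 0, 0),
                 c(0, 0, d), c(0, 0, -d),
                 c(d, 0, 0),
                 c(d * cos(2 * pi / 3), d * sin(2 * pi / 3), 0),
                 c(d * cos(4 * pi / 3), d * sin(4 * pi / 3), 0))
    bs <- .boxed_sites(paste0("C", 1:6), rep("C", 6), xyz, padding = 5,
                       attached_hydrogens = c(0L, rep(3L, 5)))
    return(.fixture_desc(bs$sites, a = bs$a, name = "defect_overvalence"))
  }
  if (kind == "polymer") {
    # one CH2 per cell bonded to its own translation images along a
    sites <- data.frame(
      label = "C1", element = "C", fx = 0, fy = 0.5, fz = 0.5,
      occupancy = 1, attached_hydrogens = 2L,
      disorder_assembly = NA_character_, disorder_group = NA_character_,
      stringsAsFactors = FALSE)
    return(.fixture_desc(sites, a = 1.54, b = 12, c = 12,
                         name = "defect_polymer"))
  }
  if (kind == "disorder") {
    stopifnot(length(groups) == 2, length(occupancies) == 2)
    sites <- data.frame(
      label = c("O1A", "O1B"), element = c("O", "O"),
      fx = c(0.5, 0.5 + 0.9 / 12), fy = 0.5, fz = 0.5,
      occupancy = occupancies, attached_hydrogens = 2L,
      disorder_assembly = "A", disorder_group = groups,
      stringsAsFactors = FALSE)
    return(.fixture_desc(sites, a = 12, name = "defect_disorder"))
  }
  # compositional: Fe/Co 1:1 on one site, two chloride ligands
  sites <- data.frame(
    label = c("Fe1", "Co1", "Cl1", "Cl2"),
    element = c("Fe", "Co", "Cl", "Cl"),
    fx = c(0.5, 0.5, 0.5 + 2.3 / 14, 0.5 - 2.3 / 14),
    fy = 0.5, fz = 0.5,
    occupancy = c(0.5, 0.5, 1, 1),
    attached_hydrogens = 0L,
    disorder_assembly = c("A", "A", NA, NA),
    disorder_group = c("1", "2", NA, NA),
    stringsAsFactors = FALSE)
  .fixture_desc(sites, a = 14, name = "defect_compositional")
}

#' Cyclooctatetraenide salt fixture
#'
#' A planar C8H8 ring with equal C-C bonds (1.41 A, between the single- and
#' double-bond means, i.e. fully delocalized) and two alkali counterions on
#' the ring axis. The counterions can only take a +1 oxidation state, so the
#' ring must absorb a 2- delocalized charge on two valence-compatible
#' carbons.
#'
#' @param counterion Alkali metal symbol.
#' @param cell_padding Gap to the cell boundary in angstroms.
#' @return A [crystal_description()].
#' @export
make_cot_salt <- function(counterion = "K", cell_padding = 5) {
  rr <- 1.41 / (2 * sin(pi / 8))
  rh <- rr + 1.08
  ang <- (0:7) * pi / 4
  dk <- covalent_radius(counterion) + covalent_radius("C") + 0.1
  h <- sqrt(max(dk^2 - rr^2, 1))
  xyz <- rbind(cbind(rr * cos(ang), rr * sin(ang), 0),
               cbind(rh * cos(ang), rh * sin(ang), 0),
               c(0, 0, h), c(0, 0, -h))
  bs <- .boxed_sites(c(paste0("C", 1:8), paste0("H", 1:8),
                       paste0(counterion, 1:2)),
                     c(rep("C", 8), rep("H", 8), rep(counterion, 2)),
                     xyz, cell_padding)
  .fixture_desc(bs$sites, a = bs$a, name = "cot_salt",
                declared_formula = stats::setNames(c(8L, 8L, 2L),
                                                   c("C", "H", counterion)))
}

# ---- CIF serialization of fixtures -----------------------------------------

#' Render a crystal description as CIF text
#'
#' Writes the restricted item vocabulary that [read_cif()] consumes, so every
#' fixture round-trips through the parser.
#'
#' @param desc A [crystal_description()].
#' @return Character vector of CIF lines.
#' @export
format_cif <- function(desc) {
  cell <- desc$cell
  quote_val <- function(x) {
    if (grepl("[ \t']", x)) paste0("\"", x, "\"") else x
  }
  lines <- c(
    sprintf("data_%s", desc$name),
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.4f", cell$alpha),
    sprintf("_cell_angle_beta %.4f", cell$beta),
    sprintf("_cell_angle_gamma %.4f", cell$gamma))
  if (!is.na(desc$space_group_number)) {
    lines <- c(lines, sprintf("_symmetry_Int_Tables_number %d",
                              desc$space_group_number))
  }
  if (!is.null(desc$declared_formula)) {
    f <- desc$declared_formula
    lines <- c(lines, paste0("_chemical_formula_sum '",
                             paste0(names(f), f, collapse = " "), "'"))
  }
  prov <- desc$provenance
  if (!is.null(prov$doi)) {
    lines <- c(lines, paste("_journal_paper_doi", prov$doi))
  }
  if (!is.null(prov$journal)) {
    lines <- c(lines, paste("_journal_name_full", quote_val(prov$journal)))
  }
  if (!is.null(prov$year) && !is.na(prov$year)) {
    lines <- c(lines, paste("_journal_year", prov$year))
  }
  if (length(desc$markup_flags) > 0) {
    lines <- c(lines, paste0("_cod_markup_flags '",
                             paste(desc$markup_flags, collapse = " "), "'"))
  }
  lines <- c(lines, "loop_", "_symmetry_equiv_pos_as_xyz",
             vapply(desc$operators, function(op)
               paste0("'", format_symop(op), "'"), character(1)))
  s <- desc$sites
  na_dot <- function(x) ifelse(is.na(x), ".", x)
  lines <- c(lines, "loop_",
             "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy", "_atom_site_attached_hydrogens",
             "_atom_site_disorder_assembly", "_atom_site_disorder_group",
             sprintf("%s %s %.8f %.8f %.8f %.4f %d %s %s",
                     s$label, s$element, s$fx, s$fy, s$fz, s$occupancy,
                     s$attached_hydrogens, na_dot(s$disorder_assembly),
                     na_dot(s$disorder_group)))
  lines
}

#' Write the full fixture set as CIF files
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (names are stable).
#' @export
write_fixture_set <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- list(
    benzene = make_benzene(),
    ferrocene = make_ferrocene(),
    azide_symmetric = make_azide(1.24, 1.24),
    azide_asymmetric = make_azide(1.35, 1.13),
    nacl = make_nacl(),
    cot_salt = make_cot_salt(),
    two_waters = make_two_waters(),
    inversion_dimer = make_inversion_dimer(),
    defect_clash = make_defect("clash"),
    defect_overvalence = make_defect("overvalence"),
    defect_polymer = make_defect("polymer"),
    defect_disorder = make_defect("disorder"),
    defect_compositional = make_defect("compositional"))
  paths <- character(0)
  for (nm in names(fixtures)) {
    p <- file.path(dir, paste0(nm, ".cif"))
    writeLines(format_cif(fixtures[[nm]]), p)
    paths[nm] <- p
  }
  invisible(paths)
}
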