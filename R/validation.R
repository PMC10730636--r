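# Six molecular-geometry checks on a perceived structure and six entry-level
# data quality tests. Nothing in this module removes atoms, bonds or entries:
# problems are recorded, entries are marked, never dropped.

empty_issues <- function() {
  data.frame(category = character(0), atom = integer(0), bond = integer(0),
             message = character(0), stringsAsFactors = FALSE)
}

issue_row <- function(category, atom = NA_integer_, bond = NA_integer_,
                      message = "") {
  stopifnot(category %in% c("pi_count", "bond_geometry", "bond_length",
                            "radical", "atom_charge", "ensemble_charge"))
  data.frame(category = category, atom = atom, bond = bond,
             message = message, stringsAsFactors = FALSE)
}

# factual pi electron count of an atom: double bonds contribute 1, triples 2;
# atoms participating in at least one delocalized bond contribute a single pi
# electron in total
.factual_pi <- function(st, a) {
  b <- st$bonds
  rows <- b$order != 0L & (b$i == a | b$j == a)
  if (any(rows & b$delocalized)) return(1L)
  sum(pmax(0L, b$order[rows] - 1L))
}

# set of expected pi counts given species and geometry
.expected_pi_set <- function(st, a, cfg) {
  nb <- .cov_neighbors(st, a)
  npos <- length(nb)
  total <- npos + st$atoms$attached_hydrogens[a]
  if (total >= 4) return(0L)
  if (total == 3) {
    if (npos < 3) return(c(0L, 1L))
    geom <- atom_geometry(st, a, cfg)
    return(if (geom == "sp2") c(0L, 1L) else 0L)
  }
  if (total == 2) {
    if (npos < 2) return(c(0L, 1L, 2L))
    geom <- atom_geometry(st, a, cfg)
    return(if (geom == "sp") c(1L, 2L) else c(0L, 1L))
  }
  if (total == 1) return(c(0L, 1L, 2L))
  0L
}

#' Check pi electron counts against atomic geometry
#'
#' Compares the factual pi electron count of every atom (double bond = 1,
#' triple bond = 2, any delocalized participation = 1 in total) with the
#' values expected from the chemical species and its geometry. Applies only
#' to B, C, N, O, Si, P, S, Cl, Ge, As, Se, Br, Te and I.
#'
#' @param st A perceived [chemical_structure()].
#' @param cfg A [perception_config()].
#' @return data.frame of issues.
#' @export
check_pi_count <- function(st, cfg = perception_config()) {
  out <- empty_issues()
  pc <- pi_capable_elements()
  for (a in seq_len(nrow(st$atoms))) {
    if (!st$atoms$element[a] %in% pc) next
    fact <- .factual_pi(st, a)
    expd <- .expected_pi_set(st, a, cfg)
    if (!fact %in% expd) {
      out <- rbind(out, issue_row(
        "pi_count", atom = a,
        message = sprintf("%s%d: factual pi count %d, expected {%s}",
                          st$atoms$element[a], a, fact,
                          paste(expd, collapse = ","))))
    }
  }
  out
}

#' Check bond types against bond and torsion angles
#'
#' Double bonds between two pyramidal centres or twisted beyond the torsion
#' threshold are flagged. Bond lengths play no role in this check.
#'
#' @inheritParams check_pi_count
#' @return data.frame of issues.
#' @export
check_bond_geometry <- function(st, cfg = perception_config()) {
  out <- empty_issues()
  for (b in which(st$bonds$order == 2L)) {
    i <- st$bonds$i[b]; j <- st$bonds$j[b]
    gi <- atom_geometry(st, i, cfg); gj <- atom_geometry(st, j, cfg)
    if (gi == "sp3" && gj == "sp3") {
      out <- rbind(out, issue_row(
        "bond_geometry", bond = b,
        message = sprintf("double bond %d-%d between two pyramidal centres",
                          i, j)))
      next
    }
    ni <- setdiff(.cov_neighbors(st, i), j)
    nj <- setdiff(.cov_neighbors(st, j), i)
    if (length(ni) == 0 || length(nj) == 0) next
    devs <- c()
    for (a in ni) for (d in nj) {
      t <- abs(.torsion_deg(.atom_xyz(st, a), .atom_xyz(st, i),
                            .atom_xyz(st, j), .atom_xyz(st, d)))
      devs <- c(devs, min(t, abs(180 - t)))
    }
    if (min(devs) > cfg$torsion_threshold) {
      out <- rbind(out, issue_row(
        "bond_geometry", bond = b,
        message = sprintf("double bond %d-%d twisted by %.0f degrees",
                          i, j, min(devs))))
    }
  }
  out
}

#' Check bond lengths against previously observed distributions
#'
#' A bond is flagged iff its length falls outside `sigma_threshold` standard
#' deviations from its assigned class mean AND some other order's class fits
#' the observed length better. Delocalized (Kekule ring) bonds are skipped:
#' their lengths sit between the single- and double-bond class means by
#' construction and the bundled class table carries no dedicated delocalized
#' classes.
#'
#' @inheritParams check_pi_count
#' @param classes Bond class table.
#' @return data.frame of issues.
#' @export
check_bond_length <- function(st, classes = default_bond_classes(),
                              cfg = perception_config()) {
  out <- empty_issues()
  z <- .atom_Z(st)
  for (b in seq_len(nrow(st$bonds))) {
    o <- st$bonds$order[b]
    if (o == 0L || st$bonds$delocalized[b]) next
    ranked <- rank_orders(z[st$bonds$i[b]], z[st$bonds$j[b]],
                          st$bonds$length[b], classes)
    if (nrow(ranked) == 0 || !o %in% ranked$order) next
    zb <- ranked$abs_z[ranked$order == o]
    if (zb <= cfg$sigma_threshold + 1e-9) next
    better <- ranked$abs_z[ranked$order != o]
    if (length(better) > 0 && any(better < zb)) {
      out <- rbind(out, issue_row(
        "bond_length", bond = b,
        message = sprintf(
          "bond %d-%d (order %d) deviates %.1f sigma with a better-fitting alternative",
          st$bonds$i[b], st$bonds$j[b], o, zb)))
    }
  }
  out
}

#' Check for radical atoms
#' @inheritParams check_pi_count
#' @return data.frame of issues.
#' @export
check_radicals <- function(st, cfg = perception_config()) {
  out <- empty_issues()
  for (a in which(st$atoms$radical)) {
    out <- rbind(out, issue_row(
      "radical", atom = a,
      message = sprintf("%s%d is a radical atom", st$atoms$element[a], a)))
  }
  out
}

#' Check formal charges against per-element allowed values
#'
#' Metal charges must belong to the element's enumerated oxidation states;
#' other charges to the set derived from the element's known valences.
#'
#' @inheritParams check_pi_count
#' @return data.frame of issues.
#' @export
check_atom_charges <- function(st, cfg = perception_config()) {
  out <- empty_issues()
  el <- element_properties()
  for (a in seq_len(nrow(st$atoms))) {
    ch <- st$atoms$charge[a]
    allowed <- el[st$atoms$element[a], "allowed_charges"][[1]]
    if (!ch %in% allowed) {
      out <- rbind(out, issue_row(
        "atom_charge", atom = a,
        message = sprintf("%s%d charge %+d outside allowed set {%s}",
                          st$atoms$element[a], a, ch,
                          paste(allowed, collapse = ","))))
    }
  }
  out
}

#' Check that the ensemble formal charge sums to zero
#' @inheritParams check_pi_count
#' @return data.frame of issues.
#' @export
check_ensemble_charge <- function(st, cfg = perception_config()) {
  s <- sum(st$atoms$charge)
  if (s == 0) return(empty_issues())
  issue_row("ensemble_charge",
            message = sprintf("ensemble formal charge sums to %+d", s))
}

#' Run all six molecular-geometry checks
#' @inheritParams check_bond_length
#' @return data.frame of issues (possibly zero rows).
#' @export
validate_structure <- function(st, classes = default_bond_classes(),
                               cfg = perception_config()) {
  rbind(check_pi_count(st, cfg),
        check_bond_geometry(st, cfg),
        check_bond_length(st, classes, cfg),
        check_radicals(st, cfg),
        check_atom_charges(st, cfg),
        check_ensemble_charge(st, cfg))
}

#' Are a declared and a computed chemical formula compatible?
#'
#' Compatible means identical, or the computed (stoichiometric) formula is a
#' positive integer multiple of the declared one, as happens when the
#' ensemble contains several independent instances of each entity.
#'
#' @param declared,computed Named element -> count vectors.
#' @return `TRUE` or `FALSE`.
#' @export
formula_compatible <- function(declared, computed) {
  if (is.null(declared) || is.null(computed)) return(FALSE)
  declared <- declared[order(names(declared))]
  computed <- computed[order(names(computed))]
  if (!identical(names(declared), names(computed))) return(FALSE)
  if (any(declared <= 0) || any(computed <= 0)) return(FALSE)
  k <- computed[[1]] / declared[[1]]
  if (abs(k - round(k)) > 1e-9 || k < 1) return(FALSE)
  all(abs(computed - k * declared) < 1e-9)
}

#' Judge an entry against the six data-quality criteria
#'
#' Criteria: `chemical_structure` (no geometry-check issues),
#' `chemical_formula` (declared vs computed compatibility; passes when no
#' formula was declared), `data_provenance` (a DOI or a journal reference),
#' `compositional_disorder` (no compositionally disordered sites),
#' `cod_markup` (not flagged duplicate/suboptimal/theoretical) and
#' `manual_review` (not manually excluded). Entries failing criteria are
#' marked, never dropped.
#'
#' @param issues Issue data.frame from [validate_structure()].
#' @param ensemble The `stoichiometric_ensemble` of the entry.
#' @return List of class `entry_verdict` with logical `criteria` and
#'   `overall_valid`.
#' @export
judge_entry <- function(issues, ensemble) {
  prov <- ensemble$provenance
  has_doi <- !is.null(prov$doi) && nzchar(prov$doi)
  has_journal <- !is.null(prov$journal) && nzchar(prov$journal) &&
    !is.null(prov$year) && !is.na(prov$year)
  crit <- c(
    chemical_structure = nrow(issues) == 0,
    chemical_formula = is.null(ensemble$declared_formula) ||
      formula_compatible(ensemble$declared_formula, ensemble$formula),
    data_provenance = has_doi || has_journal,
    compositional_disorder = !isTRUE(ensemble$contains_compositional_disorder),
    cod_markup = !any(c("duplicate", "suboptimal", "theoretical") %in%
                        ensemble$markup_flags),
    manual_review = !"manual-exclusion" %in% ensemble$markup_flags)
  structure(list(criteria = crit, overall_valid = all(crit)),
            class = "entry_verdict")
}
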