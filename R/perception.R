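# The six-step chemical-structure assignment algorithm:
#   1. determination of atomic connectivity
#   2. assignment of unambiguous higher order bonds
#   3. assignment of unambiguous functional groups
#   4. assignment of aromatic and resonance structure bonds (Kekule)
#   5. assignment of higher order bonds deviating from expected geometry
#   6. assignment of formal charges
# Bonds involving metal atoms are recorded as zero-order coordination bonds
# and ignored in formal-charge bookkeeping.

#' Perception configuration
#'
#' @param tolerance Connectivity tolerance in angstroms added to the
#'   covalent-radii sum.
#' @param max_bond_cutoff Absolute upper bound on any bond length (angstrom).
#' @param clash_factor Two atoms closer than `clash_factor` times their
#'   covalent-radii sum constitute a steric clash ("atomic bump").
#' @param merge_tol Special-position merge tolerance (angstrom).
#' @param max_polymer_atoms Entity size cap during polymer growth.
#' @param unambiguous_z |z| bound under which a bond order counts as
#'   compatible with a bond class during unambiguous assignment.
#' @param planarity_gate Degrees: a 3-coordinate atom is sp2-compatible when
#'   its bond-angle sum is within this gate of 360.
#' @param sp_gate Degrees: a 2-coordinate atom is sp-compatible when its bond
#'   angle exceeds this value.
#' @param torsion_threshold Degrees: double bonds twisted beyond this are
#'   geometry-incompatible.
#' @param kekule_max_system Largest ring system kekulized by exhaustive
#'   matching enumeration.
#' @param max_atoms Hard cap on perceived ensemble size.
#' @param sigma_threshold The 3-sigma rule threshold for bond-length
#'   validation.
#' @return A list of class `perception_config`.
#' @export
perception_config <- function(tolerance = 0.4, max_bond_cutoff = 4.0,
                              clash_factor = 0.5, merge_tol = 0.01,
                              max_polymer_atoms = 400, unambiguous_z = 3,
                              planarity_gate = 10, sp_gate = 160,
                              torsion_threshold = 25, kekule_max_system = 18,
                              max_atoms = 10000, sigma_threshold = 3) {
  stopifnot(sigma_threshold > 0, tolerance >= 0, clash_factor > 0)
  structure(list(tolerance = tolerance, max_bond_cutoff = max_bond_cutoff,
                 clash_factor = clash_factor, merge_tol = merge_tol,
                 max_polymer_atoms = max_polymer_atoms,
                 unambiguous_z = unambiguous_z,
                 planarity_gate = planarity_gate, sp_gate = sp_gate,
                 torsion_threshold = torsion_threshold,
                 kekule_max_system = kekule_max_system,
                 max_atoms = max_atoms, sigma_threshold = sigma_threshold),
            class = "perception_config")
}

#' Construct a chemical structure object
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z` and optionally
#'   `charge`, `attached_hydrogens`, `radical`, `entity`, `label`.
#' @param bonds data.frame with `i`, `j`, `order`, `delocalized`, `length`
#'   (may be zero rows).
#' @param meta Optional metadata list.
#' @return Object of class `chemical_structure`.
#' @export
chemical_structure <- function(atoms, bonds = NULL, meta = list()) {
  stopifnot(is.data.frame(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"charge_fixed" %in% names(atoms)) atoms$charge_fixed <- FALSE
  if (!"attached_hydrogens" %in% names(atoms)) atoms$attached_hydrogens <- 0L
  if (!"radical" %in% names(atoms)) atoms$radical <- FALSE
  if (!"entity" %in% names(atoms)) atoms$entity <- 1L
  if (!"label" %in% names(atoms)) {
    atoms$label <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        resolved = logical(0), delocalized = logical(0),
                        length = numeric(0))
  }
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i != bonds$j),
              all(bonds$i >= 1), all(bonds$j <= nrow(atoms)))
  }
  structure(list(atoms = atoms, bonds = bonds,
                 issues = empty_issues(), ring_systems = list(), meta = meta),
            class = "chemical_structure")
}

# ---- step 1: connectivity ---------------------------------------------------

#' Determine atomic connectivity from Cartesian coordinates
#'
#' Two atoms are bonded when their distance does not exceed
#' `min(r_A + r_B + tolerance, max_bond_cutoff)` where `r` are covalent
#' radii. All bonds start as provisional single bonds.
#'
#' @param atoms data.frame with `element`, `x`, `y`, `z`.
#' @param tolerance,max_bond_cutoff See [perception_config()].
#' @return Bond data.frame (`i < j`, provisional `order = 1`,
#'   `resolved = FALSE`).
#' @export
detect_connectivity <- function(atoms, tolerance = 0.4, max_bond_cutoff = 4.0) {
  n <- nrow(atoms)
  empty <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                      resolved = logical(0), delocalized = logical(0),
                      length = numeric(0))
  if (n < 2) return(empty)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- pmin(outer(r, r, "+") + tolerance, max_bond_cutoff)
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  b <- data.frame(i = hit[, 1], j = hit[, 2], order = 1L,
                  resolved = FALSE, delocalized = FALSE,
                  length = d[hit])
  b <- b[order(b$i, b$j), ]
  rownames(b) <- NULL
  b
}

# ---- geometry helpers -------------------------------------------------------

.covalent_bond_rows <- function(st) which(st$bonds$order != 0L)

# indices of covalently bonded neighbours of atom a (order >= 1 or unresolved)
.cov_neighbors <- function(st, a) {
  b <- st$bonds
  rows <- b$order != 0L & (b$i == a | b$j == a)
  c(b$j[rows & b$i == a], b$i[rows & b$j == a])
}

.angle_deg <- function(p1, p0, p2) {
  v1 <- p1 - p0; v2 <- p2 - p0
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

.torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb, sum(n1 * n2)) * 180 / pi
}

.atom_xyz <- function(st, a) {
  as.numeric(st$atoms[a, c("x", "y", "z")])
}

# Hybridization-like geometry class of an atom: one of
# "sp", "sp2", "sp3", "bent", "terminal", "unknown".
atom_geometry <- function(st, a, cfg = perception_config()) {
  nb <- .cov_neighbors(st, a)
  npos <- length(nb)
  total <- npos + st$atoms$attached_hydrogens[a]
  if (total >= 4) return("sp3")
  if (npos == 3) {
    # RMS out-of-plane angle: for each neighbour, the deviation of its bond
    # vector from the plane spanned by the other two
    p0 <- .atom_xyz(st, a)
    v <- lapply(nb, function(w) .atom_xyz(st, w) - p0)
    devs <- vapply(1:3, function(k) {
      o <- setdiff(1:3, k)
      n1 <- v[[o[1]]]; n2 <- v[[o[2]]]
      nrm <- c(n1[2] * n2[3] - n1[3] * n2[2],
               n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1])
      s <- sum(nrm * v[[k]]) / sqrt(sum(nrm^2) * sum(v[[k]]^2))
      abs(asin(pmin(1, pmax(-1, s))) * 180 / pi)
    }, numeric(1))
    rms <- sqrt(mean(devs^2))
    return(if (rms < cfg$planarity_gate) "sp2" else "sp3")
  }
  if (npos == 2) {
    if (total > npos) return("unknown")
    p0 <- .atom_xyz(st, a)
    ang <- .angle_deg(.atom_xyz(st, nb[1]), p0, .atom_xyz(st, nb[2]))
    return(if (ang >= cfg$sp_gate) "sp" else "bent")
  }
  if (npos <= 1 && total > npos) return("unknown")
  "terminal"
}

.sp2_compatible <- function(geom) geom != "sp3"
.sp_compatible <- function(geom) geom %in% c("sp", "terminal", "unknown")

# Current bond-order sum of an atom (unresolved covalent bonds count as 1),
# attached hydrogens included.
.order_sum <- function(st, a) {
  b <- st$bonds
  rows <- b$order != 0L & (b$i == a | b$j == a)
  sum(b$order[rows]) + st$atoms$attached_hydrogens[a]
}

# Free valence against the element's maximum known valence; 0 for metals.
.free_valence <- function(st, a) {
  info <- element_info(st$atoms$element[a])
  if (info$is_metal) return(0L)
  v <- info$valences[[1]]
  if (length(v) == 0) return(0L)
  max(0L, max(v) - .order_sum(st, a))
}

.atom_Z <- function(st) {
  el <- element_properties()
  el[st$atoms$element, "Z"]
}

# ---- preflight --------------------------------------------------------------

#' Screen for defects that guarantee an incorrect chemical description
#'
#' Reports steric clashes (two atoms closer than `clash_factor` times the
#' covalent-radii sum) and atoms with more bonded neighbours than their
#' maximum known valence allows. Any report causes [perceive()] to exclude
#' the entry.
#'
#' @param st A [chemical_structure()] with connectivity assigned.
#' @param cfg A [perception_config()].
#' @return data.frame of defects (`kind` in `c("clash", "overvalence")`).
#' @export
preflight_screen <- function(st, cfg = perception_config()) {
  atoms <- st$atoms
  out <- data.frame(kind = character(0), atom1 = integer(0),
                    atom2 = integer(0), message = character(0))
  n <- nrow(atoms)
  if (n >= 2) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    r <- covalent_radius(atoms$element)
    d <- as.matrix(stats::dist(xyz))
    lim <- cfg$clash_factor * outer(r, r, "+")
    hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      out <- rbind(out, data.frame(
        kind = "clash", atom1 = hit[k, 1], atom2 = hit[k, 2],
        message = sprintf("atomic bump: %s%d-%s%d at %.2f A",
                          atoms$element[hit[k, 1]], hit[k, 1],
                          atoms$element[hit[k, 2]], hit[k, 2],
                          d[hit[k, 1], hit[k, 2]])))
    }
  }
  el <- element_properties()
  for (a in seq_len(n)) {
    info <- el[atoms$element[a], ]
    if (info$is_metal) next
    v <- info$valences[[1]]
    if (length(v) == 0) next
    nb <- .cov_neighbors(st, a)
    nb <- nb[!el[atoms$element[nb], "is_metal"]]
    total <- length(nb) + atoms$attached_hydrogens[a]
    if (total > max(v)) {
      out <- rbind(out, data.frame(
        kind = "overvalence", atom1 = a, atom2 = NA_integer_,
        message = sprintf("%s%d has %d bonded neighbours, maximum valence %d",
                          atoms$element[a], a, total, max(v))))
    }
  }
  out
}

# ---- metal bonds ------------------------------------------------------------

#' Set every metal-incident bond to a zero-order coordination bond
#'
#' No attempt is made to resolve the most likely order of bonds involving
#' metal atoms; hapticity follows since every coordinated atom within bonding
#' distance is connected to the metal centre.
#'
#' @param st A [chemical_structure()].
#' @return The structure with metal-incident bonds set to order 0 (resolved).
#' @export
assign_metal_bonds <- function(st) {
  el <- element_properties()
  metal <- el[st$atoms$element, "is_metal"]
  rows <- metal[st$bonds$i] | metal[st$bonds$j]
  st$bonds$order[rows] <- 0L
  st$bonds$resolved[rows] <- TRUE
  st
}

# ---- contextual order candidates -------------------------------------------

# Fixed pi contribution of atom a from bonds other than bond row b.
.fixed_pi_other <- function(st, a, b) {
  bb <- st$bonds
  rows <- which(bb$order != 0L & (bb$i == a | bb$j == a))
  rows <- setdiff(rows, b)
  sum(pmax(0L, bb$order[rows] - 1L))
}

# Number of still-unresolved covalent bonds of a (excluding b) whose partner
# is pi-capable, i.e. potential additional pi sources.
.open_pi_other <- function(st, a, b) {
  bb <- st$bonds
  rows <- which(!bb$resolved & bb$order != 0L & (bb$i == a | bb$j == a))
  rows <- setdiff(rows, b)
  if (length(rows) == 0) return(0L)
  partners <- ifelse(bb$i[rows] == a, bb$j[rows], bb$i[rows])
  pc <- element_properties()[st$atoms$element[partners], "pi_capable"]
  sum(pc)
}

# Candidate (order, z) table for bond row b, filtering classes by the pi
# contexts achievable for each endpoint under each order hypothesis.
.candidate_orders <- function(st, b, classes, cfg) {
  i <- st$bonds$i[b]; j <- st$bonds$j[b]
  z <- .atom_Z(st)
  zi <- z[i]; zj <- z[j]
  z1 <- min(zi, zj); z2 <- max(zi, zj)
  sub <- classes[classes$Z1 == z1 & classes$Z2 == z2, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  d <- st$bonds$length[b]
  lo_i <- .fixed_pi_other(st, i, b); hi_i <- lo_i + 2L * .open_pi_other(st, i, b)
  lo_j <- .fixed_pi_other(st, j, b); hi_j <- lo_j + 2L * .open_pi_other(st, j, b)
  ok <- logical(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    o <- sub$order[r]
    ri <- c(lo_i + o - 1L, hi_i + o - 1L)
    rj <- c(lo_j + o - 1L, hi_j + o - 1L)
    fits <- function(pi_first, pi_second) {
      pi_first >= ri[1] && pi_first <= ri[2] &&
        pi_second >= rj[1] && pi_second <= rj[2]
    }
    if (zi <= zj) {
      ok[r] <- fits(sub$pi1[r], sub$pi2[r]) ||
        (zi == zj && fits(sub$pi2[r], sub$pi1[r]))
    } else {
      ok[r] <- sub$pi2[r] >= ri[1] && sub$pi2[r] <= ri[2] &&
        sub$pi1[r] >= rj[1] && sub$pi1[r] <= rj[2]
    }
  }
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  sub$z <- (d - sub$mean) / sub$sigma
  sub$abs_z <- abs(sub$z)
  best <- do.call(rbind, lapply(split(sub, sub$order), function(g) {
    g[which.min(g$abs_z), , drop = FALSE]
  }))
  best[order(best$abs_z, best$order), , drop = FALSE]
}

# Bonds deferred to the Kekule step: unresolved bonds lying on a cycle whose
# atoms are all pi-capable, sp2-compatible and have free valence.
.aromatic_deferred <- function(st, cfg) {
  el <- element_properties()
  n <- nrow(st$atoms)
  cand <- vapply(seq_len(n), function(a) {
    info <- el[st$atoms$element[a], ]
    !info$is_metal && info$pi_capable && .free_valence(st, a) >= 1 &&
      .sp2_compatible(atom_geometry(st, a, cfg))
  }, logical(1))
  rows <- which(!st$bonds$resolved & st$bonds$order != 0L &
                  cand[st$bonds$i] & cand[st$bonds$j])
  if (length(rows) < 3) return(integer(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = st$bonds$i[rows], to = st$bonds$j[rows], row = rows),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  bc <- igraph::biconnected_components(g)
  cyc <- integer(0)
  for (k in seq_along(bc$component_edges)) {
    eids <- bc$component_edges[[k]]
    if (length(eids) >= 3) {
      cyc <- c(cyc, igraph::edge_attr(g, "row", eids))
    }
  }
  sort(unique(cyc))
}

# ---- step 2: unambiguous higher order bonds ---------------------------------

#' Assign bond orders that are unambiguous from length and geometry
#'
#' A non-metal bond receives an order when exactly one candidate order is
#' compatible: |z| within the configured bound against the best-fitting
#' achievable-context class, free valence available at both endpoints, and
#' endpoint geometry admitting the order (sp2 planarity for doubles, near
#' linearity for triples). Bonds on all-sp2 rings are deferred to the Kekule
#' step.
#'
#' @param st A [chemical_structure()] with zero-order bonds already fixed.
#' @param classes Bond class table.
#' @param cfg A [perception_config()].
#' @return Updated structure.
#' @export
assign_unambiguous_bonds <- function(st, classes = default_bond_classes(),
                                     cfg = perception_config()) {
  el <- element_properties()
  deferred <- .aromatic_deferred(st, cfg)
  repeat {
    changed <- FALSE
    open <- which(!st$bonds$resolved & st$bonds$order != 0L)
    open <- setdiff(open, deferred)
    for (b in open) {
      i <- st$bonds$i[b]; j <- st$bonds$j[b]
      if (el[st$atoms$element[i], "is_metal"] ||
          el[st$atoms$element[j], "is_metal"]) next
      cand <- .candidate_orders(st, b, classes, cfg)
      if (nrow(cand) == 0) next
      gi <- atom_geometry(st, i, cfg); gj <- atom_geometry(st, j, cfg)
      fvi <- .free_valence(st, i); fvj <- .free_valence(st, j)
      feas <- vapply(seq_len(nrow(cand)), function(r) {
        o <- cand$order[r]
        if (cand$abs_z[r] > cfg$unambiguous_z) return(FALSE)
        if (o == 1) return(TRUE)
        if (o == 2) {
          return(fvi >= 1 && fvj >= 1 &&
                   .sp2_compatible(gi) && .sp2_compatible(gj))
        }
        fvi >= 2 && fvj >= 2 && .sp_compatible(gi) && .sp_compatible(gj)
      }, logical(1))
      if (sum(feas) == 1) {
        st$bonds$order[b] <- cand$order[feas]
        st$bonds$resolved[b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  st
}

# ---- step 3: functional groups ----------------------------------------------

# Assign the azide pattern: choose between the two-double-bond form and the
# single+triple form by the smaller total squared z against the azide-capable
# nitrogen-nitrogen classes; the structure is kept as observed, with no
# conversion to a standard resonance form afterwards.
.assign_azide <- function(st, classes, cfg) {
  el <- element_properties()
  zN <- 7L
  z <- .atom_Z(st)
  n <- nrow(st$atoms)
  best_z2 <- function(b, o) {
    i <- st$bonds$i[b]; j <- st$bonds$j[b]
    sub <- classes[classes$Z1 == zN & classes$Z2 == zN & classes$order == o, ]
    if (nrow(sub) == 0) return(1e4)
    min(((st$bonds$length[b] - sub$mean) / sub$sigma)^2)
  }
  # central N bonded to exactly two other N and nothing else
  for (a in which(st$atoms$element == "N")) {
    nb <- .cov_neighbors(st, a)
    if (length(nb) != 2 || st$atoms$attached_hydrogens[a] > 0) next
    if (!all(st$atoms$element[nb] == "N")) next
    ang <- .angle_deg(.atom_xyz(st, nb[1]), .atom_xyz(st, a),
                      .atom_xyz(st, nb[2]))
    if (ang < cfg$sp_gate) next
    # terminal nitrogens carry at most one further neighbour
    t1 <- setdiff(.cov_neighbors(st, nb[1]), a)
    t2 <- setdiff(.cov_neighbors(st, nb[2]), a)
    if (length(t1) > 1 || length(t2) > 1) next
    b1 <- which((st$bonds$i == a & st$bonds$j == nb[1]) |
                  (st$bonds$j == a & st$bonds$i == nb[1]))
    b2 <- which((st$bonds$i == a & st$bonds$j == nb[2]) |
                  (st$bonds$j == a & st$bonds$i == nb[2]))
    cost22 <- best_z2(b1, 2) + best_z2(b2, 2)
    # single+triple: the triple bond goes on the shorter contact
    if (st$bonds$length[b1] <= st$bonds$length[b2]) {
      btri <- b1; bsin <- b2
    } else {
      btri <- b2; bsin <- b1
    }
    cost13 <- best_z2(btri, 3) + best_z2(bsin, 1)
    if (cost22 <= cost13) {
      st$bonds$order[c(b1, b2)] <- 2L
    } else {
      st$bonds$order[btri] <- 3L
      st$bonds$order[bsin] <- 1L
    }
    st$bonds$resolved[c(b1, b2)] <- TRUE
  }
  st
}

# Oxo-anion style template: a non-metal centre with terminal chalcogen
# neighbours (O or S bonded to nothing else) receives as many double bonds as
# its effective valence allows, placed on the shortest contacts.
.assign_oxo_center <- function(st, classes, cfg) {
  el <- element_properties()
  centers <- which(st$atoms$element %in% c("C", "N", "S", "P", "As", "Se", "Cl", "Br", "I"))
  for (a in centers) {
    nb <- .cov_neighbors(st, a)
    sigma <- length(nb) + st$atoms$attached_hydrogens[a]
    term <- nb[vapply(nb, function(t) {
      st$atoms$element[t] %in% c("O", "S") &&
        length(.cov_neighbors(st, t)) == 1 &&
        st$atoms$attached_hydrogens[t] == 0
    }, logical(1))]
    if (length(term) < 2 && !(length(term) == 1 && st$atoms$element[a] != "C")) next
    elem <- st$atoms$element[a]
    v <- element_info(elem)$valences[[1]]
    vmax <- max(v)
    if (elem == "N" && sigma >= 3) vmax <- 4L  # quaternary N carries +1
    ndouble <- max(0L, min(length(term), vmax - sigma))
    brows <- vapply(term, function(t) {
      which((st$bonds$i == a & st$bonds$j == t) |
              (st$bonds$j == a & st$bonds$i == t))
    }, integer(1))
    if (any(st$bonds$order[brows] == 3L)) next
    ord <- order(st$bonds$length[brows], term)
    st$bonds$order[brows] <- 1L
    if (ndouble > 0) st$bonds$order[brows[ord[seq_len(ndouble)]]] <- 2L
    st$bonds$resolved[brows] <- TRUE
  }
  st
}

# Isocyanide R-N+#C-: a terminal carbon on a linear 2-coordinate nitrogen at
# triple-bond distance.
.assign_isocyanide <- function(st, classes, cfg) {
  for (a in which(st$atoms$element == "C")) {
    nb <- .cov_neighbors(st, a)
    if (length(nb) != 1 || st$atoms$attached_hydrogens[a] > 0) next
    nn <- nb[1]
    if (st$atoms$element[nn] != "N") next
    nnb <- .cov_neighbors(st, nn)
    if (length(nnb) != 2 || st$atoms$attached_hydrogens[nn] > 0) next
    ang <- .angle_deg(.atom_xyz(st, nnb[1]), .atom_xyz(st, nn),
                      .atom_xyz(st, nnb[2]))
    if (ang < cfg$sp_gate) next
    b <- which((st$bonds$i == a & st$bonds$j == nn) |
                 (st$bonds$j == a & st$bonds$i == nn))
    if (st$bonds$length[b] > 1.25) next
    st$bonds$order[b] <- 3L
    st$bonds$resolved[b] <- TRUE
    other <- setdiff(nnb, a)
    b2 <- which((st$bonds$i == nn & st$bonds$j == other) |
                  (st$bonds$j == nn & st$bonds$i == other))
    if (!st$bonds$resolved[b2]) {
      st$bonds$order[b2] <- 1L
      st$bonds$resolved[b2] <- TRUE
    }
  }
  st
}

#' Assign recognized functional-group order patterns
#'
#' Length-driven templates for azide, nitro/nitrate, carboxylate/carbonate,
#' sulfonate/sulfate, phosphate and isocyanide (nitriles are already
#' unambiguous from length and linearity). Once assigned, no conversion to a
#' standard tautomeric or resonance form is attempted.
#'
#' @inheritParams assign_unambiguous_bonds
#' @return Updated structure.
#' @export
assign_functional_groups <- function(st, classes = default_bond_classes(),
                                     cfg = perception_config()) {
  st <- .assign_azide(st, classes, cfg)
  st <- .assign_oxo_center(st, classes, cfg)
  st <- .assign_isocyanide(st, classes, cfg)
  st
}

# ---- step 5: deviant higher order bonds -------------------------------------

#' Assign higher orders to bonds with atypical geometry
#'
#' Remaining unresolved bonds between pi-capable atoms receive a higher order
#' when the bond-length class ranking supports it even though bond or torsion
#' angles are atypical. Orders fixed by earlier steps are never overridden.
#'
#' @inheritParams assign_unambiguous_bonds
#' @return Updated structure.
#' @export
assign_deviant_bonds <- function(st, classes = default_bond_classes(),
                                 cfg = perception_config()) {
  el <- element_properties()
  repeat {
    changed <- FALSE
    open <- which(!st$bonds$resolved & st$bonds$order != 0L)
    for (b in open) {
      i <- st$bonds$i[b]; j <- st$bonds$j[b]
      ei <- el[st$atoms$element[i], ]; ej <- el[st$atoms$element[j], ]
      if (ei$is_metal || ej$is_metal) next
      if (!ei$pi_capable || !ej$pi_capable) next
      ranked <- rank_orders(ei$Z, ej$Z, st$bonds$length[b], classes)
      if (nrow(ranked) == 0) next
      fv <- min(.free_valence(st, i), .free_valence(st, j))
      ranked <- ranked[ranked$order - 1L <= fv, , drop = FALSE]
      if (nrow(ranked) == 0) next
      o <- ranked$order[1]
      if (o > 1 && ranked$abs_z[1] <= cfg$unambiguous_z) {
        st$bonds$order[b] <- o
        st$bonds$resolved[b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  st
}

# ---- step 6: formal charges -------------------------------------------------

.electronegative <- c("N", "O", "S", "Se", "Te", "F", "Cl", "Br", "I", "At")

#' Assign formal charges
#'
#' Non-metal charges follow valence bookkeeping over order-1+ bonds plus
#' attached hydrogens; zero-order coordination bonds are ignored. Electron
#' deficits become negative charges on atoms coordinated to metals, on
#' electronegative atoms with only single bonds, on atoms adjacent to a
#' positive centre, or on electronegative atoms sharing an entity with a
#' metal; otherwise an odd deficit sets the radical flag. Each metal atom
#' then receives the charge that balances the summed ligand-system charge of
#' its entity, restricted to the element's enumerated oxidation states.
#'
#' @param st A [chemical_structure()] with all bond orders final.
#' @param cfg A [perception_config()].
#' @return Updated structure.
#' @export
assign_formal_charges <- function(st, cfg = perception_config()) {
  el <- element_properties()
  n <- nrow(st$atoms)
  metal <- el[st$atoms$element, "is_metal"]
  has_zero_bond <- rep(FALSE, n)
  if (nrow(st$bonds) > 0) {
    zb <- st$bonds[st$bonds$order == 0L, ]
    has_zero_bond[unique(c(zb$i, zb$j))] <- TRUE
  }
  entity_has_metal <- tapply(metal, st$atoms$entity, any)

  deficits <- integer(n)
  for (a in which(!metal)) {
    if (st$atoms$charge_fixed[a]) next
    info <- el[st$atoms$element[a], ]
    v <- info$valences[[1]]
    if (length(v) == 0 || all(v == 0)) next
    con <- .order_sum(st, a)
    if (con %in% v) {
      st$atoms$charge[a] <- 0L
    } else if (con > max(v)) {
      st$atoms$charge[a] <- con - max(v)
    } else {
      vnext <- min(v[v >= con])
      deficits[a] <- vnext - con
    }
  }
  # resolve deficits, positive neighbours now being known
  for (a in which(deficits > 0)) {
    d <- deficits[a]
    elem <- st$atoms$element[a]
    b <- st$bonds
    rows <- b$order != 0L & (b$i == a | b$j == a)
    nbrs <- c(b$j[rows & b$i == a], b$i[rows & b$j == a])
    max_order <- if (any(rows)) max(b$order[rows]) else 0L
    if (has_zero_bond[a]) {
      st$atoms$charge[a] <- -d
    } else if (elem %in% .electronegative && max_order <= 1L) {
      st$atoms$charge[a] <- -d
    } else if (length(nbrs) > 0 && any(st$atoms$charge[nbrs] > 0)) {
      st$atoms$charge[a] <- -d
    } else if (elem %in% .electronegative &&
               isTRUE(entity_has_metal[[as.character(st$atoms$entity[a])]])) {
      st$atoms$charge[a] <- -d
    } else if (d %% 2L == 1L) {
      st$atoms$radical[a] <- TRUE
    }
  }

  # metal charges balance the ligand system per entity
  for (e in unique(st$atoms$entity)) {
    idx <- which(st$atoms$entity == e)
    m <- idx[metal[idx]]
    if (length(m) == 0) next
    target <- -sum(st$atoms$charge[idx[!metal[idx]]])
    states <- lapply(st$atoms$element[m], function(s) {
      el[s, "oxidation_states"][[1]]
    })
    assign <- .balance_metal_charges(target, states)
    st$atoms$charge[m] <- assign
  }
  st
}

# Distribute `target` over metals, each constrained to its oxidation states;
# prefers the most even split. Falls back to the nearest-admissible split
# when no exact combination exists (validation will flag the imbalance).
.balance_metal_charges <- function(target, states) {
  k <- length(states)
  states <- lapply(states, function(s) if (length(s) == 0) 0L else sort(s))
  if (k == 1) {
    s <- states[[1]]
    if (target %in% s) return(target)
    return(s[which.min(abs(s - target))])
  }
  if (k <= 4 && prod(vapply(states, length, integer(1))) <= 20000) {
    grid <- as.matrix(expand.grid(states))
    sums <- rowSums(grid)
    exact <- which(sums == target)
    if (length(exact) > 0) {
      spread <- apply(grid[exact, , drop = FALSE], 1, function(r) {
        stats::var(r) + sum(abs(r - target / k)) * 1e-6
      })
      return(as.integer(grid[exact[which.min(spread)], ]))
    }
    return(as.integer(grid[which.min(abs(sums - target)), ]))
  }
  base <- target / k
  out <- integer(k)
  left <- target
  for (i in seq_len(k)) {
    want <- if (i == k) left else round(base)
    s <- states[[i]]
    out[i] <- s[which.min(abs(s - want))]
    left <- left - out[i]
  }
  out
}

# ---- the full pipeline ------------------------------------------------------

#' Perceive the chemical structure of a stoichiometric ensemble
#'
#' Runs connectivity determination, the preflight defect screen, zero-order
#' metal bond assignment and the remaining five algorithm steps in order. The
#' result is deterministic for identical input. Polymeric ensembles are
#' rejected with an explicit error (condition class
#' `cifchem_polymer_error`); fatal preflight defects raise
#' `cifchem_preflight_error` with the defect table attached.
#'
#' @param ensemble A `stoichiometric_ensemble` from [build_ensemble()].
#' @param classes Bond class table.
#' @param config A [perception_config()].
#' @param validate Run the molecular-geometry checks and store their issues?
#' @return A [chemical_structure()].
#' @export
perceive <- function(ensemble, classes = default_bond_classes(),
                     config = perception_config(), validate = TRUE) {
  stopifnot(inherits(ensemble, "stoichiometric_ensemble"))
  if (any(vapply(ensemble$entities, function(e) isTRUE(e$is_polymer),
                 logical(1)))) {
    stop(structure(class = c("cifchem_polymer_error", "error", "condition"),
                   list(message = paste0(
                     "entry ", ensemble$name,
                     " describes a polymer; polymeric molecular entities are not supported"),
                     call = NULL)))
  }
  atoms <- do.call(rbind, lapply(seq_along(ensemble$entities), function(k) {
    a <- ensemble$entities[[k]]$atoms
    data.frame(element = a$element, x = a$x, y = a$y, z = a$z,
               charge = 0L, charge_fixed = FALSE,
               attached_hydrogens = a$attached_hydrogens,
               radical = FALSE, entity = k, label = a$site_ref,
               stringsAsFactors = FALSE)
  }))
  if (nrow(atoms) > config$max_atoms) {
    stop("ensemble exceeds the configured atom limit (", config$max_atoms, ")")
  }
  st <- chemical_structure(atoms, meta = list(
    name = ensemble$name,
    space_group_number = ensemble$space_group_number,
    formula = ensemble$formula,
    declared_formula = ensemble$declared_formula,
    provenance = ensemble$provenance,
    markup_flags = ensemble$markup_flags,
    contains_compositional_disorder = ensemble$contains_compositional_disorder,
    contains_partial_occupancy = ensemble$contains_partial_occupancy,
    cell = ensemble$cell))
  st$bonds <- detect_connectivity(st$atoms, config$tolerance,
                                  config$max_bond_cutoff)
  defects <- preflight_screen(st, config)
  if (nrow(defects) > 0) {
    cond <- structure(
      class = c("cifchem_preflight_error", "error", "condition"),
      list(message = paste0("entry ", ensemble$name, " excluded: ",
                            paste(defects$message, collapse = "; ")),
           call = NULL))
    attr(cond, "defects") <- defects
    stop(cond)
  }
  st <- assign_metal_bonds(st)
  st <- assign_unambiguous_bonds(st, classes, config)
  st <- assign_functional_groups(st, classes, config)
  st <- kekulize(st, classes, config)
  st <- assign_deviant_bonds(st, classes, config)
  st$bonds$order[!st$bonds$resolved] <- 1L
  st$bonds$resolved <- rep(TRUE, nrow(st$bonds))
  st <- assign_formal_charges(st, config)
  st <- .absorb_residual_charge(st, classes, config)
  if (validate) st$issues <- validate_structure(st, classes, config)
  st
}
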