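# Reconstruction of a stoichiometrically correct molecular ensemble from the
# asymmetric unit: symmetry expansion, positional-disorder resolution,
# entity growth across lattice translations with polymer detection, and
# grouping of symmetry-equivalent entities.

#' Expand the asymmetric unit to the full unit cell
#'
#' Every atom site is imaged under every symmetry operator; images that fall
#' within `merge_tol` (minimum-image Cartesian distance) of an earlier image
#' of the same site are merged, which collapses special-position duplicates.
#'
#' @param desc A [crystal_description()].
#' @param merge_tol Special-position merge tolerance in angstroms.
#' @return A data.frame of expanded atoms with fractional and Cartesian
#'   coordinates, the generating operator index and a zero lattice shift.
#' @export
expand_to_unit_cell <- function(desc, merge_tol = 0.01) {
  stopifnot(inherits(desc, "crystal_description"))
  sites <- desc$sites
  ops <- desc$operators
  out <- list()
  for (s in seq_len(nrow(sites))) {
    frac0 <- c(sites$fx[s], sites$fy[s], sites$fz[s])
    kept <- list()
    for (k in seq_along(ops)) {
      f <- apply_symop(ops[[k]], frac0, wrap = TRUE)
      dup <- FALSE
      for (g in kept) {
        if (frac_distance(desc$cell, f, g, min_image = TRUE) < merge_tol) {
          dup <- TRUE
          break
        }
      }
      if (dup) next
      kept[[length(kept) + 1]] <- f
      out[[length(out) + 1]] <- data.frame(
        site_ref = sites$label[s], element = sites$element[s],
        fx = f[1], fy = f[2], fz = f[3],
        generating_op = k,
        occupancy = sites$occupancy[s],
        attached_hydrogens = sites$attached_hydrogens[s],
        disorder_assembly = sites$disorder_assembly[s],
        disorder_group = sites$disorder_group[s],
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, out)
  cart <- frac_to_cartesian(desc$cell, as.matrix(atoms[, c("fx", "fy", "fz")]))
  atoms$x <- cart[, 1]; atoms$y <- cart[, 2]; atoms$z <- cart[, 3]
  rownames(atoms) <- NULL
  atoms
}

#' Resolve positional disorder to a representative conformation
#'
#' Within each disorder assembly exactly one disorder group is retained,
#' selected by (1) highest summed occupancy, (2) largest atom count,
#' (3) lexicographically lesser group name. Sites belonging to no group are
#' always kept. Pairs of sites carrying different elements at (nearly) the
#' same position mark the structure as compositionally disordered; such
#' structures are flagged, not altered.
#'
#' @param sites Atom site data.frame (asymmetric unit, as in
#'   [crystal_description()]).
#' @param cell Optional [unit_cell()] used for the shared-position test.
#' @return List with `sites` (kept rows), `contains_compositional_disorder`
#'   and `contains_partial_occupancy`.
#' @export
resolve_positional_disorder <- function(sites, cell = NULL) {
  compositional <- FALSE
  if (!is.null(cell) && nrow(sites) > 1) {
    for (i in seq_len(nrow(sites) - 1)) {
      for (j in seq.int(i + 1, nrow(sites))) {
        if (sites$element[i] == sites$element[j]) next
        d <- frac_distance(cell,
                           c(sites$fx[i], sites$fy[i], sites$fz[i]),
                           c(sites$fx[j], sites$fy[j], sites$fz[j]))
        if (d < 0.5) compositional <- TRUE
      }
    }
  }
  grp <- sites$disorder_group
  asm <- sites$disorder_assembly
  asm[is.na(asm) & !is.na(grp)] <- "."
  keep <- rep(TRUE, nrow(sites))
  for (a in unique(asm[!is.na(asm)])) {
    in_asm <- which(!is.na(asm) & asm == a & !is.na(grp))
    groups <- unique(grp[in_asm])
    if (length(groups) <= 1) next
    score <- data.frame(
      name = groups,
      occ = vapply(groups, function(g)
        sum(sites$occupancy[in_asm][grp[in_asm] == g]), numeric(1)),
      n = vapply(groups, function(g)
        sum(grp[in_asm] == g), integer(1)),
      stringsAsFactors = FALSE)
    score <- score[order(-score$occ, -score$n, score$name), ]
    chosen <- score$name[1]
    keep[in_asm][grp[in_asm] != chosen] <- FALSE
  }
  kept <- sites[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(sites = kept,
       contains_compositional_disorder = compositional,
       contains_partial_occupancy = any(kept$occupancy < 1 - 1e-9))
}

# Default bond predicate: covalent-radii sum plus tolerance, capped.
radius_bond_fn <- function(tolerance = 0.4, max_bond_cutoff = 4.0) {
  force(tolerance); force(max_bond_cutoff)
  function(elem1, elem2, d) {
    d <= pmin(covalent_radius(elem1) + covalent_radius(elem2) + tolerance,
              max_bond_cutoff) & d > 1e-6
  }
}

#' Grow molecular entities across lattice translations
#'
#' Breadth-first growth over the bonding relation, following bonds into
#' neighbouring unit cells. An entity is flagged as a polymer when growth
#' reconnects to an already included image of the same unit-cell atom under a
#' different lattice shift (a periodically repeating, infinite entity); a
#' polymer entity is truncated to one period and capped at
#' `max_polymer_atoms`.
#'
#' @param atoms Expanded unit-cell atoms from [expand_to_unit_cell()].
#' @param cell The [unit_cell()].
#' @param bond_fn Vectorized predicate `f(elem1, elem2, d)` deciding bonding.
#' @param max_polymer_atoms Hard cap on entity size.
#' @return List of entities; each has `atoms` (with `lattice_shift` columns
#'   `s1 s2 s3` and Cartesian coordinates) and `is_polymer`.
#' @export
grow_entities <- function(atoms, cell, bond_fn = radius_bond_fn(),
                          max_polymer_atoms = 400) {
  n <- nrow(atoms)
  frac <- as.matrix(atoms[, c("fx", "fy", "fz")])
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  # adjacency: for each ordered pair (i, j) the lattice shifts of j that bond
  # to i at shift 0
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      delta <- sweep(shifts, 2, frac[i, ] - frac[j, ], "+")
      cart <- delta %*% t(cell$ortho)
      d <- sqrt(rowSums(cart^2))
      hit <- which(bond_fn(rep(atoms$element[i], length(d)),
                           rep(atoms$element[j], length(d)), d))
      if (i == j) hit <- hit[rowSums(abs(shifts[hit, , drop = FALSE])) > 0]
      if (length(hit) > 0) {
        nbr[[i]][[length(nbr[[i]]) + 1]] <-
          cbind(j = j, -shifts[hit, , drop = FALSE])
      }
    }
  }
  nbr <- lapply(nbr, function(x) if (length(x)) do.call(rbind, x) else NULL)

  assigned <- rep(FALSE, n)
  entities <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    shift_of <- matrix(NA_real_, n, 3)
    shift_of[seed, ] <- 0
    queue <- seed
    members <- seed
    is_polymer <- FALSE
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      nb <- nbr[[i]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]
        s <- shift_of[i, ] + nb[r, 2:4]
        if (is.na(shift_of[j, 1])) {
          if (length(members) >= max_polymer_atoms) {
            is_polymer <- TRUE
            next
          }
          shift_of[j, ] <- s
          members <- c(members, j)
          queue <- c(queue, j)
        } else if (any(abs(shift_of[j, ] - s) > 1e-6)) {
          # reconnection to another image of the same atom: periodic entity
          is_polymer <- TRUE
        }
      }
    }
    members <- sort(members)
    assigned[members] <- TRUE
    ent_atoms <- atoms[members, , drop = FALSE]
    sh <- shift_of[members, , drop = FALSE]
    ent_atoms$s1 <- sh[, 1]; ent_atoms$s2 <- sh[, 2]; ent_atoms$s3 <- sh[, 3]
    f <- as.matrix(ent_atoms[, c("fx", "fy", "fz")]) + sh
    cart <- f %*% t(cell$ortho)
    ent_atoms$x <- cart[, 1]; ent_atoms$y <- cart[, 2]; ent_atoms$z <- cart[, 3]
    rownames(ent_atoms) <- NULL
    entities[[length(entities) + 1]] <-
      list(atoms = ent_atoms, is_polymer = is_polymer)
  }
  entities
}

# Element -> count map of one entity, attached hydrogens included.
entity_formula <- function(entity) {
  tab <- table(entity$atoms$element)
  out <- stats::setNames(as.integer(tab), names(tab))
  nh <- sum(entity$atoms$attached_hydrogens)
  if (nh > 0) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + nh
  out[order(names(out))]
}

.sum_formulas <- function(lst) {
  all <- sort(unique(unlist(lapply(lst, names))))
  out <- stats::setNames(integer(length(all)), all)
  for (f in lst) out[names(f)] <- out[names(f)] + f
  out
}

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)

#' Build the stoichiometric ensemble of a crystal description
#'
#' Resolves positional disorder, expands the asymmetric unit, grows entities
#' and groups symmetry-equivalent entities (identical multisets of
#' originating sites). The minimal stoichiometric grouping retains each
#' crystallographically independent entity with its multiplicity divided by
#' the overall greatest common divisor, so chemically identical but
#' crystallographically independent entities stay distinct. Partially
#' occupied sites are retained at full weight in the formula.
#'
#' @param desc A [crystal_description()].
#' @param config A [perception_config()].
#' @return An object of class `stoichiometric_ensemble` with fields
#'   `entities` (each with `atoms`, `is_polymer`, `multiplicity`), `formula`,
#'   `space_group_number`, `contains_compositional_disorder`,
#'   `contains_partial_occupancy`, `cell` and `name`.
#' @export
build_ensemble <- function(desc, config = perception_config()) {
  res <- resolve_positional_disorder(desc$sites, desc$cell)
  desc2 <- desc
  desc2$sites <- res$sites
  atoms <- expand_to_unit_cell(desc2, merge_tol = config$merge_tol)
  entities <- grow_entities(
    atoms, desc$cell,
    bond_fn = radius_bond_fn(config$tolerance, config$max_bond_cutoff),
    max_polymer_atoms = config$max_polymer_atoms)

  sig <- vapply(entities, function(e)
    paste(sort(e$atoms$site_ref), collapse = "|"), character(1))
  counts <- table(sig)
  g <- Reduce(.gcd2, as.integer(counts))
  selected <- list()
  for (s in names(counts)) {
    idx <- which(sig == s)
    # deterministic representative choice: earliest generating operators
    ord <- order(vapply(idx, function(k)
      paste(sprintf("%03d", sort(entities[[k]]$atoms$generating_op)),
            collapse = ""), character(1)))
    take <- idx[ord][seq_len(as.integer(counts[[s]]) / g)]
    for (k in take) {
      e <- entities[[k]]
      e$multiplicity <- 1L
      selected[[length(selected) + 1]] <- e
    }
  }
  formula <- .sum_formulas(lapply(selected, entity_formula))
  structure(list(
    entities = selected,
    formula = formula,
    space_group_number = desc$space_group_number,
    contains_compositional_disorder = res$contains_compositional_disorder,
    contains_partial_occupancy = res$contains_partial_occupancy,
    cell = desc$cell,
    provenance = desc$provenance,
    markup_flags = desc$markup_flags,
    declared_formula = desc$declared_formula,
    name = desc$name),
    class = "stoichiometric_ensemble")
}

#' Dump an ensemble as extended XYZ text (debug aid)
#' @param ens A `stoichiometric_ensemble`.
#' @return Character vector of XYZ lines.
#' @export
ensemble_xyz <- function(ens) {
  atoms <- do.call(rbind, lapply(seq_along(ens$entities), function(k) {
    a <- ens$entities[[k]]$atoms
    a$entity <- k
    a
  }))
  c(nrow(atoms),
    sprintf("entities=%d space_group=%s", length(ens$entities),
            ens$space_group_number),
    sprintf("%-2s %12.6f %12.6f %12.6f # entity %d site %s",
            atoms$element, atoms$x, atoms$y, atoms$z, atoms$entity,
            atoms$site_ref))
}
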