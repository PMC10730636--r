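# Step 4: aromatic and resonance structure bonds. Aromatic ring systems are
# expressed in the Kekule representation via a perfect matching on the pi
# subgraph; among feasible matchings the one minimizing the total squared
# bond-length z-score is chosen, with charge introduction penalized
# lexicographically first. Delocalized charges (cyclopentadienyl,
# cyclooctatetraenide, ...) are expressed as integer charges on
# valence-compatible ring atoms left out of the matching.

# Best squared z of a (pair, order) over all contexts; large penalty when no
# class exists for the hypothesized order.
.kekule_z2 <- function(classes, z1, z2, order, d) {
  sub <- classes[classes$Z1 == min(z1, z2) & classes$Z2 == max(z1, z2) &
                   classes$order == order, ]
  if (nrow(sub) == 0) return(1e4)
  min(((d - sub$mean) / sub$sigma)^2)
}

# Exhaustive matching enumeration over one ring system.
# verts: atom indices; edges: data.frame(row, i, j); skippable: logical per
# vertex (may be left unmatched at the price of a formal charge).
.enumerate_matchings <- function(verts, edges, skippable, edge_cost2,
                                 edge_cost1, target_skips = 0L) {
  nv <- length(verts)
  pos <- stats::setNames(seq_len(nv), verts)
  adj <- lapply(seq_len(nv), function(v) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- pos[[as.character(edges$i[e])]]
    b <- pos[[as.character(edges$j[e])]]
    adj[[a]] <- c(adj[[a]], e)
    adj[[b]] <- c(adj[[b]], e)
  }
  best <- list(cost = Inf, doubled = NULL, skipped = NULL)
  state <- rep(0L, nv)  # 0 undecided, 1 matched, 2 skipped
  doubled <- logical(nrow(edges))

  base_cost <- sum(edge_cost1)
  recurse <- function(cost) {
    v <- which(state == 0L)[1]
    if (is.na(v)) {
      total <- cost + abs(skipped_count() - target_skips) * 1e6
      if (total < best$cost) {
        best <<- list(cost = total, doubled = doubled,
                      skipped = verts[state == 2L])
      }
      return(invisible())
    }
    # try matching v through each available incident edge, ascending partner
    cand <- adj[[v]]
    partners <- vapply(cand, function(e) {
      a <- pos[[as.character(edges$i[e])]]
      b <- pos[[as.character(edges$j[e])]]
      if (a == v) b else a
    }, integer(1))
    ordc <- order(verts[partners])
    for (k in ordc) {
      e <- cand[k]
      w <- partners[k]
      if (state[w] != 0L) next
      state[v] <<- 1L; state[w] <<- 1L; doubled[e] <<- TRUE
      recurse(cost - edge_cost1[e] + edge_cost2[e])
      state[v] <<- 0L; state[w] <<- 0L; doubled[e] <<- FALSE
    }
    if (skippable[v]) {
      state[v] <<- 2L
      recurse(cost)
      state[v] <<- 0L
    }
    invisible()
  }
  skipped_count <- function() sum(state == 2L)
  recurse(base_cost)
  best
}

#' Kekulize aromatic ring systems
#'
#' Ring systems of pi-capable, sp2-compatible atoms whose bonds were left
#' ambiguous receive an alternating single/double assignment from a perfect
#' matching of the ring pi subgraph. Among feasible assignments the number of
#' introduced formal charges is minimized first, then the sum of squared
#' bond-length z-scores; ties resolve deterministically toward the lowest
#' atom index. Atoms left out of the matching receive a formal charge of -1
#' when the element admits it; all ring-system bonds are flagged as
#' delocalized.
#'
#' @inheritParams assign_unambiguous_bonds
#' @return Updated structure.
#' @export
kekulize <- function(st, classes = default_bond_classes(),
                     cfg = perception_config()) {
  rows <- .aromatic_deferred(st, cfg)
  rows <- rows[!st$bonds$resolved[rows]]
  if (length(rows) == 0) return(st)
  z <- .atom_Z(st)
  g <- igraph::graph_from_data_frame(
    data.frame(from = st$bonds$i[rows], to = st$bonds$j[rows], row = rows),
    directed = FALSE)
  comp <- igraph::components(g)
  el <- element_properties()
  for (cid in seq_len(comp$no)) {
    vnames <- as.integer(names(comp$membership)[comp$membership == cid])
    erows <- rows[st$bonds$i[rows] %in% vnames & st$bonds$j[rows] %in% vnames]
    edges <- data.frame(row = erows, i = st$bonds$i[erows],
                        j = st$bonds$j[erows])
    verts <- sort(vnames)
    skippable <- vapply(verts, function(a) {
      -1L %in% el[st$atoms$element[a], "allowed_charges"][[1]]
    }, logical(1))
    cost2 <- vapply(seq_len(nrow(edges)), function(e) {
      .kekule_z2(classes, z[edges$i[e]], z[edges$j[e]], 2L,
                 st$bonds$length[edges$row[e]])
    }, numeric(1))
    cost1 <- vapply(seq_len(nrow(edges)), function(e) {
      .kekule_z2(classes, z[edges$i[e]], z[edges$j[e]], 1L,
                 st$bonds$length[edges$row[e]])
    }, numeric(1))
    if (length(verts) > cfg$kekule_max_system) {
      # too large for exhaustive search: greedy maximal matching
      matched <- rep(FALSE, length(verts))
      names(matched) <- verts
      doubled <- logical(nrow(edges))
      for (e in order(cost2)) {
        a <- as.character(edges$i[e]); b <- as.character(edges$j[e])
        if (!matched[[a]] && !matched[[b]]) {
          matched[[a]] <- TRUE; matched[[b]] <- TRUE
          doubled[e] <- TRUE
        }
      }
      skipped <- as.integer(names(matched)[!matched])
      best <- list(doubled = doubled, skipped = skipped)
    } else {
      best <- .enumerate_matchings(verts, edges, skippable, cost2, cost1)
      if (!is.finite(best$cost)) {
        st$issues <- rbind(st$issues, issue_row(
          "pi_count", atom = verts[1], bond = NA_integer_,
          message = "no feasible Kekule assignment for ring system"))
        next
      }
    }
    st$bonds$order[edges$row] <- ifelse(best$doubled, 2L, 1L)
    st$bonds$resolved[edges$row] <- TRUE
    st$bonds$delocalized[edges$row] <- TRUE
    for (a in best$skipped) {
      st$atoms$charge[a] <- -1L
      st$atoms$charge_fixed[a] <- TRUE
    }
    st$ring_systems <- c(st$ring_systems,
                         list(list(verts = verts, edges = edges,
                                   skippable = skippable,
                                   cost2 = cost2, cost1 = cost1)))
  }
  st
}

# After formal-charge assignment: when an entity is left with a positive
# residual charge (typically metals whose smallest admissible oxidation state
# exceeds the summed ligand charge), delocalized ring systems may absorb it
# by leaving additional valence-compatible atoms out of the matching, as in
# the cyclooctatetraenide dianion convention. Ring systems are re-matched
# with the required number of charge carriers, minimizing the same squared-z
# objective.
.absorb_residual_charge <- function(st, classes, cfg) {
  if (is.null(st$ring_systems) || length(st$ring_systems) == 0) return(st)
  for (e in unique(st$atoms$entity)) {
    idx <- which(st$atoms$entity == e)
    residual <- sum(st$atoms$charge[idx])
    if (residual <= 0) next
    for (sys in st$ring_systems) {
      if (residual <= 0) break
      if (!all(sys$verts %in% idx)) next
      already <- sum(st$atoms$charge_fixed[sys$verts] &
                       st$atoms$charge[sys$verts] < 0)
      k <- already + residual
      if (length(sys$verts) > cfg$kekule_max_system) next
      best <- .enumerate_matchings(sys$verts, sys$edges, sys$skippable,
                                   sys$cost2, sys$cost1, target_skips = k)
      if (!is.finite(best$cost) || length(best$skipped) != k) next
      st$bonds$order[sys$edges$row] <- ifelse(best$doubled, 2L, 1L)
      prev <- sys$verts[st$atoms$charge_fixed[sys$verts]]
      st$atoms$charge[prev] <- 0L
      st$atoms$charge_fixed[prev] <- FALSE
      st$atoms$charge[best$skipped] <- -1L
      st$atoms$charge_fixed[best$skipped] <- TRUE
      residual <- residual - (k - already)
    }
  }
  st
}
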