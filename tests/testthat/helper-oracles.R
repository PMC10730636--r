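# Independent oracles, deliberately written as naive brute force.

# all-pairs connectivity oracle: plain double loop over the distance rule
oracle_connectivity <- function(elements, xyz, tolerance = 0.4,
                                max_bond_cutoff = 4.0) {
  n <- length(elements)
  out <- data.frame(i = integer(0), j = integer(0))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      lim <- min(covalent_radius(elements[i]) + covalent_radius(elements[j]) +
                   tolerance, max_bond_cutoff)
      if (d <= lim && d > 1e-6) out <- rbind(out, data.frame(i = i, j = j))
    }
  }
  out
}

# exhaustive enumeration of matchings of a ring-system edge list with a fixed
# number of unmatched ("skipped") vertices; returns the minimal achievable
# sum of squared z-scores
oracle_min_matching_cost <- function(verts, edges, cost2, cost1, skips = 0) {
  best <- Inf
  n_e <- nrow(edges)
  # every subset of edges; feasible matchings leave (|verts| - 2|M|) = skips
  for (mask in 0:(2^n_e - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_e) - 1)) > 0)
    used <- c(edges$i[sel], edges$j[sel])
    if (anyDuplicated(used)) next
    if (length(verts) - 2 * length(sel) != skips) next
    cost <- sum(cost2[sel]) + sum(cost1[setdiff(seq_len(n_e), sel)])
    best <- min(best, cost)
  }
  best
}

# brute-force membership of Z in the literal metal range union
oracle_is_metal <- function(z) {
  z %in% c(3:4, 11:13, 19:31, 37:51, 55:84, 87:103)
}
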