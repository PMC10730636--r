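# Shared test builders: ad-hoc molecules in large P1 boxes, so perception can
# be exercised on hand-placed geometries.

desc_from_xyz <- function(elements, xyz, attached_h = 0L, padding = 6,
                          name = "adhoc", labels = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(labels)) {
    labels <- paste0(elements, seq_along(elements))
  }
  a <- max(apply(xyz, 2, function(v) diff(range(v)))) + 2 * padding
  centre <- colMeans(apply(xyz, 2, range))
  frac <- sweep(xyz, 2, centre) / a + 0.5
  sites <- data.frame(label = labels, element = elements,
                      fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                      occupancy = 1,
                      attached_hydrogens = as.integer(attached_h),
                      stringsAsFactors = FALSE)
  crystal_description(cell = unit_cell(a, a, a), operators = list(),
                      sites = sites, space_group_number = 1L, name = name)
}

perceive_xyz <- function(elements, xyz, attached_h = 0L, ...,
                         cfg = perception_config()) {
  perceive(build_ensemble(desc_from_xyz(elements, xyz, attached_h, ...),
                          cfg), config = cfg)
}

# order of the bond between atoms a and b (NA when absent)
bond_order_between <- function(st, a, b) {
  r <- which((st$bonds$i == a & st$bonds$j == b) |
               (st$bonds$i == b & st$bonds$j == a))
  if (length(r) == 0) NA_integer_ else st$bonds$order[r]
}

# trigonal-planar sp2 carbonyl-like skeleton: center at origin, terminal
# atoms at given distances in the xy-plane
trigonal_xyz <- function(d1, d2, d3) {
  rbind(c(0, 0, 0),
        c(d1, 0, 0),
        c(d2 * cos(2 * pi / 3), d2 * sin(2 * pi / 3), 0),
        c(d3 * cos(4 * pi / 3), d3 * sin(4 * pi / 3), 0))
}
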