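test_that("expansion count equals sites x operators for general positions", {
  set.seed(7)
  ops_sets <- list(
    list(parse_symop("x,y,z")),
    list(parse_symop("x,y,z"), parse_symop("-x,-y,-z")),
    list(parse_symop("x,y,z"), parse_symop("-x,y+1/2,-z+1/2"),
         parse_symop("-x,-y,-z"), parse_symop("x,-y+1/2,z+1/2")))
  for (ops in ops_sets) {
    n_sites <- 3
    sites <- data.frame(
      label = paste0("C", 1:n_sites), element = "C",
      fx = runif(n_sites, 0.05, 0.45), fy = runif(n_sites, 0.05, 0.45),
      fz = runif(n_sites, 0.05, 0.45), stringsAsFactors = FALSE)
    desc <- crystal_description(unit_cell(10, 10, 10), ops, sites)
    atoms <- expand_to_unit_cell(desc)
    expect_equal(nrow(atoms), n_sites * length(ops))
  }
})

test_that("special-position images merge within tolerance", {
  ops <- list(parse_symop("x,y,z"), parse_symop("-x,-y,-z"))
  sites <- data.frame(label = "O1", element = "O", fx = 0, fy = 0, fz = 0,
                      stringsAsFactors = FALSE)
  desc <- crystal_description(unit_cell(10, 10, 10), ops, sites)
  expect_equal(nrow(expand_to_unit_cell(desc)), 1)
  # general position under the same operators stays doubled
  sites2 <- data.frame(label = "O1", element = "O",
                       fx = 0.21, fy = 0.33, fz = 0.4,
                       stringsAsFactors = FALSE)
  desc2 <- crystal_description(unit_cell(10, 10, 10), ops, sites2)
  expect_equal(nrow(expand_to_unit_cell(desc2)), 2)
})

test_that("positional disorder resolves by occupancy, size, then name", {
  mk <- function(groups, occs, elements = "O") {
    n <- length(groups)
    data.frame(label = paste0("O", seq_len(n)),
               element = rep_len(elements, n),
               fx = 0.5 + seq_len(n) * 0.05, fy = 0.5, fz = 0.5,
               occupancy = occs, attached_hydrogens = 0L,
               disorder_assembly = "A", disorder_group = groups,
               stringsAsFactors = FALSE)
  }
  # (1) highest summed occupancy wins
  r <- resolve_positional_disorder(mk(c("1", "2"), c(0.3, 0.7)))
  expect_equal(r$sites$disorder_group, "2")
  # (2) most atoms wins at equal summed occupancy
  s <- rbind(mk(c("1", "2"), c(0.8, 0.4)), mk("2", 0.4))
  s$label <- paste0("O", 1:3)
  r <- resolve_positional_disorder(s)
  expect_true(all(r$sites$disorder_group == "2"))
  expect_equal(nrow(r$sites), 2)
  # (3) lexicographically lesser name wins full ties
  r <- resolve_positional_disorder(mk(c("2", "1"), c(0.5, 0.5)))
  expect_equal(r$sites$disorder_group, "1")
  expect_true(r$contains_partial_occupancy)
})

test_that("shared-site different-element pairs flag compositional disorder", {
  desc <- make_defect("compositional")
  r <- resolve_positional_disorder(desc$sites, desc$cell)
  expect_true(r$contains_compositional_disorder)
  # entry stays in the output: ensemble is still built, entity retained
  ens <- build_ensemble(desc)
  expect_true(ens$contains_compositional_disorder)
  expect_gte(length(ens$entities), 1)
})

test_that("grow_entities finds isolated molecules and flags polymers", {
  ens <- build_ensemble(make_benzene())
  expect_equal(length(ens$entities), 1)
  expect_equal(nrow(ens$entities[[1]]$atoms), 12)
  expect_false(ens$entities[[1]]$is_polymer)

  ens <- build_ensemble(make_defect("polymer"))
  expect_true(any(vapply(ens$entities, `[[`, logical(1), "is_polymer")))
})

test_that("entity growth follows bonds across the cell boundary", {
  # C2H6 completed through an inversion centre: 2 atoms, one entity
  ens <- build_ensemble(make_inversion_dimer())
  expect_equal(length(ens$entities), 1)
  ent <- ens$entities[[1]]
  expect_equal(nrow(ent$atoms), 2)
  d <- sqrt(sum((as.numeric(ent$atoms[1, c("x", "y", "z")]) -
                   as.numeric(ent$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(d, 1.54, tolerance = 1e-6)
  expect_equal(ens$formula, c(C = 2L, H = 6L))
})

test_that("crystallographically independent entities stay distinct", {
  ens <- build_ensemble(make_two_waters())
  expect_equal(length(ens$entities), 2)
  expect_equal(ens$formula, c(H = 4L, O = 2L))
})

test_that("stoichiometric ratios are preserved", {
  ens <- build_ensemble(make_nacl())
  expect_equal(ens$formula, c(Cl = 1L, Na = 1L))
  # symmetry copies collapse to the minimal grouping: a benzene-like pair of
  # sites under P-1 yields one representative entity
  ops <- list(parse_symop("x,y,z"), parse_symop("-x,-y,-z"))
  sites <- data.frame(label = c("O1"), element = "O",
                      fx = 0.2, fy = 0.3, fz = 0.4,
                      occupancy = 1, attached_hydrogens = 2L,
                      stringsAsFactors = FALSE)
  desc <- crystal_description(unit_cell(12, 12, 12), ops, sites,
                              space_group_number = 2L)
  ens <- build_ensemble(desc)
  expect_equal(length(ens$entities), 1)
  expect_equal(ens$formula, c(H = 2L, O = 1L))
  expect_equal(ens$space_group_number, 2L)
})

test_that("ensemble formula is invariant under site permutation and keeps
          partial occupancy at full weight", {
  desc <- make_ferrocene()
  set.seed(3)
  perm <- sample(nrow(desc$sites))
  desc2 <- desc
  desc2$sites <- desc$sites[perm, ]
  e1 <- build_ensemble(desc)
  e2 <- build_ensemble(desc2)
  expect_equal(e1$formula, e2$formula)

  desc3 <- make_nacl()
  desc3$sites$occupancy <- c(0.5, 1)
  e3 <- build_ensemble(desc3)
  expect_equal(e3$formula, c(Cl = 1L, Na = 1L))  # full weight
  expect_true(e3$contains_partial_occupancy)
})
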