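# structure with one assigned bond and explicit geometry, for check units
two_atom_structure <- function(e1, e2, d, order = 1L, delocalized = FALSE) {
  st <- chemical_structure(
    data.frame(element = c(e1, e2), x = c(0, d), y = 0, z = 0))
  st$bonds <- data.frame(i = 1L, j = 2L, order = order, resolved = TRUE,
                         delocalized = delocalized, length = d)
  st
}

test_that("pi count check compares factual against geometry-expected values", {
  # sp3-like carbon (4 sigma neighbours) carrying a double bond: flagged
  xyz <- rbind(c(0, 0, 0), c(1.33, 0, 0))
  st <- chemical_structure(
    data.frame(element = c("C", "C"), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               attached_hydrogens = c(3L, 3L)))
  st$bonds <- data.frame(i = 1L, j = 2L, order = 2L, resolved = TRUE,
                         delocalized = FALSE, length = 1.33)
  iss <- check_pi_count(st)
  expect_equal(nrow(iss), 2)  # both carbons have 4 total neighbours
  expect_true(all(iss$category == "pi_count"))

  # benzene carbon: factual 1 (delocalized), expected admits 1
  st <- perceive(build_ensemble(make_benzene()))
  expect_equal(nrow(check_pi_count(st)), 0)

  # metal atoms are outside the checked element list
  st <- perceive(build_ensemble(make_ferrocene()))
  expect_equal(nrow(check_pi_count(st)), 0)
})

test_that("bond geometry check flags twisted doubles, ignores length", {
  mk_twist <- function(twist_deg) {
    phi <- twist_deg * pi / 180
    d <- 1.50
    s120 <- sin(120 * pi / 180); c120 <- cos(120 * pi / 180)
    c2 <- c(1.33, 0, 0)
    # substituents of atom 2 rotated about the bond axis by the twist
    q <- function(sgn) {
      y <- sgn * s120
      c2 + d * c(-c120, y * cos(phi), y * sin(phi))
    }
    xyz <- rbind(c(0, 0, 0), c2,
                 d * c(c120, s120, 0), d * c(c120, -s120, 0),
                 q(1), q(-1))
    st <- chemical_structure(
      data.frame(element = rep("C", 6), x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3], attached_hydrogens = c(0L, 0L, 3L, 3L, 3L, 3L)))
    st$bonds <- data.frame(
      i = c(1L, 1L, 1L, 2L, 2L), j = c(2L, 3L, 4L, 5L, 6L),
      order = c(2L, 1L, 1L, 1L, 1L), resolved = TRUE, delocalized = FALSE,
      length = c(1.33, d, d, d, d))
    st
  }
  expect_equal(nrow(check_bond_geometry(mk_twist(2))), 0)
  iss <- check_bond_geometry(mk_twist(40))
  expect_equal(nrow(iss), 1)
  expect_equal(iss$category, "bond_geometry")
  # single bonds are never flagged regardless of geometry
  st <- mk_twist(40)
  st$bonds$order[1] <- 1L
  expect_equal(nrow(check_bond_geometry(st)), 0)
})

test_that("bond length check needs both a 3-sigma deviation and a better
          alternative", {
  header <- "atom1\tatom2\torder\tpi1\tpi2\tmean\tsigma\tcount"
  with_alt <- load_bond_classes(withr::local_tempfile(lines = c(
    header,
    "C\tC\t1\t0\t0\t1.54\t0.02\t10",
    "C\tC\t2\t1\t1\t1.62\t0.02\t10")))
  no_alt <- load_bond_classes(withr::local_tempfile(lines = c(
    header,
    "C\tC\t1\t0\t0\t1.54\t0.02\t10")))

  # at the mean: no issue
  expect_equal(nrow(check_bond_length(two_atom_structure("C", "C", 1.54),
                                      with_alt)), 0)
  # z = 3.0 exactly: within the three-sigma range, no issue
  expect_equal(nrow(check_bond_length(two_atom_structure("C", "C", 1.60),
                                      with_alt)), 0)
  # z = 3.5 with a better-fitting order-2 class: flagged
  iss <- check_bond_length(two_atom_structure("C", "C", 1.61), with_alt)
  expect_equal(nrow(iss), 1)
  expect_equal(iss$category, "bond_length")
  # z = 3.5 but no alternative: not flagged
  expect_equal(nrow(check_bond_length(two_atom_structure("C", "C", 1.61),
                                      no_alt)), 0)
})

test_that("bond length flag rate is monotone as the threshold tightens", {
  header <- "atom1\tatom2\torder\tpi1\tpi2\tmean\tsigma\tcount"
  cls <- load_bond_classes(withr::local_tempfile(lines = c(
    header,
    "C\tC\t1\t0\t0\t1.50\t0.02\t10",
    "C\tC\t2\t1\t1\t1.40\t0.02\t10")))
  set.seed(42)
  lengths <- 1.50 + stats::rnorm(40, sd = 0.05)
  lengths <- lengths[lengths > 1.2]
  rate <- function(thr) {
    cfg <- perception_config(sigma_threshold = thr)
    sum(vapply(lengths, function(d) {
      nrow(check_bond_length(two_atom_structure("C", "C", d), cls, cfg))
    }, numeric(1)))
  }
  rates <- vapply(c(4, 3, 2, 1, 0.5), rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("radical and charge checks", {
  st <- perceive_xyz("C", rbind(c(0, 0, 0)), attached_h = 3L)
  expect_equal(check_radicals(st)$category, "radical")
  st <- perceive(build_ensemble(make_two_waters()))
  expect_equal(nrow(check_radicals(st)), 0)

  # NO-like odd-electron diatomic
  st <- perceive_xyz(c("N", "O"), rbind(c(0, 0, 0), c(1.21, 0, 0)))
  expect_equal(nrow(check_radicals(st)), 1)

  st <- perceive(build_ensemble(make_ferrocene()))
  expect_equal(nrow(check_atom_charges(st)), 0)  # Fe 2+ is enumerated
  st$atoms$charge[st$atoms$element == "Fe"] <- 9L
  expect_equal(nrow(check_atom_charges(st)), 1)
  st2 <- two_atom_structure("C", "C", 1.54)
  st2$atoms$charge[1] <- -5L
  expect_equal(check_atom_charges(st2)$category, "atom_charge")
  # O 1- (carboxylate-like) is within the valence-derived set
  st3 <- two_atom_structure("C", "O", 1.30)
  st3$atoms$charge[2] <- -1L
  st3$atoms$charge[1] <- 1L
  expect_equal(nrow(check_atom_charges(st3)), 0)
})

test_that("ensemble charge check", {
  st <- perceive(build_ensemble(make_nacl()))
  expect_equal(nrow(check_ensemble_charge(st)), 0)
  st <- perceive(build_ensemble(make_ferrocene()))
  expect_equal(nrow(check_ensemble_charge(st)), 0)
  lone <- two_atom_structure("Na", "Cl", 2.8, order = 0L)
  lone$atoms$charge <- c(0L, -1L)
  expect_equal(check_ensemble_charge(lone)$category, "ensemble_charge")
})

test_that("formula compatibility is exact multiplication", {
  expect_true(formula_compatible(parse_formula("C6 H12 O6"),
                                 parse_formula("C12 H24 O12")))
  f <- parse_formula("C6 H12 O6")
  expect_true(formula_compatible(f, f))
  expect_false(formula_compatible(parse_formula("C6 H12 O6"),
                                  parse_formula("C6 H12 O5")))
  expect_false(formula_compatible(parse_formula("C6 H12 O6"),
                                  parse_formula("C9 H18 O9")))  # k = 1.5
  # randomized property: f vs k*f compatible for all k >= 1, and the
  # declared formula is never a multiple of a smaller computed one
  set.seed(5)
  for (rep in 1:20) {
    els <- sample(c("C", "H", "N", "O", "S"), sample(2:4, 1))
    f <- stats::setNames(sample(1:20, length(els)), els)
    k <- sample(1:5, 1)
    expect_true(formula_compatible(f, k * f))
    if (k > 1) expect_false(formula_compatible(k * f, f))
  }
})

test_that("judge_entry applies the six criteria and marks, never drops", {
  ens <- build_ensemble(make_benzene())
  st <- perceive(ens)
  v <- judge_entry(st$issues, ens)
  expect_true(v$overall_valid)
  expect_equal(length(v$criteria), 6)

  # a single formula mismatch fails exactly one criterion
  ens2 <- ens
  ens2$declared_formula <- c(C = 6L, H = 5L)
  v2 <- judge_entry(st$issues, ens2)
  expect_false(v2$overall_valid)
  expect_equal(sum(!v2$criteria), 1)
  expect_false(v2$criteria[["chemical_formula"]])

  # compositional disorder fixture fails that criterion but stays judged
  ens3 <- build_ensemble(make_defect("compositional"))
  st3 <- perceive(ens3)
  v3 <- judge_entry(st3$issues, ens3)
  expect_false(v3$criteria[["compositional_disorder"]])

  # markup flags map to cod_markup / manual_review
  ens4 <- ens
  ens4$markup_flags <- c("duplicate", "manual-exclusion")
  v4 <- judge_entry(st$issues, ens4)
  expect_false(v4$criteria[["cod_markup"]])
  expect_false(v4$criteria[["manual_review"]])

  # provenance: DOI or journal+year suffices
  ens5 <- ens
  ens5$provenance <- list(doi = NULL, journal = "Acta", year = 1999)
  expect_true(judge_entry(st$issues, ens5)$criteria[["data_provenance"]])
  ens5$provenance <- list()
  expect_false(judge_entry(st$issues, ens5)$criteria[["data_provenance"]])
})
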