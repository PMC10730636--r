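all_fixture_descs <- function() {
  list(benzene = make_benzene(), ferrocene = make_ferrocene(),
       azide_sym = make_azide(1.24, 1.24), azide_asym = make_azide(1.35, 1.13),
       nacl = make_nacl(), cot = make_cot_salt(),
       two_waters = make_two_waters(), dimer = make_inversion_dimer())
}

test_that("connectivity equals the brute-force all-pairs oracle on every fixture", {
  for (nm in names(all_fixture_descs())) {
    ens <- build_ensemble(all_fixture_descs()[[nm]])
    atoms <- do.call(rbind, lapply(ens$entities, function(e)
      e$atoms[, c("element", "x", "y", "z")]))
    got <- detect_connectivity(atoms)
    want <- oracle_connectivity(atoms$element,
                                as.matrix(atoms[, c("x", "y", "z")]))
    expect_equal(got[, c("i", "j")], want, label = nm,
                 ignore_attr = "row.names")
    expect_true(all(got$order == 1L) && all(!got$resolved), label = nm)
    # bond lengths equal endpoint distances
    for (b in seq_len(nrow(got))) {
      d <- sqrt(sum((as.numeric(atoms[got$i[b], c("x", "y", "z")]) -
                       as.numeric(atoms[got$j[b], c("x", "y", "z")]))^2))
      expect_equal(got$length[b], d, tolerance = 1e-12)
    }
  }
  # simple distance cases
  two_c <- data.frame(element = "C", x = c(0, 1.54), y = 0, z = 0)
  expect_equal(nrow(detect_connectivity(two_c)), 1)
  two_c$x[2] <- 4.0
  expect_equal(nrow(detect_connectivity(two_c)), 0)
})

test_that("preflight screens bumps and exceeded valence", {
  st <- chemical_structure(
    data.frame(element = c("C", "C"), x = c(0, 0.5), y = 0, z = 0))
  st$bonds <- detect_connectivity(st$atoms)
  def <- preflight_screen(st)
  expect_true(any(def$kind == "clash"))

  r <- tryCatch(perceive(build_ensemble(make_defect("overvalence"))),
                error = identity)
  expect_s3_class(r, "cifchem_preflight_error")
  expect_true(any(attr(r, "defects")$kind == "overvalence"))

  st <- perceive(build_ensemble(make_benzene()))  # clean structure passes
  expect_equal(nrow(preflight_screen(st)), 0)
})

test_that("all metal-incident bonds become zero-order; hapticity is complete", {
  st <- perceive(build_ensemble(make_ferrocene()))
  fe <- which(st$atoms$element == "Fe")
  fe_bonds <- st$bonds[st$bonds$i == fe | st$bonds$j == fe, ]
  expect_equal(nrow(fe_bonds), 10)           # bound to all 10 ring carbons
  expect_true(all(fe_bonds$order == 0L))
  partners <- setdiff(c(fe_bonds$i, fe_bonds$j), fe)
  expect_true(all(st$atoms$element[partners] == "C"))

  # global convention: no order-1+ bond ever touches a metal
  el <- element_properties()
  for (nm in names(all_fixture_descs())) {
    r <- tryCatch(perceive(build_ensemble(all_fixture_descs()[[nm]])),
                  error = identity)
    if (inherits(r, "error")) next
    metal <- el[r$atoms$element, "is_metal"]
    touching <- metal[r$bonds$i] | metal[r$bonds$j]
    expect_true(all(r$bonds$order[touching] == 0L), label = nm)
  }

  # benzene unchanged: no metals
  st <- perceive(build_ensemble(make_benzene()))
  expect_false(any(st$bonds$order == 0L))
})

test_that("unambiguous orders: carbonyl, alkane, nitrile", {
  # formaldehyde-like: C=O at 1.22 with two explicit H
  st <- perceive_xyz(c("C", "O", "H", "H"), trigonal_xyz(1.22, 1.09, 1.09))
  expect_equal(bond_order_between(st, 1, 2), 2L)
  expect_equal(sum(st$atoms$charge), 0)

  # ethane-like C-C at 1.54, sp3 carbons
  st <- perceive_xyz(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                     attached_h = c(3L, 3L))
  expect_equal(bond_order_between(st, 1, 2), 1L)

  # acetonitrile-like C#N at 1.16, linear
  st <- perceive_xyz(c("C", "C", "N"),
                     rbind(c(0, 0, 0), c(1.47, 0, 0), c(1.47 + 1.16, 0, 0)),
                     attached_h = c(3L, 0L, 0L))
  expect_equal(bond_order_between(st, 2, 3), 3L)
  expect_equal(sum(st$atoms$charge), 0)
  expect_equal(nrow(st$issues), 0)
})

test_that("azide duality follows the observed bond lengths", {
  st <- perceive(build_ensemble(make_azide(1.24, 1.24)))
  n <- which(st$atoms$element == "N")
  orders <- sort(c(bond_order_between(st, n[1], n[2]),
                   bond_order_between(st, n[2], n[3])))
  expect_equal(orders, c(2L, 2L))

  st <- perceive(build_ensemble(make_azide(1.35, 1.13)))
  n <- which(st$atoms$element == "N")
  expect_equal(bond_order_between(st, n[1], n[2]), 1L)
  expect_equal(bond_order_between(st, n[2], n[3]), 3L)
  # both forms balance: azide -1, counterion +1
  expect_equal(sum(st$atoms$charge), 0)
})

test_that("nitro-like groups get one double, one single and a charge split", {
  # nitromethane-like: C-N plus two terminal O at equal 1.22
  xyz <- rbind(trigonal_xyz(1.47, 1.22, 1.22)[c(2, 1, 3, 4), ])
  st <- perceive_xyz(c("C", "N", "O", "O"), xyz, attached_h = c(3L, 0, 0, 0))
  o_orders <- sort(c(bond_order_between(st, 2, 3), bond_order_between(st, 2, 4)))
  expect_equal(o_orders, c(1L, 2L))
  expect_equal(st$atoms$charge[2], 1L)
  expect_equal(sort(st$atoms$charge[3:4]), c(-1L, 0L))
  expect_equal(sum(st$atoms$charge), 0)
})

test_that("kekulize produces valid minimal matchings (exhaustive oracle)", {
  cfg <- perception_config()
  classes <- default_bond_classes()
  for (desc in list(make_benzene(), make_ferrocene(), make_cot_salt())) {
    st <- perceive(build_ensemble(desc))
    for (sys in st$ring_systems) {
      edges <- sys$edges
      orders <- st$bonds$order[edges$row]
      # valid matching: each ring atom has at most one incident double bond
      dbl <- edges[orders == 2L, ]
      expect_false(anyDuplicated(c(dbl$i, dbl$j)) > 0)
      # every matched-or-charged accounting is complete
      matched <- unique(c(dbl$i, dbl$j))
      skipped <- setdiff(sys$verts, matched)
      expect_true(all(st$atoms$charge[skipped] == -1L))
      # minimality of the squared-z objective at the realized skip count
      cost <- sum(sys$cost2[orders == 2L]) + sum(sys$cost1[orders == 1L])
      want <- oracle_min_matching_cost(sys$verts, edges, sys$cost2, sys$cost1,
                                       skips = length(skipped))
      expect_equal(cost, want, tolerance = 1e-9, label = desc$name)
    }
  }
})

test_that("benzene kekulizes to alternating orders deterministically", {
  st1 <- perceive(build_ensemble(make_benzene()))
  st2 <- perceive(build_ensemble(make_benzene()))
  expect_identical(st1$bonds, st2$bonds)
  ring <- st1$bonds[st1$bonds$delocalized, ]
  expect_equal(sort(ring$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(all(st1$atoms$charge == 0L))
})

test_that("cyclopentadienyl rings carry exactly one carbanion each", {
  st <- perceive(build_ensemble(make_ferrocene()))
  expect_equal(st$atoms$charge[st$atoms$element == "Fe"], 2L)
  charged_c <- which(st$atoms$element == "C" & st$atoms$charge == -1L)
  expect_equal(length(charged_c), 2)  # one per ring
  expect_equal(length(st$ring_systems), 2)
  for (sys in st$ring_systems) {
    expect_equal(sum(charged_c %in% sys$verts), 1)
    orders <- st$bonds$order[sys$edges$row]
    expect_equal(sort(orders), c(1L, 1L, 1L, 2L, 2L))
  }
  expect_equal(sum(st$atoms$charge), 0)
})

test_that("delocalized even rings absorb residual charge from alkali ions", {
  st <- perceive(build_ensemble(make_cot_salt()))
  expect_equal(sum(st$atoms$charge[st$atoms$element == "K"]), 2L)
  expect_equal(sum(st$atoms$charge[st$atoms$element == "C"] == -1L), 2)
  expect_equal(sum(st$atoms$charge), 0)
  expect_equal(nrow(st$issues), 0)
})

test_that("deviant geometry still receives higher orders from length ranking", {
  # pyramidalized alkene: C=C at 1.36 with both substituents of each carbon
  # lifted 15 degrees out of the double-bond plane (same side: pyramidal)
  phi <- 15 * pi / 180
  d <- 1.50
  s120 <- sin(120 * pi / 180); c120 <- cos(120 * pi / 180)
  p_plus <- d * c(c120, s120 * cos(phi), s120 * sin(phi))
  p_minus <- d * c(c120, -s120 * cos(phi), s120 * sin(phi))
  c2 <- c(1.36, 0, 0)
  xyz <- rbind(c(0, 0, 0), c2, p_plus, p_minus, c2 - p_plus, c2 - p_minus)
  st <- perceive_xyz(rep("C", 6), xyz, attached_h = c(0, 0, 3, 3, 3, 3))
  expect_equal(bond_order_between(st, 1, 2), 2L)
  # ... via the deviant step: the geometry gate classifies C1 as pyramidal
  st0 <- chemical_structure(st$atoms, st$bonds)
  expect_equal(atom_geometry(st0, 1), "sp3")

  # plain single bond unchanged; assigned orders never overridden
  st <- perceive_xyz(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                     attached_h = c(3L, 3L))
  st2 <- assign_deviant_bonds(st)
  expect_identical(st2$bonds$order, st$bonds$order)
})

test_that("formal charges: water, halide pairs, hydride and radicals", {
  st <- perceive(build_ensemble(make_two_waters()))
  expect_true(all(st$atoms$charge == 0L))

  st <- perceive(build_ensemble(make_nacl()))
  expect_equal(st$atoms$charge[st$atoms$element == "Cl"], -1L)
  expect_equal(st$atoms$charge[st$atoms$element == "Na"], 1L)

  # methyl radical: carbon deficit with no anion route
  st <- perceive_xyz("C", rbind(c(0, 0, 0)), attached_h = 3L)
  expect_true(st$atoms$radical[1])
  expect_equal(st$atoms$charge[1], 0L)

  # metal-coordinated carbene carbon takes the full deficit as 2-
  xyz <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  st <- perceive_xyz(c("Ir", "C"), xyz, attached_h = c(0L, 2L))
  expect_equal(st$atoms$charge[2], -2L)
  expect_equal(st$atoms$charge[1], 2L)
  expect_equal(sum(st$atoms$charge), 0)
})

test_that("perceive is idempotent and deterministic", {
  for (desc in list(make_benzene(), make_ferrocene(), make_azide(1.35, 1.13))) {
    st <- perceive(build_ensemble(desc))
    # rebuild a crystal description from the perceived geometry
    xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
    desc2 <- desc_from_xyz(st$atoms$element, xyz,
                           attached_h = st$atoms$attached_hydrogens,
                           name = desc$name)
    st2 <- perceive(build_ensemble(desc2))
    expect_equal(sort(st2$bonds$order), sort(st$bonds$order), label = desc$name)
    expect_equal(sort(st2$atoms$charge), sort(st$atoms$charge),
                 label = desc$name)
    expect_identical(to_smiles(st2, "crystal"), to_smiles(st, "crystal"),
                     label = desc$name)
  }
})

test_that("neutral fixtures sum to zero formal charge", {
  for (nm in names(all_fixture_descs())) {
    r <- tryCatch(perceive(build_ensemble(all_fixture_descs()[[nm]])),
                  error = identity)
    if (inherits(r, "error")) next
    expect_equal(sum(r$atoms$charge), 0, label = nm)
  }
})

test_that("polymeric input is rejected with an explicit error", {
  ens <- build_ensemble(make_defect("polymer"))
  expect_error(perceive(ens), "polymer", class = "cifchem_polymer_error")
})
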