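# a long saturated chain built directly as a structure (n atoms, n-1 bonds)
chain_structure <- function(n) {
  atoms <- data.frame(element = rep("C", n),
                      x = 1.54 * seq_len(n), y = 0, z = 0,
                      attached_hydrogens = 2L)
  st <- chemical_structure(atoms)
  st$bonds <- data.frame(i = seq_len(n - 1), j = 2:n, order = 1L,
                         resolved = TRUE, delocalized = FALSE, length = 1.54)
  st
}

test_that("V2000 writes water and enforces the 999-atom/bond limit", {
  st <- perceive(build_ensemble(make_two_waters()))
  # make a single explicit water instead: O with two positioned H
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  stw <- perceive_xyz(c("O", "H", "H"), xyz)
  txt <- write_molfile_v2000(stw, "water")
  p <- parse_v2000(txt)
  expect_equal(p$natoms, 3)
  expect_equal(p$nbonds, 2)
  expect_true(all(p$bonds$type == 1))

  big <- chain_structure(1000)
  expect_error(write_molfile_v2000(big), "999")
  expect_no_error(write_molfile_v3000(big))
})

test_that("V2000 round-trips through an independent parser", {
  for (desc in list(make_ferrocene(), make_azide(1.35, 1.13),
                    make_benzene(), make_cot_salt())) {
    st <- perceive(build_ensemble(desc))
    p <- parse_v2000(write_molfile_v2000(st, desc$name))
    expect_equal(p$natoms, nrow(st$atoms), label = desc$name)
    expect_equal(p$nbonds, nrow(st$bonds), label = desc$name)
    expect_equal(p$elements, st$atoms$element, label = desc$name)
    expect_equal(p$charges, as.integer(st$atoms$charge), label = desc$name)
    # type 8 <-> order 0, other orders carried through exactly
    want <- ifelse(st$bonds$order == 0L, 8L, st$bonds$order)
    expect_equal(p$bonds$type, want, label = desc$name)
    expect_equal(p$bonds$i, st$bonds$i)
    expect_equal(p$bonds$j, st$bonds$j)
    expect_equal(unname(p$xyz), unname(as.matrix(st$atoms[, c("x", "y", "z")])),
                 tolerance = 1e-4)
  }
})

test_that("V3000 uses bond type 9 for coordination bonds", {
  st <- perceive(build_ensemble(make_ferrocene()))
  p <- parse_v3000(write_molfile_v3000(st, "ferrocene"))
  expect_equal(sum(p$bonds$type == 9), 10)
  expect_equal(p$charges[p$elements == "Fe"], 2L)
  expect_equal(sum(p$charges == -1L), 2)

  stw <- perceive_xyz(c("O", "H", "H"),
                      rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  pw <- parse_v3000(write_molfile_v3000(stw))
  expect_true(all(pw$bonds$type == 1))
})

test_that("SDF records carry validity and issues and keep input order", {
  ens <- build_ensemble(make_benzene())
  st <- perceive(ens)
  rec <- sdf_record(st, judge_entry(st$issues, ens))
  txt <- write_sdf(list(rec))
  expect_equal(length(gregexpr("\\$\\$\\$\\$", txt)[[1]]), 1)
  expect_match(txt, "> <COD_SDF_VALIDITY_STATUS>\nvalid", fixed = TRUE)
  expect_match(txt, "> <COD_SDF_ISSUES>", fixed = TRUE)

  # invalid entries are present with a failing status, not omitted
  ens2 <- ens
  ens2$markup_flags <- "duplicate"
  rec2 <- sdf_record(st, judge_entry(st$issues, ens2))
  txt2 <- write_sdf(list(rec, rec2))
  blocks <- strsplit(txt2, "\\$\\$\\$\\$")[[1]]
  expect_equal(length(blocks) - 1, 2)
  expect_match(blocks[2], "invalid: cod_markup")
})

test_that("TSV modes share an identical body", {
  mk_entry <- function(desc) {
    ens <- build_ensemble(desc)
    st <- perceive(ens)
    list(id = ens$name, structure = st,
         verdict = judge_entry(st$issues, ens))
  }
  entries <- list(mk_entry(make_benzene()), mk_entry(make_nacl()))
  plain <- write_tsv(entries, "plain")
  header <- write_tsv(entries, "header")
  dwar <- write_tsv(entries, "dwar")
  expect_true(endsWith(header, plain))
  expect_true(endsWith(dwar, plain))
  expect_match(header, "C1-Problems\tIs valid entry")
  expect_match(dwar, "<datawarrior-fileinfo>", fixed = TRUE)
  # header-only output for empty input
  expect_equal(write_tsv(list(), "header"),
               "Identifier\tSmiles\tC1-Problems\tIs valid entry\n")
  # issue lists land in C1-Problems
  st <- entries[[1]]$structure
  st$issues <- rbind(issue_row("radical", atom = 1, message = "a"),
                     issue_row("atom_charge", atom = 2, message = "b"))
  row <- write_tsv(list(list(id = "x", structure = st,
                             verdict = list(overall_valid = FALSE))), "plain")
  expect_match(row, "radical: a; atom_charge: b")
})

test_that("strip_coordination_bonds separates or fuses ligands", {
  st <- perceive(build_ensemble(make_ferrocene()))
  ncomp <- function(s) {
    if (nrow(s$bonds) == 0) return(nrow(s$atoms))
    g <- igraph::graph_from_data_frame(
      data.frame(from = s$bonds$i, to = s$bonds$j), directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(s$atoms))))
    igraph::components(g)$no
  }
  expect_equal(ncomp(strip_coordination_bonds(st, "remove")), 3)
  expect_equal(ncomp(strip_coordination_bonds(st, "to_single")), 1)
  stb <- perceive(build_ensemble(make_benzene()))
  expect_identical(strip_coordination_bonds(stb, "remove")$bonds, stb$bonds)
  expect_identical(strip_coordination_bonds(stb, "to_single")$bonds, stb$bonds)
})

test_that("SMILES scopes: crystal, components, ligands", {
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  stw <- perceive_xyz(c("O", "H", "H"), xyz)
  expect_equal(to_smiles(stw, "components"), "O")

  st <- perceive(build_ensemble(make_ferrocene()))
  lig <- to_smiles(st, "ligands")
  expect_equal(length(lig), 3)  # two ring anions plus the iron cation
  expect_equal(sum(lig == "[Fe+2]"), 1)
  expect_equal(sum(grepl("CH-", lig, fixed = TRUE)), 2)
  # ligand-scope string count equals the component count after removal
  stripped <- strip_coordination_bonds(st, "remove")
  g <- igraph::graph_from_data_frame(
    data.frame(from = stripped$bonds$i, to = stripped$bonds$j),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(st$atoms))))
  expect_equal(length(lig), igraph::components(g)$no)

  # two-entity crystal: crystal scope is one dot-joined string
  st2 <- perceive(build_ensemble(make_two_waters()))
  expect_equal(to_smiles(st2, "crystal"), "O.O")
  expect_equal(length(to_smiles(st2, "components")), 2)
})

test_that("writers are pure: identical inputs give byte-identical output", {
  st1 <- perceive(build_ensemble(make_ferrocene()))
  st2 <- perceive(build_ensemble(make_ferrocene()))
  expect_identical(write_molfile_v2000(st1), write_molfile_v2000(st2))
  expect_identical(write_molfile_v3000(st1), write_molfile_v3000(st2))
  expect_identical(to_smiles(st1, "crystal"), to_smiles(st2, "crystal"))
})
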