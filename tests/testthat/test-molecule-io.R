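# SMILES parsing, charge/multiplicity assignment, stereoisomer enumeration,
# atom mapping and XYZ round trips.

test_that("parse_smiles recovers heavy atoms, charges and aromaticity", {
  g <- parse_smiles("CCI")
  expect_equal(n_heavy_atoms(g), 3)
  expect_setequal(g$atoms$element, c("C", "I"))
  expect_equal(g$total_charge, 0)

  phenolate <- parse_smiles("[O-]c1ccccc1")
  expect_equal(phenolate$total_charge, -1)
  expect_equal(sum(phenolate$atoms$charge), -1)

  phenol <- parse_smiles("Oc1ccccc1")
  expect_equal(n_heavy_atoms(phenol), 7)
  aromatic_bonds <- phenol$bonds[phenol$bonds$order == 1.5, ]
  expect_equal(nrow(aromatic_bonds), 6)  # one aromatic ring of size 6
  ring_atoms <- unique(c(aromatic_bonds$i, aromatic_bonds$j))
  expect_length(ring_atoms, 6)
})

test_that("parse errors report the offending position", {
  err <- tryCatch(parse_smiles("CC(C"), error = identity)
  expect_match(conditionMessage(err), "unmatched")
  err <- tryCatch(parse_smiles("CCXC"), error = identity)
  expect_match(conditionMessage(err), "position 3")
})

test_that("implicit hydrogen assignment follows default valences", {
  expect_equal(parse_smiles("C")$atoms$implicit_h, 4L)
  expect_equal(parse_smiles("I")$atoms$implicit_h, 1L)     # hydrogen iodide
  expect_equal(parse_smiles("Oc1ccccc1")$atoms$implicit_h,
               c(1L, 0L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(parse_smiles("[CH3]")$atoms$implicit_h, 3L)
  expect_equal(sum(parse_smiles("O=S(=O)=O")$atoms$implicit_h), 0L)
})

test_that("multiplicity follows the electron-parity rule", {
  expect_equal(guess_multiplicity(parse_smiles("Oc1ccccc1")), 1L)   # 50 e
  expect_equal(electron_count(parse_smiles("Oc1ccccc1")), 50L)
  expect_equal(guess_multiplicity(parse_smiles("[CH3]")), 2L)       # 9 e
  expect_equal(electron_count(parse_smiles("[CH3]")), 9L)
  expect_equal(guess_multiplicity(parse_smiles("[O-]c1ccccc1")), 1L)
  expect_equal(electron_count(parse_smiles("[O-]c1ccccc1")), 50L)
})

test_that("different SMILES spellings of one molecule share a connectivity key", {
  spellings <- list(
    c("Oc1ccccc1", "c1ccc(O)cc1", "c1cc(O)ccc1"),
    c("CCO", "OCC", "C(O)C"),
    c("CCI", "ICC"),
    c("CC(=O)Cl", "ClC(C)=O")
  )
  for (group in spellings) {
    keys <- vapply(group, function(s) connectivity_key(parse_smiles(s)),
                   character(1))
    expect_length(unique(keys), 1)
  }
  # distinct molecules never collide
  distinct <- c("Oc1ccccc1", "[O-]c1ccccc1", "CCO", "COC", "CCI", "CCC")
  keys <- vapply(distinct, function(s) connectivity_key(parse_smiles(s)),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("stereoisomer enumeration counts 2^k over unspecified elements", {
  expect_length(enumerate_stereoisomers(parse_smiles("CCI")), 1)
  expect_length(enumerate_stereoisomers(parse_smiles("CC(F)Cl")), 2)
  expect_length(enumerate_stereoisomers(parse_smiles("FC=CF")), 2)
  # specified centers are untouched
  expect_length(enumerate_stereoisomers(parse_smiles("F[C@H](Cl)C")), 1)
  # two independent elements combine multiplicatively
  expect_length(enumerate_stereoisomers(parse_smiles("CC(F)C(Cl)Br")), 4)
  isos <- enumerate_stereoisomers(parse_smiles("FC=CF"))
  geoms <- vapply(isos, function(g) g$bonds$geom[g$bonds$order == 2],
                  character(1))
  expect_setequal(geoms, c("E", "Z"))
})

test_that("derive_mapping isolates the changing atoms of the ether synthesis", {
  m <- derive_mapping(williamson_mapped_smiles())
  # ether O (4), attacked ethyl C (2), leaving iodine (3); ring spectates
  expect_setequal(m$changed_atoms, c(2L, 3L, 4L))
  expect_false(any(5:10 %in% m$changed_atoms))
  expect_equal(nrow(m$formed_bonds), 1)
  expect_setequal(as.integer(m$formed_bonds[1, ]), c(2L, 4L))
  expect_setequal(as.integer(m$broken_bonds[1, ]), c(2L, 3L))
})

test_that("changed atoms are symmetric under reaction reversal and empty for identity", {
  fwd <- williamson_mapped_smiles()
  parts <- strsplit(fwd, ">>", fixed = TRUE)[[1]]
  rev <- paste0(parts[2], ">>", parts[1])
  expect_equal(derive_mapping(fwd)$changed_atoms,
               derive_mapping(rev)$changed_atoms)

  ident <- "[CH3:1][CH2:2][I:3]>>[CH3:1][CH2:2][I:3]"
  expect_length(derive_mapping(ident)$changed_atoms, 0)
})

test_that("non-bijective mappings are rejected", {
  expect_error(derive_mapping("[CH3:1]C.[CH3:1]C>>[CH4:1]"), "non-bijective")
})

test_that("XYZ files round-trip coordinates to 1e-6 Angstrom", {
  s <- embed_3d(parse_smiles("CCO"), seed = 5)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, path)
  back <- read_xyz(path)
  expect_equal(back$elements, s$graph$atoms$element)
  expect_lt(max(abs(back$coords - s$coords)), 1e-6)
  expect_match(back$comment, "charge=0")
})

test_that("embedding is deterministic, clash-free and makes hydrogens explicit", {
  g <- parse_smiles("C")
  s1 <- embed_3d(g, seed = 42)
  expect_equal(nrow(s1$coords), 5)  # CH4
  expect_gte(min(dist(s1$coords)), 0.5)
  s2 <- embed_3d(g, seed = 42)
  expect_identical(s1$coords, s2$coords)
  s3 <- embed_3d(g, seed = 43)
  expect_false(identical(s1$coords, s3$coords))

  bigger <- embed_3d(parse_smiles("CCOc1ccccc1"), seed = 7)
  expect_gte(min(dist(bigger$coords)), 0.5)
})

test_that("the clash repairer separates overlapping atoms to d_min", {
  clash <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(3, 0, 0))
  fixed <- repair_clashes(clash, d_min = 0.5)
  expect_gte(min(dist(fixed)), 0.5)
  # deterministic
  expect_identical(fixed, repair_clashes(clash, d_min = 0.5))
  # untouched when already clean
  clean <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_identical(repair_clashes(clean), clean)
})

test_that("structure invariants reject clashes and inconsistent spin parity", {
  g <- parse_smiles("CC")
  expect_error(qc_structure(g, matrix(0, 8, 3)), "minimum interatomic distance")
  s <- embed_3d(g, seed = 1)
  expect_error(qc_structure(g, s$coords, multiplicity = 2),
               "incompatible with multiplicity")
  expect_silent(validate_structure(embed_3d(parse_smiles("[CH3]"), seed = 1)))
  expect_equal(embed_3d(parse_smiles("[CH3]"), seed = 1)$multiplicity, 2L)
})
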