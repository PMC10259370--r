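# Constrained bimolecular trial enumeration and mapping-based pruning.

test_that("reactive atoms default to all non-hydrogens", {
  iodoethane <- embed_3d(parse_smiles("CCI"), 1)
  phenol <- embed_3d(parse_smiles("Oc1ccccc1"), 2)
  expect_equal(reactive_atoms(iodoethane), 1:3)
  expect_length(reactive_atoms(phenol), 7)
})

test_that("a mapping restricts reactive atoms to the forming-bond participants", {
  m <- derive_mapping(williamson_mapped_smiles())
  cons <- trial_constraints(mapping = m)
  rxn <- parse_reaction_smiles(williamson_mapped_smiles())
  phenol_mapped <- rxn$reactants[[2]]
  iodo_mapped <- rxn$reactants[[1]]
  expect_length(reactive_atoms(phenol_mapped, cons), 1)  # only the O
  expect_equal(phenol_mapped$atoms$element[reactive_atoms(phenol_mapped, cons)],
               "O")
  expect_length(reactive_atoms(iodo_mapped, cons), 1)    # only the attacked C
  # unmapped molecule with a mapping constraint is an error
  expect_error(reactive_atoms(parse_smiles("CCI"), cons), "no atom-map")
})

test_that("trial counts follow |A| x |B| x rotamers x attack points", {
  iodoethane <- embed_3d(parse_smiles("CCI"), 1)
  phenol <- embed_3d(parse_smiles("Oc1ccccc1"), 2)
  tr <- generate_trials(iodoethane, phenol)
  expect_equal(nrow(tr), 84)  # 3 x 7 x 2 x 2
  expect_equal(count_trials(3, 7), 84L)

  one <- trial_constraints(n_rotamers = 1, n_attack_points = 1)
  hi <- embed_3d(parse_smiles("I"), 1)
  water <- embed_3d(parse_smiles("O"), 1)
  expect_equal(nrow(generate_trials(hi, water, one)), 1)
  expect_equal(count_trials(0, 5), 0L)
})

test_that("mapping pruning keeps exactly the formed O-C pair", {
  rxn <- parse_reaction_smiles(williamson_mapped_smiles())
  m <- derive_mapping(rxn)
  A <- embed_3d(rxn$reactants[[1]], 1)  # iodoethane, mapped
  B <- embed_3d(rxn$reactants[[2]], 2)  # phenol, mapped
  tr <- generate_trials(A, B, trial_constraints(mapping = m))
  expect_equal(nrow(tr), 4)  # 1 x 1 x 2 x 2
  # soundness: every surviving pair is a formed cross-bond
  ma <- A$heavy_graph$atoms$map_index[tr$atom_a]
  mb <- B$heavy_graph$atoms$map_index[tr$atom_b]
  expect_true(all(paste(pmin(ma, mb), pmax(ma, mb)) %in%
                  paste(pmin(m$formed_bonds[, 1], m$formed_bonds[, 2]),
                        pmax(m$formed_bonds[, 1], m$formed_bonds[, 2]))))
  # completeness: the known O-C forming pair survives
  els <- paste0(A$heavy_graph$atoms$element[tr$atom_a],
                B$heavy_graph$atoms$element[tr$atom_b])
  expect_true(all(els == "CO"))
})

test_that("trial count doubles quadratically with system size", {
  for (n in c(1, 3, 8)) {
    expect_equal(count_trials(2 * n, 2 * n) / count_trials(n, n), 4)
  }
})

test_that("generated trials match the brute-force oracle on random sizes", {
  cons <- trial_constraints()
  set.seed(202)
  sizes <- cbind(sample(1:12, 25, replace = TRUE),
                 sample(1:12, 25, replace = TRUE))
  for (k in seq_len(nrow(sizes))) {
    A <- alkane_structure(sizes[k, 1])
    B <- alkane_structure(sizes[k, 2])
    tr <- generate_trials(A, B, cons)
    oracle <- brute_force_trials(reactive_atoms(A, cons),
                                 reactive_atoms(B, cons),
                                 cons$n_rotamers, cons$n_attack_points)
    expect_equal(nrow(tr), nrow(oracle))
    expect_equal(nrow(tr), count_trials(sizes[k, 1], sizes[k, 2], cons))
    expect_equal(unname(as.matrix(tr)), unname(oracle))
  }
})

test_that("identical inputs give identical ordered trial lists", {
  A <- embed_3d(parse_smiles("CCI"), 1)
  B <- embed_3d(parse_smiles("Oc1ccccc1"), 2)
  t1 <- generate_trials(A, B)
  t2 <- generate_trials(A, B)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # lexicographic ordering on (atom_a, atom_b, rotamer, attack)
  key <- order(t1$atom_a, t1$atom_b, t1$rotamer, t1$attack)
  expect_equal(key, seq_len(nrow(t1)))
})
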