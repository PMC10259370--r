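# Surrogate and external energy backends.

test_that("the surrogate energy is a pure function of the molecular graph", {
  be <- surrogate_backend()
  s1 <- embed_3d(parse_smiles("CCO"), seed = 1)
  s2 <- embed_3d(parse_smiles("CCO"), seed = 99)  # different conformer
  e1 <- calc_energy(be, s1)
  e2 <- calc_energy(be, s2)
  expect_true(e1$converged)
  expect_identical(e1$energy, e2$energy)
  expect_identical(calc_energy(be, s1)$energy, e1$energy)
})

test_that("bond increments reproduce the ethanol / dimethyl ether difference", {
  be <- surrogate_backend()
  ethanol <- calc_energy(be, embed_3d(parse_smiles("CCO"), 1))$energy
  dme <- calc_energy(be, embed_3d(parse_smiles("COC"), 1))$energy
  # (O-H + C-C) - (C-H + C-O) = (-460 - 350) - (-400 - 360) = -50
  expect_equal(ethanol - dme, -50)
})

test_that("an empty molecule is rejected by the energy contract", {
  be <- surrogate_backend()
  s <- embed_3d(parse_smiles("C"), 1)
  s$graph$atoms <- s$graph$atoms[0, ]
  expect_error(calc_energy(be, s), "empty molecule")
})

test_that("the Williamson rule table yields the published step energetics", {
  fx <- williamson_fixture()
  rxn <- parse_reaction_smiles(williamson_mapped_smiles())
  A <- embed_3d(rxn$reactants[[1]], 1)
  B <- embed_3d(rxn$reactants[[2]], 2)
  m <- derive_mapping(rxn)
  tr <- generate_trials(A, B, trial_constraints(mapping = m))
  res <- search_step(fx$backend, tr, 1)
  expect_equal(res$outcome, "step_found")
  en <- step_energetics(res$step)
  expect_equal(unname(en["barrier"]), 218)
  expect_equal(unname(en["energy"]), -34)
})

test_that("trials outside the rule table return no_step", {
  be <- surrogate_backend()  # empty rule table
  A <- embed_3d(parse_smiles("CCI"), 1)
  B <- embed_3d(parse_smiles("Oc1ccccc1"), 2)
  tr <- generate_trials(A, B)
  expect_equal(search_step(be, tr, 1)$outcome, "no_step")
})

test_that("the Hartree conversion constant matches its printed value", {
  expect_equal(HARTREE_KJ_PER_MOL, 2625.499639)
})

test_that("a missing external program is an actionable error, never a silent no_step", {
  be <- external_backend(executable = "no-such-qc-program-on-path")
  A <- embed_3d(parse_smiles("CCI"), 1)
  B <- embed_3d(parse_smiles("Oc1ccccc1"), 2)
  tr <- generate_trials(A, B)
  res <- search_step(be, tr, 1)
  expect_equal(res$outcome, "error")
  expect_match(res$diagnostic, "not found on PATH")
  en <- calc_energy(be, A)
  expect_false(en$converged)
  expect_true(is.na(en$energy))
  expect_match(en$diagnostic, "not found on PATH")
})

test_that("the external adapter passes charge and spin through verbatim", {
  be <- external_backend(executable = "xtb", extra_args = c("--gfn", "2"))
  cmd <- external_command(be, "mol.xyz", charge = -1, multiplicity = 2)
  expect_equal(cmd, c("xtb", "mol.xyz", "--chrg", "-1", "--uhf", "1",
                      "--gfn", "2"))
})
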