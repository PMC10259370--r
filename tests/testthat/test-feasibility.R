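# Thermodynamic filtering and Maxwell-Boltzmann kinetic dominance.

test_that("MB survival matches its boundary and quadrature values", {
  cfg <- feasibility_config()
  expect_equal(mb_survival(0, cfg), 1.0)
  # E = RT: frozen value computed independently by quadrature of the
  # 3-DOF kinetic-energy density
  rt <- cfg$gas_constant * cfg$temperature
  expect_equal(mb_survival(rt, cfg), 0.5724067, tolerance = 1e-6)
  expect_error(mb_survival(-1, cfg), "non-negative")
})

test_that("MB survival agrees with the quadrature oracle over a T/E grid", {
  for (temp in c(298.15, 373.15, 500)) {
    cfg <- feasibility_config(temperature = temp)
    E <- seq(0, 300, by = 10)
    closed <- mb_survival(E, cfg)
    oracle <- mb_survival_quadrature(E, cfg)
    expect_lt(max(abs(closed - oracle) / oracle), 1e-6)
  }
})

test_that("MB survival is strictly decreasing in energy", {
  cfg <- feasibility_config()
  E <- seq(0, 400, by = 5)
  s <- mb_survival(E, cfg)
  expect_true(all(diff(s) < 0))
})

test_that("the 218 vs 250 kJ/mol window is four orders of magnitude at 100 C", {
  r <- dominance_ratio(218, 250)
  expect_gte(r, 1e4)
  expect_lt(r, 1e5)
  expect_equal(floor(log10(r)), 4)
})

test_that("dominance ratio vanishes as the window shrinks and matches quadrature", {
  cfg <- feasibility_config()
  eps <- c(10, 1, 0.1, 0.01)
  ratios <- vapply(eps, function(e) dominance_ratio(100, 100 + e, cfg),
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[length(ratios)], 1e-2)

  oracle <- (mb_survival_quadrature(100, cfg) - mb_survival_quadrature(132, cfg)) /
    mb_survival_quadrature(132, cfg)
  expect_equal(dominance_ratio(100, 132, cfg), oracle, tolerance = 1e-6)

  expect_error(dominance_ratio(250, 218), "barrier_lo < barrier_hi")
})

.energy_net <- function(des, barriers = des + 100) {
  # small network with one reaction per (barrier, reaction energy) pair
  net <- reaction_network()
  for (k in seq_along(des)) {
    prod <- embed_3d(parse_smiles(strrep("C", k)), 1)
    st <- elementary_step(
      reactants = list(embed_3d(parse_smiles("CCI"), 1),
                       embed_3d(parse_smiles("Oc1ccccc1"), 2)),
      products = list(prod),
      e_react = -1000, e_ts = -1000 + max(barriers[k], max(0, des[k])),
      e_prod = -1000 + des[k])
    register_step(net, st)
  }
  net
}

test_that("thermo_filter removes exactly the endothermic reactions", {
  net <- .energy_net(c(-34, -48, -52, 10))
  surv <- thermo_filter(net, feasibility_config())
  expect_length(surv, 3)
  rx <- network_reactions(net)
  expect_false(rx$id[rx$reaction_energy > 0] %in% surv)

  all_endo <- .energy_net(c(5, 80, 120))
  expect_length(thermo_filter(all_endo, feasibility_config()), 0)
})

test_that("the Williamson surrogate network validates the target reaction", {
  w <- cached_williamson_report()
  net <- w$report$network
  cfg <- w$fixture$config$feasibility
  expect_length(thermo_filter(net, cfg), 4)  # 34 of 38 ruled out
  v <- assess(net, w$fixture$target, cfg)
  expect_equal(v$status, "validated")
  expect_true(v$target_found)
  expect_equal(v$target_barrier, 218)
  expect_equal(v$target_energy, -34)
  expect_equal(nrow(v$competitors), 2)  # the -48 and -52 ring attacks
  expect_setequal(v$competitors$barrier, c(250, 253))
  expect_gte(v$dominance_ratio, 1e4)
})

test_that("raising the target barrier above its competitors flips the verdict", {
  # same energetic layout, but the target now has the highest barrier
  net <- reaction_network()
  mk <- function(barrier, de, prods) {
    elementary_step(
      reactants = list(embed_3d(parse_smiles("CCI"), 1),
                       embed_3d(parse_smiles("Oc1ccccc1"), 2)),
      products = lapply(prods, function(s) embed_3d(parse_smiles(s), 1)),
      e_react = -1000, e_ts = -1000 + barrier, e_prod = -1000 + de)
  }
  register_step(net, mk(260, -34, c("CCOc1ccccc1", "I")))
  register_step(net, mk(250, -48, c("CCc1ccccc1O", "I")))
  v <- assess(net, list(reactants = c("CCI", "Oc1ccccc1"),
                        products = "CCOc1ccccc1"),
              feasibility_config())
  expect_equal(v$status, "invalidated")
})

test_that("error-dominated or incomplete explorations are inconclusive", {
  net <- .energy_net(c(-34))
  cfg <- feasibility_config()
  target <- list(reactants = c("CCI", "Oc1ccccc1"), products = "C")
  v <- assess(net, target, cfg, exploration = list(complete = TRUE, n_errors = 5))
  expect_equal(v$status, "inconclusive")
  v <- assess(net, target, cfg, exploration = list(complete = FALSE, n_errors = 0))
  expect_equal(v$status, "inconclusive")
  # absent target: invalidated only when the exploration completed cleanly
  missing <- list(reactants = c("CCI", "Oc1ccccc1"), products = "CCCCCCCC")
  v <- assess(net, missing, cfg, exploration = list(complete = TRUE, n_errors = 0))
  expect_equal(v$status, "invalidated")
  v <- assess(net, missing, cfg, exploration = list(complete = FALSE, n_errors = 0))
  expect_equal(v$status, "inconclusive")
})

test_that("assess is monotone in the dominance threshold", {
  w <- cached_williamson_report()
  net <- w$report$network
  statuses <- vapply(c(1, 100, 1e4, 1e5, 1e7), function(thr) {
    assess(net, w$fixture$target,
           feasibility_config(dominance_threshold = thr))$status
  }, character(1))
  # once invalidated, raising the threshold never re-validates
  flips <- rle(statuses)$values
  expect_true(all(flips %in% c("validated", "invalidated")))
  expect_lte(length(flips), 2)
  if (length(flips) == 2) {
    expect_equal(flips, c("validated", "invalidated"))
  }
})
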