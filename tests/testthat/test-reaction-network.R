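# Compound aggregation, reaction merging and network serialization.

test_that("structures aggregate into compounds by connectivity", {
  net <- reaction_network()
  conf1 <- embed_3d(parse_smiles("Oc1ccccc1"), seed = 1)
  conf2 <- embed_3d(parse_smiles("Oc1ccccc1"), seed = 2)
  c1 <- register_structure(net, conf1)
  c2 <- register_structure(net, conf2)
  expect_equal(as.character(c1), as.character(c2))  # same compound
  expect_equal(network_summary(net)$n_compounds, 1)
  expect_equal(network_summary(net)$n_structures, 2)

  register_structure(net, embed_3d(parse_smiles("CCOc1ccccc1"), seed = 1))
  expect_equal(network_summary(net)$n_compounds, 2)

  # registering the identical structure again changes nothing
  before <- network_summary(net)
  register_structure(net, conf1)
  expect_equal(network_summary(net), before)
})

.mini_step <- function(barrier, de, products = c("CCOc1ccccc1", "I"),
                       e_react = -5000) {
  elementary_step(
    reactants = list(embed_3d(parse_smiles("CCI"), 1),
                     embed_3d(parse_smiles("Oc1ccccc1"), 2)),
    products = lapply(products, function(s) embed_3d(parse_smiles(s), 1)),
    e_react = e_react, e_ts = e_react + barrier, e_prod = e_react + de)
}

test_that("steps with the same compound pair merge; best_barrier is the running minimum", {
  net <- reaction_network()
  r1 <- register_step(net, .mini_step(218, -34))
  r2 <- register_step(net, .mini_step(250, -30))
  expect_equal(as.character(r1), as.character(r2))
  rx <- network_reactions(net)
  expect_equal(nrow(rx), 1)
  expect_equal(rx$n_steps, 2)
  expect_equal(rx$best_barrier, 218)
  expect_equal(rx$reaction_energy, -34)

  # different products make a different reaction
  register_step(net, .mini_step(250, -48, products = c("CCc1ccccc1O", "I")))
  expect_equal(network_summary(net)$n_reactions, 2)
})

test_that("a barrierless-limit step yields a zero barrier", {
  net <- reaction_network()
  register_step(net, .mini_step(0, -10))
  expect_equal(network_reactions(net)$best_barrier, 0)
})

test_that("violated step invariants are rejected with the failing inequality", {
  expect_error(.mini_step(-20, -3), "E_TS .* < E_react")
  expect_error(.mini_step(5, 40), "E_TS .* < E_prod")
  # identical connectivity on both sides is not an elementary step
  expect_error(elementary_step(
    reactants = list(embed_3d(parse_smiles("CCO"), 1)),
    products = list(embed_3d(parse_smiles("CCO"), 2)),
    e_react = -100, e_prod = -100, e_ts = -90),
    "connectivity must differ")
})

test_that("summary counts endothermic reactions above the tolerance", {
  net <- reaction_network()
  expect_equal(network_summary(net),
               list(n_compounds = 0L, n_structures = 0L, n_steps = 0L,
                    n_reactions = 0L, n_endothermic = 0L))

  register_step(net, .mini_step(218, -34))
  register_step(net, .mini_step(250, -48, products = c("CCc1ccccc1O", "I")))
  register_step(net, .mini_step(100, 10, products = c("CCO")))
  s <- network_summary(net)
  expect_equal(s$n_reactions, 3)
  expect_equal(s$n_endothermic, 1)
})

test_that("compound member counts conserve the number of registered structures", {
  net <- reaction_network()
  smiles <- c("CCI", "Oc1ccccc1", "CCO", "CCI", "CCOc1ccccc1")
  for (k in seq_along(smiles)) {
    register_structure(net, embed_3d(parse_smiles(smiles[k]), seed = k))
  }
  members <- sum(vapply(net$compounds, function(cp) length(cp$members),
                        integer(1)))
  expect_equal(members, network_summary(net)$n_structures)
})

test_that("step registration order does not change reactions or barriers", {
  steps <- list(
    .mini_step(218, -34),
    .mini_step(260, -34),
    .mini_step(250, -48, products = c("CCc1ccccc1O", "I")),
    .mini_step(300, -48, products = c("CCc1ccccc1O", "I")),
    .mini_step(90, 12, products = c("CCO"))
  )
  snapshot <- function(perm) {
    net <- reaction_network()
    for (st in steps[perm]) register_step(net, st)
    rx <- network_reactions(net)
    # compound ids depend on registration order; translate to connectivity
    # keys so permutations are comparable
    key_of <- vapply(net$compounds, `[[`, character(1), "key")
    translate <- function(ids) {
      paste(sort(key_of[strsplit(ids, "+", fixed = TRUE)[[1]]]),
            collapse = "&")
    }
    rx$reactants <- vapply(rx$reactants, translate, character(1))
    rx$products <- vapply(rx$products, translate, character(1))
    rx <- rx[order(rx$reactants, rx$products), c("reactants", "products",
                                                 "n_steps", "best_barrier",
                                                 "reaction_energy")]
    rownames(rx) <- NULL
    rx
  }
  base <- snapshot(1:5)
  for (perm in list(5:1, c(3, 5, 1, 4, 2), c(2, 4, 5, 3, 1))) {
    expect_equal(snapshot(perm), base)
  }
})

test_that("networks round-trip through JSON with ids, keys and energies intact", {
  net <- reaction_network()
  register_step(net, .mini_step(218.123456789, -34.987654321))
  register_step(net, .mini_step(250, -48, products = c("CCc1ccccc1O", "I")))
  path <- withr::local_tempfile(fileext = ".json")
  network_to_json(net, path)
  net2 <- network_from_json(path)
  expect_equal(network_reactions(net2), network_reactions(net))
  expect_identical(sort(names(net2$compounds)), sort(names(net$compounds)))
  expect_identical(
    vapply(net$compounds, `[[`, character(1), "key"),
    vapply(net2$compounds, `[[`, character(1), "key"))
  expect_equal(net2$steps$e1$e_react, net$steps$e1$e_react, tolerance = 1e-12)
  # a second round trip is byte-stable
  expect_identical(as.character(network_to_json(net2)),
                   as.character(network_to_json(net)))
})

test_that("the bipartite edge list covers every reaction side", {
  net <- reaction_network()
  register_step(net, .mini_step(218, -34))
  el <- network_edge_list(net)
  expect_equal(nrow(el), 4)  # 2 reactants + 2 products
  expect_setequal(el$side, c("reactant", "product"))
})
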