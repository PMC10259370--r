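# End-to-end step and route validation, confidence combination, fixtures.

test_that("confidence updates follow the default combiner and stay in [0, 1]", {
  expect_equal(update_confidence(0.42, "validated"), 0.71)
  expect_equal(update_confidence(1.0, "invalidated"), 0.5)
  for (c0 in seq(0, 1, by = 0.1)) {
    expect_equal(update_confidence(c0, "inconclusive"), c0)
    for (w in c(0, 0.3, 0.5, 1)) {
      up <- update_confidence(c0, "validated", w)
      down <- update_confidence(c0, "invalidated", w)
      expect_gte(up, c0 - 1e-12)   # validation never lowers confidence
      expect_lte(down, c0 + 1e-12) # invalidation never raises it
      expect_gte(down, 0)
      expect_lte(up, 1)
    }
  }
})

test_that("the Williamson step validates end-to-end and raises its confidence", {
  w <- cached_williamson_report()
  rep <- w$report
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$verdict$status, "validated")
  expect_equal(rep$n_trials_generated, 84)
  expect_equal(rep$n_trials_run, 84)
  expect_equal(rep$summary$n_reactions, 38)
  expect_equal(rep$summary$n_endothermic, 34)
  expect_equal(rep$initial_confidence, 0.42)
  expect_equal(rep$updated_confidence, 0.71)
  expect_gt(rep$updated_confidence, rep$initial_confidence)
})

test_that("a decomposition whose second step finds nothing under budget is inconclusive", {
  fx <- friedel_crafts_fixture()
  rep <- validate_step(fx$step, fx$config)
  expect_equal(rep$verdict$status, "inconclusive")
  statuses <- vapply(rep$sub_reports, function(r) r$verdict$status, character(1))
  expect_equal(statuses, c("validated", "inconclusive"))
  # the second sub-search ran out of budget, not out of chemistry
  expect_lt(rep$n_trials_run, rep$n_trials_generated)
  expect_equal(rep$updated_confidence, rep$initial_confidence)
})

test_that("a mapping with no changing atoms is inconclusive with a clear diagnostic", {
  step <- retro_step(product = "CCI", precursors = c("CCI", "Oc1ccccc1"),
                     confidence = 0.5,
                     mapped_smiles = "[CH3:1][CH2:2][I:3]>>[CH3:1][CH2:2][I:3]")
  rep <- validate_step(step, validation_config())
  expect_equal(rep$verdict$status, "inconclusive")
  expect_match(paste(rep$verdict$diagnostics, collapse = " "),
               "no reactive coordinate")
  expect_equal(rep$updated_confidence, 0.5)
})

test_that("route validation respects the shared trial budget", {
  rr <- random_route_fixture(3, seed = 11)
  out <- validate_route(rr$route, rr$config)
  expect_length(out$route, 3)
  expect_equal(out$priority_step,
               which.min(vapply(rr$route, `[[`, numeric(1), "confidence")))
  for (k in 1:3) {
    expect_equal(out$route[[k]]$confidence,
                 out$reports[[k]]$updated_confidence)
  }

  none <- validate_route(rr$route, rr$config, budget = 0)
  statuses <- vapply(none$reports, function(r) r$verdict$status, character(1))
  expect_equal(statuses, rep("inconclusive", 3))
  for (k in 1:3) {
    expect_equal(none$route[[k]]$confidence, rr$route[[k]]$confidence)
  }
  expect_equal(none$total_trials, 0)
})

test_that("route validation is deterministic under a fixed seed", {
  rr <- random_route_fixture(2, seed = 5)
  out1 <- validate_route(rr$route, rr$config)
  rr2 <- random_route_fixture(2, seed = 5)
  out2 <- validate_route(rr2$route, rr2$config)
  expect_identical(
    lapply(out1$reports, function(r)
      list(r$verdict$status, r$n_trials_run, r$updated_confidence,
           network_reactions(r$network))),
    lapply(out2$reports, function(r)
      list(r$verdict$status, r$n_trials_run, r$updated_confidence,
           network_reactions(r$network))))
})

test_that("fixture files are byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (name in c("williamson", "friedel_crafts", "random_route")) {
    make_fixtures(name, seed = 7, dir = file.path(d1, name))
    make_fixtures(name, seed = 7, dir = file.path(d2, name))
    f1 <- list.files(file.path(d1, name), full.names = TRUE)
    f2 <- list.files(file.path(d2, name), full.names = TRUE)
    expect_equal(basename(f1), basename(f2))
    for (k in seq_along(f1)) {
      expect_identical(readLines(f1[k]), readLines(f2[k]))
    }
  }
  expect_error(make_fixtures("grignard"), "should be one of")
})

test_that("routes and backends survive a JSON round trip", {
  d <- withr::local_tempdir()
  make_fixtures("williamson", dir = d)
  route <- read_route(file.path(d, "route.json"))
  expect_length(route, 1)
  expect_equal(route[[1]]$product, "CCOc1ccccc1")
  expect_equal(route[[1]]$confidence, 0.42)
  backend <- backend_from_json(file.path(d, "backend.json"))
  rep <- validate_step(route[[1]], validation_config(backend = backend))
  expect_equal(rep$verdict$status, "validated")
})

test_that("every discovered step is attributable to its producing trial", {
  w <- cached_williamson_report()
  net <- w$report$network
  expect_length(net$provenance, length(net$steps))
  expect_setequal(names(net$provenance), names(net$steps))
  tr <- net$provenance[[net$steps$e1$id]]
  expect_named(tr, c("atom_a", "atom_b", "rotamer", "attack"),
               ignore.order = TRUE)
})
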