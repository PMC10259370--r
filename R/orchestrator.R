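# End-to-end validation loop: ingest a retrosynthetic step, prepare inputs,
# run a constrained exploration with the configured backend, aggregate the
# results into a reaction network, assess feasibility, and combine the
# verdict with the AI confidence score.

#' Construct a retrosynthetic step record
#'
#' One single-step prediction: a product, its suggested precursors, an
#' optional atom-mapped reaction SMILES, and the AI model's confidence.
#' Roles, stoichiometries, declared byproducts and work-up metadata are
#' accepted and logged; byproducts and work-up are schema fields only and do
#' not steer the exploration.
#'
#' @param product Product SMILES.
#' @param precursors Character vector of precursor SMILES.
#' @param confidence AI confidence in `[0, 1]`.
#' @param mapped_smiles Optional atom-mapped reaction SMILES.
#' @param roles Optional per-precursor roles, each one of `"reactant"`,
#'   `"reagent"`, `"solvent"`, `"catalyst"` (default: all `"reactant"`,
#'   since precursor lists do not come with role annotations).
#' @param stoichiometry Optional positive integer per precursor.
#' @param decomposition Optional ordered list of elementary sub-reactions for
#'   multi-step overall transformations; each element is a list with
#'   `precursors` and `products` (SMILES vectors) and optionally
#'   `mapped_smiles`.
#' @param byproducts,workup Optional metadata (recorded, not simulated).
#' @return An object of class `retro_step`.
#' @export
retro_step <- function(product, precursors, confidence, mapped_smiles = NULL,
                       roles = NULL, stoichiometry = NULL,
                       decomposition = NULL, byproducts = NULL,
                       workup = NULL) {
  stopifnot(is.character(product), length(product) == 1L,
            is.character(precursors), length(precursors) >= 1L,
            is.numeric(confidence), confidence >= 0, confidence <= 1)
  if (is.null(roles)) roles <- rep("reactant", length(precursors))
  stopifnot(length(roles) == length(precursors),
            all(roles %in% c("reactant", "reagent", "solvent", "catalyst")))
  if (!is.null(stoichiometry)) {
    stopifnot(length(stoichiometry) == length(precursors),
              all(stoichiometry >= 1), all(stoichiometry == round(stoichiometry)))
  }
  structure(list(product = product, precursors = precursors,
                 confidence = confidence, mapped_smiles = mapped_smiles,
                 roles = roles, stoichiometry = stoichiometry,
                 decomposition = decomposition, byproducts = byproducts,
                 workup = workup),
            class = "retro_step")
}

#' @export
print.retro_step <- function(x, ...) {
  cat(sprintf("<retro_step> %s <= %s (confidence %.2f)%s\n", x$product,
              paste(x$precursors, collapse = " + "), x$confidence,
              if (!is.null(x$decomposition))
                sprintf(", %d elementary sub-reactions", length(x$decomposition))
              else ""))
  invisible(x)
}

#' Validation configuration
#'
#' @param backend Energy backend (default: a bare [surrogate_backend()]).
#' @param constraints [trial_constraints()] for the exploration.
#' @param feasibility [feasibility_config()].
#' @param combiner_weight Weight `w` of the default confidence combiner.
#' @param combiner Confidence-update function with signature
#'   `(confidence, status, weight)`; pluggable, defaults to
#'   [update_confidence()]. Any replacement must keep confidences in
#'   `[0, 1]`, never lower them on validation nor raise them on
#'   invalidation.
#' @param seed Seed for 3D embedding and any backend randomness.
#' @param trial_budget Maximum elementary-step trials per step (default
#'   `Inf`); an exploration cut short by this budget is reported as
#'   incomplete and can only yield an inconclusive negative.
#' @param prune_with_mapping If `TRUE` and a mapping is available, restrict
#'   trials to the mapped forming bonds (the minimal-calculation mode); the
#'   default `FALSE` explores all heavy-atom pairs so competing reactions are
#'   discovered too.
#' @param add_species Extra SMILES (e.g. a catalyst dimer) registered into
#'   the network before exploration.
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(backend = surrogate_backend(),
                              constraints = trial_constraints(),
                              feasibility = feasibility_config(),
                              combiner_weight = 0.5,
                              combiner = update_confidence,
                              seed = 1L, trial_budget = Inf,
                              prune_with_mapping = FALSE,
                              add_species = character(0)) {
  stopifnot(combiner_weight >= 0, combiner_weight <= 1)
  structure(list(backend = backend, constraints = constraints,
                 feasibility = feasibility,
                 combiner_weight = combiner_weight, combiner = combiner,
                 seed = as.integer(seed), trial_budget = trial_budget,
                 prune_with_mapping = prune_with_mapping,
                 add_species = add_species),
            class = "validation_config")
}

#' Combine an AI confidence with an exploration verdict
#'
#' Default combiner with weight `w`:
#' validated `c' = 1 - (1 - c)(1 - w)`, invalidated `c' = c (1 - w)`,
#' inconclusive `c' = c`. Keeps confidences in `[0, 1]`, never lowers a
#' confidence on validation and never raises one on invalidation.
#'
#' @param confidence Prior confidence in `[0, 1]`.
#' @param status Verdict status (`"validated"`, `"invalidated"`,
#'   `"inconclusive"`) or a `verdict` object.
#' @param weight Update weight `w` in `[0, 1]` (default 0.5).
#' @return Updated confidence in `[0, 1]`.
#' @examples
#' update_confidence(0.42, "validated")  # 0.71
#' @export
update_confidence <- function(confidence, status, weight = 0.5) {
  stopifnot(confidence >= 0, confidence <= 1, weight >= 0, weight <= 1)
  if (inherits(status, "verdict")) status <- status$status
  out <- switch(status,
    validated = 1 - (1 - confidence) * (1 - weight),
    invalidated = confidence * (1 - weight),
    inconclusive = confidence,
    stop("unknown verdict status: ", status))
  min(1, max(0, out))
}

# Run the exploration for one (bi)molecular reaction: returns verdict,
# network and tallies. `budget` caps the number of trials actually executed.
.explore_reaction <- function(reactant_smiles, product_smiles, mapped_smiles,
                              config, budget = Inf) {
  mapping <- NULL
  mapped_reactants <- NULL
  if (!is.null(mapped_smiles)) {
    rxn <- parse_reaction_smiles(mapped_smiles)
    mapping <- derive_mapping(rxn)
    if (length(mapping$changed_atoms) == 0L) {
      return(list(verdict = structure(list(
        status = "inconclusive", target_found = FALSE,
        target_id = NA_character_, target_barrier = NA_real_,
        target_energy = NA_real_,
        competitors = data.frame(reaction = character(0), barrier = numeric(0),
                                 energy = numeric(0), ratio = numeric(0)),
        dominance_ratio = NA_real_,
        diagnostics = "no reactive coordinate: the mapping shows no changing atoms"),
        class = "verdict"),
        network = reaction_network(), n_generated = 0L, n_run = 0L,
        n_found = 0L, n_no_step = 0L, n_errors = 0L))
    }
    mapped_reactants <- rxn$reactants
  }

  graphs <- lapply(reactant_smiles, parse_smiles)
  # swap in the mapped reactant graphs (they carry map indices) when available
  if (!is.null(mapped_reactants)) {
    keys <- vapply(graphs, connectivity_key, character(1))
    mkeys <- vapply(mapped_reactants, connectivity_key, character(1))
    for (k in seq_along(graphs)) {
      hit <- match(keys[k], mkeys)
      if (!is.na(hit)) {
        graphs[[k]] <- mapped_reactants[[hit]]
        mkeys[hit] <- NA_character_
      }
    }
  }

  if (length(graphs) < 2L) {
    return(list(verdict = structure(list(
      status = "inconclusive", target_found = FALSE,
      target_id = NA_character_, target_barrier = NA_real_,
      target_energy = NA_real_,
      competitors = data.frame(reaction = character(0), barrier = numeric(0),
                               energy = numeric(0), ratio = numeric(0)),
      dominance_ratio = NA_real_,
      diagnostics = "bimolecular exploration needs two reactant species"),
      class = "verdict"),
      network = reaction_network(), n_generated = 0L, n_run = 0L,
      n_found = 0L, n_no_step = 0L, n_errors = 0L))
  }

  emb <- function(g, off) tryCatch(embed_3d(g, seed = config$seed + off),
                                   error = function(e) e)
  A <- emb(graphs[[1]], 0L)
  B <- emb(graphs[[2]], 1L)
  if (inherits(A, "error") || inherits(B, "error")) {
    msg <- conditionMessage(if (inherits(A, "error")) A else B)
    return(list(verdict = structure(list(
      status = "inconclusive", target_found = FALSE,
      target_id = NA_character_, target_barrier = NA_real_,
      target_energy = NA_real_,
      competitors = data.frame(reaction = character(0), barrier = numeric(0),
                               energy = numeric(0), ratio = numeric(0)),
      dominance_ratio = NA_real_,
      diagnostics = paste("structure preparation failed:", msg)),
      class = "verdict"),
      network = reaction_network(), n_generated = 0L, n_run = 0L,
      n_found = 0L, n_no_step = 0L, n_errors = 0L))
  }

  constraints <- config$constraints
  if (config$prune_with_mapping && !is.null(mapping)) {
    constraints$mapping <- mapping
  }
  trials <- generate_trials(A, B, constraints)
  n_gen <- nrow(trials)
  n_run <- min(n_gen, max(0, floor(budget)))
  complete <- n_run == n_gen

  net <- reaction_network()
  for (sm in config$add_species) register_structure(net, parse_smiles(sm))
  n_found <- n_no_step <- n_errors <- 0L
  for (i in seq_len(n_run)) {
    res <- search_step(config$backend, trials, i)
    if (res$outcome == "step_found") {
      register_step(net, res$step,
                    trial = list(atom_a = trials$atom_a[i],
                                 atom_b = trials$atom_b[i],
                                 rotamer = trials$rotamer[i],
                                 attack = trials$attack[i]))
      n_found <- n_found + 1L
    } else if (res$outcome == "no_step") {
      n_no_step <- n_no_step + 1L
    } else {
      n_errors <- n_errors + 1L
    }
  }

  verdict <- assess(net,
                    target = list(reactants = reactant_smiles,
                                  products = product_smiles),
                    config = config$feasibility,
                    exploration = list(complete = complete,
                                       n_errors = n_errors))
  list(verdict = verdict, network = net, n_generated = n_gen, n_run = n_run,
       n_found = n_found, n_no_step = n_no_step, n_errors = n_errors)
}

#' Validate one retrosynthetic step
#'
#' Runs the full loop: SMILES to graphs to sanitized 3D structures,
#' constrained bimolecular trial enumeration, elementary-step searches with
#' the configured backend, network aggregation, feasibility assessment and
#' confidence update. Precursors with roles `"solvent"` or `"catalyst"` do
#' not enter the bimolecular trial pair (catalytic chemistry belongs in an
#' explicit `decomposition`). When a decomposition into elementary
#' sub-reactions is supplied, each sub-reaction is validated in order under
#' the shared trial budget; the step verdict is `validated` only if every
#' sub-reaction is, `invalidated` as soon as one is, and `inconclusive`
#' otherwise.
#'
#' @param step A [retro_step()].
#' @param config A [validation_config()].
#' @param budget Optional trial budget overriding `config$trial_budget`.
#' @return An object of class `validation_report`: `verdict`, `network`
#'   (last explored network), `summary` counts, trial tallies,
#'   `updated_confidence`, per-sub-reaction `sub_reports`, provenance.
#' @export
validate_step <- function(step, config = validation_config(), budget = NULL) {
  stopifnot(inherits(step, "retro_step"), inherits(config, "validation_config"))
  if (is.null(budget)) budget <- config$trial_budget

  participates <- step$roles %in% c("reactant", "reagent")
  sub_reports <- NULL

  if (!is.null(step$decomposition)) {
    statuses <- character(0)
    sub_reports <- list()
    remaining <- budget
    for (k in seq_along(step$decomposition)) {
      sub <- step$decomposition[[k]]
      res <- .explore_reaction(sub$precursors, sub$products,
                               sub$mapped_smiles, config, remaining)
      remaining <- remaining - res$n_run
      sub_reports[[k]] <- res
      statuses <- c(statuses, res$verdict$status)
    }
    status <- if (all(statuses == "validated")) "validated"
              else if (any(statuses == "invalidated")) "invalidated"
              else "inconclusive"
    last <- sub_reports[[length(sub_reports)]]
    verdict <- structure(list(
      status = status, target_found = all(statuses == "validated"),
      target_id = NA_character_, target_barrier = NA_real_,
      target_energy = NA_real_,
      competitors = data.frame(reaction = character(0), barrier = numeric(0),
                               energy = numeric(0), ratio = numeric(0)),
      dominance_ratio = NA_real_,
      diagnostics = sprintf("decomposition verdicts: %s",
                            paste(statuses, collapse = ", "))),
      class = "verdict")
    res <- list(verdict = verdict, network = last$network,
                n_generated = sum(vapply(sub_reports, `[[`, numeric(1), "n_generated")),
                n_run = sum(vapply(sub_reports, `[[`, numeric(1), "n_run")),
                n_found = sum(vapply(sub_reports, `[[`, numeric(1), "n_found")),
                n_no_step = sum(vapply(sub_reports, `[[`, numeric(1), "n_no_step")),
                n_errors = sum(vapply(sub_reports, `[[`, numeric(1), "n_errors")))
  } else {
    res <- .explore_reaction(step$precursors[participates], step$product,
                             step$mapped_smiles, config, budget)
  }

  updated <- config$combiner(step$confidence, res$verdict$status,
                             config$combiner_weight)
  structure(list(
    step = step, verdict = res$verdict, network = res$network,
    summary = network_summary(res$network,
                              endo_tol = config$feasibility$endo_tol),
    n_trials_generated = res$n_generated, n_trials_run = res$n_run,
    n_steps_found = res$n_found, n_no_step = res$n_no_step,
    n_errors = res$n_errors,
    initial_confidence = step$confidence, updated_confidence = updated,
    sub_reports = sub_reports,
    provenance = list(backend = class(config$backend)[1], seed = config$seed,
                      prune_with_mapping = config$prune_with_mapping,
                      temperature = config$feasibility$temperature,
                      combiner_weight = config$combiner_weight)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s\n", x$step$product, x$verdict$status))
  cat(sprintf("  trials %d/%d run, %d steps found, %d no-step, %d errors\n",
              x$n_trials_run, x$n_trials_generated, x$n_steps_found,
              x$n_no_step, x$n_errors))
  cat(sprintf("  network: %d compounds, %d reactions (%d endothermic)\n",
              x$summary$n_compounds, x$summary$n_reactions,
              x$summary$n_endothermic))
  cat(sprintf("  confidence %.3f -> %.3f\n", x$initial_confidence,
              x$updated_confidence))
  invisible(x)
}

#' Validate a whole retrosynthetic route
#'
#' Steps are processed in order under a shared trial budget (by default the
#' one-core-week capacity of `budget`). Once the budget is exhausted the
#' remaining steps are reported as inconclusive with their confidences
#' unchanged — never silently skipped. The lowest-confidence step is flagged
#' as the validation priority.
#'
#' @param route List of [retro_step()] objects (non-empty).
#' @param config A [validation_config()].
#' @param budget A [budget_model()] fixing the total trial budget, or a
#'   plain number of trials.
#' @return An object of class `route_report`: per-step `reports`, the
#'   updated `route` (confidences replaced), `total_trials`, `budget`,
#'   `priority_step` (index of the lowest initial confidence).
#' @export
validate_route <- function(route, config = validation_config(),
                           budget = budget_model()) {
  stopifnot(is.list(route), length(route) >= 1L)
  capacity <- if (inherits(budget, "budget_model")) trials_in_budget(budget)
              else as.numeric(budget)
  remaining <- capacity
  used <- 0
  reports <- vector("list", length(route))
  for (k in seq_along(route)) {
    reports[[k]] <- validate_step(route[[k]], config, budget = remaining)
    remaining <- remaining - reports[[k]]$n_trials_run
    used <- used + reports[[k]]$n_trials_run
    route[[k]]$confidence <- reports[[k]]$updated_confidence
  }
  confidences <- vapply(reports, `[[`, numeric(1), "initial_confidence")
  structure(list(reports = reports, route = route,
                 total_trials = used, budget = capacity,
                 priority_step = which.min(confidences)),
            class = "route_report")
}

#' @export
print.route_report <- function(x, ...) {
  cat(sprintf("<route_report> %d steps, %s/%s trials used, priority: step %d\n",
              length(x$reports), format(x$total_trials, big.mark = " "),
              format(x$budget, big.mark = " "), x$priority_step))
  for (k in seq_along(x$reports)) {
    r <- x$reports[[k]]
    cat(sprintf("  step %d: %s (confidence %.3f -> %.3f)\n", k,
                r$verdict$status, r$initial_confidence, r$updated_confidence))
  }
  invisible(x)
}
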