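# Feasibility analysis: thermodynamic rule-out plus a Maxwell-Boltzmann
# kinetic-dominance test.
#
# The model is deliberately energy-only: barriers are differences of total
# electronic energies with no nuclear-motion or entropic corrections.
# Endothermic reactions are ruled out first (thermodynamic control
# assumption). Among the surviving, more exothermic competitors of a target
# reaction, the target dominates kinetically when the population of
# reactant pairs with kinetic energy above the target's barrier but below a
# competitor's vastly exceeds the population above the competitor's barrier.
# The kinetic-energy distribution is the three-translational-degree-of-
# freedom Maxwell-Boltzmann form, whose survival function is the regularized
# upper incomplete gamma function Q(3/2, E/RT).

#' Feasibility configuration
#'
#' @param temperature Temperature in K (default 373.15, i.e. 100 degrees C).
#' @param endo_tol Endothermicity tolerance in kJ/mol: reactions with
#'   `reaction_energy > endo_tol` are ruled out (default 0).
#' @param dominance_threshold Minimum population ratio for the target to
#'   count as kinetically dominant (default 100; dimensionless, must be
#'   at least 1).
#' @param gas_constant Gas constant in kJ/(mol K).
#' @param error_budget Number of backend errors tolerated before a verdict
#'   degrades to inconclusive (default 0).
#' @return An object of class `feasibility_config`.
#' @export
feasibility_config <- function(temperature = 373.15, endo_tol = 0,
                               dominance_threshold = 100,
                               gas_constant = 8.3144626e-3,
                               error_budget = 0L) {
  stopifnot(temperature > 0, dominance_threshold >= 1, gas_constant > 0)
  structure(list(temperature = temperature, endo_tol = endo_tol,
                 dominance_threshold = dominance_threshold,
                 gas_constant = gas_constant,
                 error_budget = as.integer(error_budget)),
            class = "feasibility_config")
}

.erfc <- function(z) 2 * stats::pnorm(-sqrt(2) * z)

#' Maxwell-Boltzmann kinetic-energy survival probability
#'
#' Probability that a molecule's kinetic energy exceeds `E` for the
#' three-degree-of-freedom Maxwell-Boltzmann distribution at the configured
#' temperature: `Q(3/2, x) = erfc(sqrt(x)) + (2/sqrt(pi)) sqrt(x) exp(-x)`
#' with `x = E / RT`.
#'
#' @param E Energy (vectorized), kJ/mol, non-negative.
#' @param config A [feasibility_config()].
#' @return Survival probabilities in (0, 1].
#' @examples
#' cfg <- feasibility_config()
#' mb_survival(0, cfg)                                   # 1
#' mb_survival(cfg$gas_constant * cfg$temperature, cfg)  # 0.5724 at E = RT
#' @export
mb_survival <- function(E, config = feasibility_config()) {
  stopifnot(inherits(config, "feasibility_config"))
  if (any(E < 0)) stop("mb_survival requires non-negative energies")
  x <- E / (config$gas_constant * config$temperature)
  .erfc(sqrt(x)) + (2 / sqrt(pi)) * sqrt(x) * exp(-x)
}

#' Kinetic dominance ratio between two barriers
#'
#' Ratio of the population able to cross only the lower barrier (kinetic
#' energy in `[barrier_lo, barrier_hi]`) to the population able to cross the
#' higher one (`> barrier_hi`):
#' `(S(lo) - S(hi)) / S(hi)` with `S` the [mb_survival()] function.
#'
#' @param barrier_lo,barrier_hi Barriers in kJ/mol with
#'   `0 <= barrier_lo < barrier_hi`.
#' @param config A [feasibility_config()].
#' @return Dimensionless population ratio.
#' @examples
#' dominance_ratio(218, 250)  # about 2.8e4 at 373.15 K: four orders of magnitude
#' @export
dominance_ratio <- function(barrier_lo, barrier_hi,
                            config = feasibility_config()) {
  if (barrier_lo < 0) stop("barriers must be non-negative")
  if (barrier_lo >= barrier_hi) {
    stop("dominance_ratio requires barrier_lo < barrier_hi")
  }
  s_lo <- mb_survival(barrier_lo, config)
  s_hi <- mb_survival(barrier_hi, config)
  (s_lo - s_hi) / s_hi
}

#' Thermodynamic rule-out filter
#'
#' Keeps reactions with `reaction_energy <= endo_tol`, i.e. removes the
#' endothermic ones under the thermodynamic-control assumption.
#'
#' @param net A [reaction_network()].
#' @param config A [feasibility_config()].
#' @return Character vector of surviving reaction ids.
#' @export
thermo_filter <- function(net, config = feasibility_config()) {
  stopifnot(inherits(net, "reaction_network"))
  rx <- network_reactions(net)
  rx$id[rx$reaction_energy <= config$endo_tol]
}

# Resolve a target side specification (SMILES strings, connectivity keys or
# compound ids) into a sorted vector of compound ids; unknown compounds map
# to NA.
.resolve_compounds <- function(net, spec) {
  vapply(spec, function(x) {
    if (x %in% names(net$compounds)) return(x)
    key <- if (startsWith(x, "v1|")) x else connectivity_key(parse_smiles(x))
    id <- unname(net$key_index[key])
    if (is.null(id) || is.na(id)) NA_character_ else id
  }, character(1), USE.NAMES = FALSE)
}

#' Assess a target reaction against an explored network
#'
#' Verdict logic: the target is `validated` when it is found in the network,
#' survives the endothermicity filter, and kinetically dominates every
#' surviving competitor that is more exothermic than itself (population
#' ratio at least `dominance_threshold` for each). It is `invalidated` when
#' it is absent from a *completed* exploration, is itself ruled out as
#' endothermic, or is dominated by a competitor. It is `inconclusive` when
#' the exploration was incomplete or backend errors exceeded the budget.
#' Competitors less exothermic than the target are ignored.
#'
#' @param net A [reaction_network()].
#' @param target List with `reactants` and `products`: character vectors of
#'   SMILES (or compound ids/keys). The reactant multiset must match exactly;
#'   every listed product must appear among the reaction's products (declared
#'   byproducts may be omitted).
#' @param config A [feasibility_config()].
#' @param exploration Optional list describing the exploration run:
#'   `complete` (logical), `n_errors` (integer). Defaults assume a complete,
#'   error-free exploration.
#' @return An object of class `verdict`: `status`, `target_found`,
#'   `target_id`, `target_barrier`, `target_energy`, `competitors` (data
#'   frame with reaction id, barrier, energy, ratio), `dominance_ratio`
#'   (minimum over competitors), `diagnostics`.
#' @export
assess <- function(net, target, config = feasibility_config(),
                   exploration = NULL) {
  stopifnot(inherits(net, "reaction_network"), is.list(target))
  if (is.null(exploration)) exploration <- list(complete = TRUE, n_errors = 0L)
  diag <- character(0)

  errors_ok <- exploration$n_errors <= config$error_budget
  if (!errors_ok) {
    diag <- c(diag, sprintf("backend errors (%d) exceeded budget (%d)",
                            exploration$n_errors, config$error_budget))
  }
  if (!isTRUE(exploration$complete)) {
    diag <- c(diag, "exploration incomplete (trial budget exhausted)")
  }

  rcids <- .resolve_compounds(net, target$reactants)
  pcids <- .resolve_compounds(net, target$products)
  rx <- network_reactions(net)

  target_id <- NA_character_
  if (!anyNA(rcids) && !anyNA(pcids)) {
    want_r <- paste(sort(rcids), collapse = "+")
    for (k in seq_len(nrow(rx))) {
      have_p <- strsplit(rx$products[k], "+", fixed = TRUE)[[1]]
      if (rx$reactants[k] == want_r && all(pcids %in% have_p)) {
        target_id <- rx$id[k]
        break
      }
    }
  }
  target_found <- !is.na(target_id)

  empty_comp <- data.frame(reaction = character(0), barrier = numeric(0),
                           energy = numeric(0), ratio = numeric(0))
  mk <- function(status, barrier = NA_real_, energy = NA_real_,
                 competitors = empty_comp, ratio = NA_real_) {
    structure(list(status = status, target_found = target_found,
                   target_id = target_id, target_barrier = barrier,
                   target_energy = energy, competitors = competitors,
                   dominance_ratio = ratio, diagnostics = diag),
              class = "verdict")
  }

  if (!target_found) {
    if (isTRUE(exploration$complete) && errors_ok) {
      diag <- c(diag, "target reaction not found in completed exploration")
      return(mk("invalidated"))
    }
    diag <- c(diag, "target reaction not found; exploration not definitive")
    return(mk("inconclusive"))
  }

  if (!errors_ok || !isTRUE(exploration$complete)) {
    # target observed, but the search cannot be trusted as exhaustive
    trow <- rx[rx$id == target_id, ]
    return(mk("inconclusive", trow$best_barrier, trow$reaction_energy))
  }

  survivors <- thermo_filter(net, config)
  trow <- rx[rx$id == target_id, ]
  if (!(target_id %in% survivors)) {
    diag <- c(diag, sprintf("target reaction endothermic (%.1f kJ/mol)",
                            trow$reaction_energy))
    return(mk("invalidated", trow$best_barrier, trow$reaction_energy))
  }

  comp <- rx[rx$id %in% survivors & rx$id != target_id &
             rx$reaction_energy < trow$reaction_energy, , drop = FALSE]
  if (nrow(comp) == 0L) {
    return(mk("validated", trow$best_barrier, trow$reaction_energy))
  }
  ratio <- vapply(seq_len(nrow(comp)), function(k) {
    if (comp$best_barrier[k] <= trow$best_barrier) return(0)
    dominance_ratio(trow$best_barrier, comp$best_barrier[k], config)
  }, numeric(1))
  competitors <- data.frame(reaction = comp$id, barrier = comp$best_barrier,
                            energy = comp$reaction_energy, ratio = ratio,
                            row.names = NULL)
  status <- if (all(ratio >= config$dominance_threshold)) "validated"
            else "invalidated"
  if (status == "invalidated") {
    diag <- c(diag, "target dominated by a more exothermic competitor")
  }
  mk(status, trow$best_barrier, trow$reaction_energy, competitors, min(ratio))
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s%s\n", x$status,
              if (x$target_found)
                sprintf(" (barrier %.1f kJ/mol, reaction energy %.1f kJ/mol)",
                        x$target_barrier, x$target_energy)
              else " (target not found)"))
  if (nrow(x$competitors) > 0) {
    cat(sprintf("  %d more-exothermic competitor(s); min dominance ratio %.3g\n",
                nrow(x$competitors), x$dominance_ratio))
  }
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}
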