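# Compute-budget arithmetic and size-scaling model for exploration planning.
#
# With semiempirical energies a single elementary-step trial costs about 20
# CPU seconds, so one core probes 604800 / 20 = 30240 trials in a week and
# 100 cores about 3 million. Cost per trial scales roughly quadratically
# with system size, and the bimolecular trial count is itself quadratic in
# system size, so doubling the reactant sizes cuts one week's reaction
# coverage by 2^(2+2) = 16.

#' Compute-budget model
#'
#' @param sec_per_trial Average CPU seconds per elementary-step trial
#'   (default 20, averaged over successful and unsuccessful trials alike).
#' @param cores Number of CPU cores (default 1).
#' @param walltime Wall-clock budget in seconds (default one week,
#'   604800 s).
#' @param cost_scaling_exponent Scaling exponent of per-trial cost with
#'   system size (default 2, semiempirical energies and gradients).
#' @param trial_scaling_exponent Scaling exponent of the trial count with
#'   system size (default 2, bimolecular atom-pair enumeration).
#' @param success_fraction Optional informational fraction of trials that
#'   discover a step; not asserted anywhere, configurable because it is an
#'   empirical property of the exploration software.
#' @return An object of class `budget_model`.
#' @export
budget_model <- function(sec_per_trial = 20, cores = 1L, walltime = 604800,
                         cost_scaling_exponent = 2,
                         trial_scaling_exponent = 2,
                         success_fraction = NULL) {
  stopifnot(sec_per_trial > 0, cores >= 1, walltime >= 0,
            cost_scaling_exponent > 0, trial_scaling_exponent > 0)
  structure(list(sec_per_trial = sec_per_trial, cores = as.integer(cores),
                 walltime = walltime,
                 cost_scaling_exponent = cost_scaling_exponent,
                 trial_scaling_exponent = trial_scaling_exponent,
                 success_fraction = success_fraction),
            class = "budget_model")
}

#' Number of elementary-step trials affordable within a budget
#'
#' `floor(cores * walltime / sec_per_trial)`.
#'
#' @param model A [budget_model()].
#' @return Integer-valued numeric trial count.
#' @examples
#' trials_in_budget(budget_model())              # 30240: one core, one week
#' trials_in_budget(budget_model(cores = 100))   # 3024000: about 3 million
#' @export
trials_in_budget <- function(model = budget_model()) {
  stopifnot(inherits(model, "budget_model"))
  floor(model$cores * model$walltime / model$sec_per_trial)
}

#' Coverage penalty for larger systems
#'
#' Growing both reactants by `size_ratio` multiplies the per-trial cost by
#' `size_ratio^cost_scaling_exponent` and the trial count by
#' `size_ratio^trial_scaling_exponent`, so the fraction of reaction space
#' covered in a fixed budget shrinks by the product:
#' `size_ratio^(cost + trial exponents)`. Doubling the system size with the
#' default quadratic/quadratic model costs a factor of 16.
#'
#' @param size_ratio Ratio of new to old system size (> 0).
#' @param model A [budget_model()].
#' @return Dimensionless coverage factor.
#' @examples
#' coverage_factor(2)  # 16
#' @export
coverage_factor <- function(size_ratio, model = budget_model()) {
  stopifnot(size_ratio > 0)
  size_ratio^(model$cost_scaling_exponent + model$trial_scaling_exponent)
}

#' Does a planned exploration fit the budget?
#'
#' @param model A [budget_model()].
#' @param planned_trials Number of trials the exploration would run.
#' @return A list: `fits` (logical), `capacity`, `utilization`
#'   (planned/capacity) and a human-readable `advisory` (which also notes
#'   that switching to DFT energies typically costs another factor of 100 to
#'   1000, hardware- and system-dependent).
#' @export
feasibility_report <- function(model = budget_model(), planned_trials) {
  stopifnot(planned_trials >= 0)
  capacity <- trials_in_budget(model)
  fits <- planned_trials <= capacity
  utilization <- if (capacity > 0) planned_trials / capacity
                 else as.numeric(planned_trials > 0) * Inf
  advisory <- sprintf(
    paste0("%.0f of %.0f affordable trials (%.1f%% utilization) on %d core(s) ",
           "over %.2f days at %.0f s/trial; %s. Note: DFT-quality energies ",
           "typically slow each trial down by a factor of 100 to 1000."),
    planned_trials, capacity, 100 * min(utilization, 9.99), model$cores,
    model$walltime / 86400, model$sec_per_trial,
    if (fits) "the exploration fits the budget"
    else "the exploration does NOT fit the budget")
  list(fits = fits, capacity = capacity, utilization = utilization,
       advisory = advisory)
}
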