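#' Workload reduction from CAD as a pre-screening reader
#'
#' When CAD triages scans before any radiologist involvement, it rules out
#' a fraction of the nodule-free scans; scans with a nodule are always
#' passed on. The expected fraction of the radiologist's workload removed
#' is therefore `ruleout_fraction * (1 - prevalence)`.
#'
#' With the published inputs (nodule prevalence 22-51% at baseline
#' screening, 80% rule-out of nodule-free scans) this gives reductions of
#' 0.624 (best case, low prevalence) and 0.392 (worst case).
#'
#' @param prevalence Proportion of scans with at least one detected nodule.
#' @param ruleout_fraction Proportion of nodule-free scans the CAD rules out.
#' @return The workload-reduction proportion.
#' @examples
#' workload_reduction(0.22, 0.80) # 0.624
#' workload_reduction(0.51, 0.80) # 0.392
#' @export
workload_reduction <- function(prevalence, ruleout_fraction) {
  assert_proportion(prevalence, "prevalence")
  assert_proportion(ruleout_fraction, "ruleout_fraction")
  ruleout_fraction * (1 - prevalence)
}

#' Saved reading time for a pre-screening scenario
#'
#' Applies a workload-reduction fraction to the pooled reading time without
#' CAD: a scan that is never read saves its whole reading time, so the
#' expected per-case saving is `reduction * mean`, and the 95% CI is the
#' reduction applied to the CI bounds of the pooled time. No uncertainty on
#' prevalence or the rule-out fraction is propagated; that uncertainty is
#' represented by the best/worst scenario pair instead.
#'
#' @param no_cad_pooled A `pooled_estimate` for reading time without CAD.
#' @param reduction Workload-reduction proportion (see
#'   [workload_reduction()]).
#' @param label Scenario label, e.g. `"best_case"` or `"worst_case"`.
#' @return A tibble of class `prescreen_scenario` with columns `label`,
#'   `workload_reduction`, `saved_time_s`, `ci_lo`, `ci_hi` (all unrounded
#'   seconds) plus their display-rounded integer counterparts
#'   `saved_time_display`, `ci_lo_display`, `ci_hi_display`.
#' @examples
#' pooled <- pooled_from_printed(162, 111, 212, k_studies = 5)
#' scenario_saved_time(pooled, 0.62, "best_case")
#' @export
scenario_saved_time <- function(no_cad_pooled, reduction, label = "scenario") {
  stopifnot(inherits(no_cad_pooled, "pooled_estimate"))
  assert_proportion(reduction, "reduction")
  saved <- reduction * no_cad_pooled$mean
  lo <- reduction * no_cad_pooled$ci_lo
  hi <- reduction * no_cad_pooled$ci_hi
  out <- tibble::tibble(
    label = label,
    workload_reduction = reduction,
    saved_time_s = saved,
    ci_lo = lo,
    ci_hi = hi,
    saved_time_display = round_half_up(saved, 0),
    ci_lo_display = round_half_up(lo, 0),
    ci_hi_display = round_half_up(hi, 0)
  )
  structure(out, class = unique(c("prescreen_scenario", class(out))))
}

#' Best- and worst-case pre-screening scenarios
#'
#' Builds the two bracketing scenarios from a prevalence range: the best
#' case uses the low prevalence (most scans nodule-free, largest
#' reduction), the worst case the high prevalence.
#'
#' @inheritParams scenario_saved_time
#' @param scenario_config A list with `prevalence_lo`, `prevalence_hi`,
#'   `ruleout_fraction` (as returned in [load_settings()]`$scenario`).
#' @param use_printed_worst_point If TRUE, overrides the worst-case
#'   displayed point value with the published 64 s (the published table
#'   prints 64 where the scaling rule gives 0.39 x 162 = 63.18 -> 63);
#'   the unrounded value is kept as computed either way. Default FALSE.
#' @param reduction_policy `"percent_rounded"` (default) rounds each
#'   reduction half-up to a whole percent before applying it, matching
#'   the published derivation (62% and 39%, giving the printed scenario
#'   CIs exactly); `"exact"` uses the unrounded fractions (0.624, 0.392).
#' @return A `prescreen_scenario` tibble with rows `best_case`,
#'   `worst_case`.
#' @export
prescreen_scenarios <- function(no_cad_pooled, scenario_config,
                                use_printed_worst_point = FALSE,
                                reduction_policy = c("percent_rounded",
                                                     "exact")) {
  reduction_policy <- match.arg(reduction_policy)
  adj <- function(x) {
    if (reduction_policy == "percent_rounded") round_half_up(x, 2) else x
  }
  red_best <- adj(workload_reduction(scenario_config$prevalence_lo,
                                     scenario_config$ruleout_fraction))
  red_worst <- adj(workload_reduction(scenario_config$prevalence_hi,
                                      scenario_config$ruleout_fraction))
  out <- dplyr::bind_rows(
    scenario_saved_time(no_cad_pooled, red_best, "best_case"),
    scenario_saved_time(no_cad_pooled, red_worst, "worst_case")
  )
  if (use_printed_worst_point) {
    out$saved_time_display[out$label == "worst_case"] <- 64
  }
  structure(out, class = unique(c("prescreen_scenario", class(out))))
}
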