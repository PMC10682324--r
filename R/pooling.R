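#' Convert a median and interquartile range to an approximate mean and SD
#'
#' Several reading-time studies report medians with IQRs rather than means
#' with SDs. To pool them on a common scale we use the Wan-type moment
#' estimators: mean approximated by `(q1 + median + q3) / 3`, and SD by
#' `(q3 - q1)` divided by 1.35 when the sample size is unknown, or by the
#' sample-size-dependent Wan denominator
#' `2 * qnorm((0.75 n - 0.125) / (n + 0.25))` when `n` is given.
#'
#' @param median Reported median (seconds).
#' @param q1,q3 First and third quartiles.
#' @param n Optional sample size behind the summary.
#' @return A named list with elements `mean` and `sd`.
#' @examples
#' median_iqr_to_mean_sd(160, 96, 245)
#' @export
median_iqr_to_mean_sd <- function(median, q1, q3, n = NULL) {
  assert_scalar_number(median, "median")
  assert_scalar_number(q1, "q1")
  assert_scalar_number(q3, "q3")
  if (q1 > q3) stop("`q1` must be <= `q3`", call. = FALSE)
  if (!(q1 <= median && median <= q3)) {
    stop("`median` must lie between `q1` and `q3`", call. = FALSE)
  }
  mean_est <- (q1 + median + q3) / 3
  denom <- if (is.null(n) || is.na(n)) {
    1.35
  } else {
    assert_scalar_number(n, "n", lower = 1)
    2 * stats::qnorm((0.75 * n - 0.125) / (n + 0.25))
  }
  sd_est <- (q3 - q1) / denom
  if (sd_est == 0) {
    warning("degenerate IQR (q1 == q3): sd estimated as 0", call. = FALSE)
  }
  list(mean = mean_est, sd = sd_est)
}

#' Convert a confidence interval to a standard error
#'
#' Assumes a symmetric normal-theory interval: `se = (hi - lo) / (2 z)`,
#' with `z = qnorm(1 - (1 - level) / 2)` (1.959964 at 95%).
#'
#' @param ci_lo,ci_hi Interval bounds (any sign; must be ordered).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return The implied standard error.
#' @examples
#' ci_to_se(39, 44) # ~1.276
#' @export
ci_to_se <- function(ci_lo, ci_hi, level = 0.95) {
  assert_scalar_number(ci_lo, "ci_lo")
  assert_scalar_number(ci_hi, "ci_hi")
  if (ci_lo > ci_hi) stop("`ci_lo` must be <= `ci_hi`", call. = FALSE)
  if (level <= 0 || level >= 1) {
    stop("`level` must lie strictly in (0, 1)", call. = FALSE)
  }
  se <- (ci_hi - ci_lo) / (2 * stats::qnorm(1 - (1 - level) / 2))
  if (se == 0) warning("zero-width interval: se is 0", call. = FALSE)
  se
}

new_pooled_estimate <- function(mean, ci_lo, ci_hi, k_studies, tau2 = NA_real_,
                                q_stat = NA_real_, method = "unweighted") {
  stopifnot(ci_lo <= mean + 1e-12, mean <= ci_hi + 1e-12, k_studies >= 1)
  structure(
    list(mean = mean, ci_lo = ci_lo, ci_hi = ci_hi,
         k_studies = as.integer(k_studies), tau2 = tau2, q_stat = q_stat,
         method = method),
    class = "pooled_estimate"
  )
}

#' Construct a pooled estimate directly from published values
#'
#' The published pooled reading times (e.g. 162 s, 95% CI 111-212, for
#' reading without CAD) cannot be re-derived exactly because the original
#' pooling weights are not reported. For replication runs they are treated
#' as authoritative inputs and wrapped in a `pooled_estimate` tagged
#' `method = "printed"`.
#'
#' @param mean,ci_lo,ci_hi Published pooled mean and 95% CI (seconds).
#' @param k_studies Number of studies behind the published value.
#' @return A `pooled_estimate`.
#' @export
pooled_from_printed <- function(mean, ci_lo, ci_hi, k_studies = 1L) {
  new_pooled_estimate(mean, ci_lo, ci_hi, k_studies, method = "printed")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (%s, k = %d): %.2f s (95%% CI: %.2f-%.2f)\n",
              x$method, x$k_studies, x$mean, x$ci_lo, x$ci_hi))
  if (!is.na(x$tau2)) {
    cat(sprintf("  tau^2 = %.3f, Q = %.3f\n", x$tau2, x$q_stat))
  }
  invisible(x)
}

#' Pool study-level effects with a random-effects model
#'
#' Two pooling methods are exposed, plus a fixed-effect reference:
#'
#' * `"dersimonian_laird"`: the moment-based random-effects estimator.
#'   With inverse-variance weights `w_i = 1/se_i^2` and the fixed-effect
#'   mean `ybar_FE`, the heterogeneity statistic is
#'   `Q = sum(w_i (y_i - ybar_FE)^2)`, the between-study variance
#'   `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and the
#'   pooled mean uses weights `1/(se_i^2 + tau2)` with a normal 95% CI.
#'   Requires a standard error for every effect.
#' * `"unweighted"`: arithmetic mean of the study estimates with a
#'   t-based 95% CI on the k estimates. Used by default because some
#'   published observations carry no dispersion at all, making a complete
#'   inverse-variance pool impossible without imputation.
#' * `"fixed_effect"`: inverse-variance mean with a normal CI (no tau2).
#'
#' @param effects A data frame with columns `estimate` and (for weighted
#'   methods) `se`; an optional `study_label` is carried through.
#' @param method Pooling method (see above).
#' @return A `pooled_estimate` with mean, 95% CI, `k_studies`, and for
#'   DerSimonian-Laird also `tau2` and `q_stat`.
#' @examples
#' eff <- data.frame(estimate = c(70, 80, 85), se = c(8, 9, 10))
#' pool_random_effects(eff, method = "dersimonian_laird")
#' @export
pool_random_effects <- function(effects,
                                method = c("unweighted", "dersimonian_laird",
                                           "fixed_effect")) {
  method <- match.arg(method)
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) == 0) {
    stop("cannot pool an empty set of effects", call. = FALSE)
  }
  y <- effects$estimate
  if (anyNA(y)) stop("effect estimates must not be missing", call. = FALSE)
  k <- length(y)
  z <- stats::qnorm(0.975)

  if (method == "unweighted") {
    m <- mean(y)
    if (k == 1) {
      warning("single effect: unweighted CI is degenerate", call. = FALSE)
      return(new_pooled_estimate(m, m, m, 1L, method = method))
    }
    half <- stats::qt(0.975, df = k - 1) * stats::sd(y) / sqrt(k)
    return(new_pooled_estimate(m, m - half, m + half, k, method = method))
  }

  se <- effects$se
  if (is.null(se) || anyNA(se)) {
    stop("method '", method, "' requires a standard error for every ",
         "effect; supply or impute the missing se values, or use ",
         "method = 'unweighted'", call. = FALSE)
  }
  if (any(se <= 0)) stop("standard errors must be > 0", call. = FALSE)
  w <- 1 / se^2
  y_fe <- sum(w * y) / sum(w)

  if (method == "fixed_effect") {
    se_fe <- sqrt(1 / sum(w))
    return(new_pooled_estimate(y_fe, y_fe - z * se_fe, y_fe + z * se_fe, k,
                               tau2 = 0, method = method))
  }

  q_stat <- sum(w * (y - y_fe)^2)
  tau2 <- if (k == 1) 0 else {
    max(0, (q_stat - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  w_star <- 1 / (se^2 + tau2)
  m <- sum(w_star * y) / sum(w_star)
  se_pooled <- sqrt(1 / sum(w_star))
  new_pooled_estimate(m, m - z * se_pooled, m + z * se_pooled, k,
                      tau2 = tau2, q_stat = q_stat, method = method)
}

# Per-study effect extraction ------------------------------------------
#
# Reduces corpus rows to one (estimate, se) pair per study for a given arm.
# Medians/IQRs are converted with the Wan-type estimators; difference CIs
# are converted to SEs; arm-level SEs need a per-row `n_scans` column
# (present in simulated corpora, absent from the published table). Readers
# within a study are averaged so one cohort enters the pool once.

arm_value <- function(row, arm, n) {
  central <- row[[paste0(arm, "_central")]]
  kind <- row[[paste0(arm, "_dispersion_kind")]]
  if (kind == "iqr_bounds") {
    conv <- median_iqr_to_mean_sd(central, row[[paste0(arm, "_lo")]],
                                  row[[paste0(arm, "_hi")]], n = n)
    est <- conv$mean
    sd_arm <- conv$sd
  } else {
    est <- central
    sd_arm <- if (kind == "sd") row[[paste0(arm, "_dispersion")]] else NA_real_
  }
  se <- if (!is.na(sd_arm) && !is.null(n) && !is.na(n)) {
    sd_arm / sqrt(n)
  } else {
    NA_real_
  }
  list(estimate = est, se = se, sd = sd_arm)
}

row_effect <- function(row, arm) {
  n <- if ("n_scans" %in% names(row)) row$n_scans else NA_real_
  no <- arm_value(row, "no_cad", n)
  with <- arm_value(row, "with_cad", n)
  switch(
    arm,
    no_cad = tibble::tibble(estimate = no$estimate, se = no$se),
    with_cad_concurrent = tibble::tibble(estimate = with$estimate,
                                         se = with$se),
    saved_time_concurrent = {
      diff <- if (!is.na(row$diff_seconds)) row$diff_seconds else {
        with$estimate - no$estimate
      }
      se <- if (!is.na(row$diff_ci_lo)) {
        ci_to_se(row$diff_ci_lo, row$diff_ci_hi)
      } else if (!is.na(no$se) && !is.na(with$se)) {
        sqrt(no$se^2 + with$se^2)
      } else {
        NA_real_
      }
      tibble::tibble(estimate = -diff, se = se)  # positive = time saved
    },
    stop("unknown arm '", arm, "'", call. = FALSE)
  )
}

#' Extract per-study effects for one pooling arm
#'
#' @param corpus An `rt_corpus` (see [load_corpus()]).
#' @param arm `"no_cad"`, `"with_cad_concurrent"`, or
#'   `"saved_time_concurrent"`. All three arms are restricted to
#'   concurrent-reader rows, matching the published pooled row; saved time
#'   is returned as a positive magnitude.
#' @param multi_reader Policy for several reader rows within one study:
#'   `"average_within_study"` (default; one cohort enters once) or
#'   `"treat_as_independent"`.
#' @param impute_missing_se If TRUE, missing standard errors are replaced
#'   by the largest observed SE in the arm (a conservative imputation that
#'   enables a complete inverse-variance pool). Default FALSE.
#' @return A tibble with columns `study_label`, `estimate`, `se`.
#' @export
extract_effects <- function(corpus, arm,
                            multi_reader = c("average_within_study",
                                             "treat_as_independent"),
                            impute_missing_se = FALSE) {
  multi_reader <- match.arg(multi_reader)
  corpus <- tibble::as_tibble(corpus)
  rows <- dplyr::filter(corpus, .data$reading_mode == "concurrent_reader")
  if (nrow(rows) == 0) {
    stop("no concurrent-reader observations for arm '", arm, "'",
         call. = FALSE)
  }
  eff <- dplyr::bind_cols(
    study_label = rows$study_label,
    purrr::map_dfr(seq_len(nrow(rows)), function(i) row_effect(rows[i, ], arm))
  )
  if (multi_reader == "average_within_study") {
    eff <- eff |>
      dplyr::group_by(.data$study_label) |>
      dplyr::summarise(
        # mean of r reader means; SE of that mean assuming independent readers
        se = if (dplyr::n() == 1) .data$se[1] else {
          if (anyNA(.data$se)) NA_real_ else sqrt(sum(.data$se^2)) / dplyr::n()
        },
        estimate = mean(.data$estimate),
        .groups = "drop"
      ) |>
      dplyr::select("study_label", "estimate", "se")
  }
  if (impute_missing_se && anyNA(eff$se)) {
    if (all(is.na(eff$se))) {
      stop("cannot impute standard errors: none observed in this arm",
           call. = FALSE)
    }
    eff$se[is.na(eff$se)] <- max(eff$se, na.rm = TRUE)
  }
  eff
}

#' Pool reading times (or time savings) across the corpus
#'
#' Extracts one effect per study for the requested arm (converting
#' median/IQR summaries and CIs as needed, averaging multi-reader rows
#' within a study) and pools with [pool_random_effects()].
#'
#' @inheritParams extract_effects
#' @inheritParams pool_random_effects
#' @return A `pooled_estimate`.
#' @examples
#' pool_reading_times(load_corpus("table1"), "saved_time_concurrent")
#' @export
pool_reading_times <- function(corpus, arm,
                               method = c("unweighted", "dersimonian_laird",
                                          "fixed_effect"),
                               multi_reader = "average_within_study",
                               impute_missing_se = FALSE) {
  method <- match.arg(method)
  eff <- extract_effects(corpus, arm, multi_reader = multi_reader,
                         impute_missing_se = impute_missing_se)
  pool_random_effects(eff, method = method)
}

#' Range of reading-time increase with CAD as a second reader
#'
#' In second-reader mode the radiologist reads unaided first, so CAD always
#' adds time; the summary of interest is the min-max range of the reported
#' increases.
#'
#' @param corpus An `rt_corpus`.
#' @return A named list with `min_increase` and `max_increase` (seconds).
#' @examples
#' summarize_second_reader(load_corpus("table1")) # 33 to 41 s
#' @export
summarize_second_reader <- function(corpus) {
  rows <- dplyr::filter(tibble::as_tibble(corpus),
                        .data$reading_mode == "second_reader",
                        !is.na(.data$diff_seconds))
  if (nrow(rows) == 0) {
    stop("no second-reader observations with a reported time difference",
         call. = FALSE)
  }
  list(min_increase = min(rows$diff_seconds),
       max_increase = max(rows$diff_seconds))
}
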