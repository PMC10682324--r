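#' Specify a simulated multi-study reader-timing corpus
#'
#' Defines the ground truth for a simulated corpus shaped like the
#' published evidence table: each study carries its own true time saving
#' drawn from `Normal(mu_saving_s, tau_between_study_s^2)` (between-study
#' heterogeneity), and each reader reads `scans_per_reader` scans whose
#' per-scan times scatter with SD `sigma_within_s` around the study means.
#' Defaults mirror the magnitudes seen in the published corpus: ~160 s
#' unaided reading, ~77 s saved by concurrent CAD, between-study SD 25 s,
#' within-study per-scan SD 40 s, 6 studies of one reader x 100 scans.
#'
#' @param n_studies Number of studies.
#' @param readers_per_study Readers per study (each becomes a corpus row).
#' @param scans_per_reader Scans timed per reader and arm.
#' @param mu_no_cad_s True mean reading time without CAD, seconds.
#' @param mu_saving_s True mean time saved by CAD, seconds.
#' @param tau_between_study_s Between-study SD of the true saving, seconds.
#' @param sigma_within_s Within-study per-scan SD, seconds.
#' @param distribution Per-scan time distribution: `"normal"` or
#'   `"lognormal"` (moment-matched so the stated means and SDs hold on the
#'   natural scale, reproducing the right skew of real reading times).
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   spec including the seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_studies = 6, readers_per_study = 1,
                            scans_per_reader = 100, mu_no_cad_s = 160,
                            mu_saving_s = 77, tau_between_study_s = 25,
                            sigma_within_s = 40,
                            distribution = c("normal", "lognormal"),
                            seed = 1L) {
  distribution <- match.arg(distribution)
  for (f in c("n_studies", "readers_per_study", "scans_per_reader")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 ||
        v != as.integer(v)) {
      stop("`", f, "` must be a positive integer", call. = FALSE)
    }
  }
  assert_scalar_number(mu_no_cad_s, "mu_no_cad_s", lower = 0)
  assert_scalar_number(mu_saving_s, "mu_saving_s", lower = 0)
  assert_scalar_number(tau_between_study_s, "tau_between_study_s", lower = 0)
  assert_scalar_number(sigma_within_s, "sigma_within_s", lower = 0)
  if (mu_saving_s >= mu_no_cad_s) {
    stop("`mu_saving_s` must be smaller than `mu_no_cad_s`", call. = FALSE)
  }
  structure(
    list(n_studies = as.integer(n_studies),
         readers_per_study = as.integer(readers_per_study),
         scans_per_reader = as.integer(scans_per_reader),
         mu_no_cad_s = mu_no_cad_s, mu_saving_s = mu_saving_s,
         tau_between_study_s = tau_between_study_s,
         sigma_within_s = sigma_within_s, distribution = distribution,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

draw_times <- function(n, mean, sd, distribution) {
  if (sd == 0) return(rep(mean, n))
  if (distribution == "normal") {
    stats::rnorm(n, mean, sd)
  } else {
    # moment-matched lognormal: E = mean, SD = sd on the natural scale
    sdlog <- sqrt(log(1 + (sd / mean)^2))
    meanlog <- log(mean) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  }
}

#' Simulate a reader-timing corpus with known ground truth
#'
#' Draws per-scan reading times per the spec and summarises each reader
#' into a corpus row in the same schema as the published table (mean +- SD
#' per arm, signed difference), plus an `n_scans` column so standard
#' errors — and hence DerSimonian-Laird pooling — are available
#' downstream. Identical specs (including the seed) give identical
#' corpora.
#'
#' @param spec A [simulation_spec()].
#' @return An `rt_corpus` tibble with one row per study x reader and an
#'   extra `n_scans` column.
#' @examples
#' corpus <- simulate_corpus(simulation_spec(seed = 42))
#' pool_reading_times(corpus, "saved_time_concurrent",
#'                    method = "dersimonian_laird")
#' @export
simulate_corpus <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::local_seed(spec$seed)
  rows <- purrr::map_dfr(seq_len(spec$n_studies), function(s) {
    theta_s <- stats::rnorm(1, spec$mu_saving_s, spec$tau_between_study_s)
    purrr::map_dfr(seq_len(spec$readers_per_study), function(r) {
      t0 <- draw_times(spec$scans_per_reader, spec$mu_no_cad_s,
                       spec$sigma_within_s, spec$distribution)
      mu1 <- max(spec$mu_no_cad_s - theta_s, 1)  # times stay positive
      t1 <- draw_times(spec$scans_per_reader, mu1, spec$sigma_within_s,
                       spec$distribution)
      sd0 <- if (spec$scans_per_reader > 1) stats::sd(t0) else NA_real_
      sd1 <- if (spec$scans_per_reader > 1) stats::sd(t1) else NA_real_
      # degenerate (noiseless or single-scan) summaries carry no dispersion
      kind <- if (is.na(sd0) || sd0 == 0 || is.na(sd1) || sd1 == 0) {
        "none"
      } else {
        "sd"
      }
      if (kind == "none") sd0 <- sd1 <- NA_real_
      tibble::tibble(
        study_label = sprintf("Sim study %02d", s),
        country = "Simulated", modality = "low_dose_CT",
        cad_product = "SimCAD", reading_mode = "concurrent_reader",
        reader_label = if (spec$readers_per_study > 1) {
          sprintf("Reader %d", r)
        } else {
          NA_character_
        },
        no_cad_central = mean(t0), no_cad_dispersion_kind = kind,
        no_cad_dispersion = sd0, no_cad_lo = NA_real_, no_cad_hi = NA_real_,
        with_cad_central = mean(t1), with_cad_dispersion_kind = kind,
        with_cad_dispersion = sd1, with_cad_lo = NA_real_,
        with_cad_hi = NA_real_,
        diff_seconds = mean(t1) - mean(t0),
        diff_ci_lo = NA_real_, diff_ci_hi = NA_real_,
        p_value = NA_character_,
        n_scans = spec$scans_per_reader
      )
    })
  })
  # simulated differences can land on either side of zero; the sign
  # invariant is a property of the published table, not of noisy draws
  out <- tibble::as_tibble(rows)
  structure(out, class = unique(c("rt_corpus", class(out))))
}

#' Simulate a screening population passing through CAD triage
#'
#' Draws a screening population of `n_scans` CT scans: each scan carries a
#' nodule with probability `prevalence`; nodule-free scans are ruled out
#' by the pre-screening CAD with probability
#' `ruleout_sensitivity_for_negatives`, nodule-positive scans are never
#' ruled out. The expected ruled-out fraction is therefore
#' [workload_reduction()]`(prevalence, ruleout)`.
#'
#' @param n_scans Number of scans in the population.
#' @param prevalence Probability a scan has a detectable nodule.
#' @param ruleout_sensitivity_for_negatives Probability a nodule-free scan
#'   is ruled out by the CAD.
#' @param seed Integer seed.
#' @return A named list: `n_ruled_out`, `n_read_by_radiologist` (summing
#'   to `n_scans`).
#' @examples
#' simulate_screening_population(10000, 0.22, 0.80, seed = 7)
#' @export
simulate_screening_population <- function(n_scans, prevalence,
                                          ruleout_sensitivity_for_negatives,
                                          seed = 1L) {
  assert_scalar_number(n_scans, "n_scans", lower = 1)
  assert_proportion(prevalence, "prevalence")
  assert_proportion(ruleout_sensitivity_for_negatives,
                    "ruleout_sensitivity_for_negatives")
  withr::local_seed(seed)
  n_positive <- stats::rbinom(1, n_scans, prevalence)
  n_ruled_out <- stats::rbinom(1, n_scans - n_positive,
                               ruleout_sensitivity_for_negatives)
  list(n_ruled_out = n_ruled_out,
       n_read_by_radiologist = n_scans - n_ruled_out)
}
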