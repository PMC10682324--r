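#' Reading-time evidence corpus
#'
#' The corpus holds one row per published reader-timing observation: a study
#' arm-pair timed with and without DL-CAD assistance, in one of two reading
#' modes (`second_reader`: radiologist reads unaided, then reviews CAD marks;
#' `concurrent_reader`: CAD marks are shown during the read). Multi-reader
#' studies contribute one row per reader sharing a `study_label`.
#'
#' Time summaries come in three flavours, tagged by `*_dispersion_kind`:
#' `sd` (mean with standard deviation in `*_dispersion`), `iqr_bounds`
#' (median with quartiles in `*_lo`/`*_hi`), or `none` (a bare mean).
#' The signed time difference is stored as with-CAD minus no-CAD, so a
#' negative difference means time saved.
#'
#' The packaged fixture (`locator = "table1"`) transcribes the published
#' evidence table: 2 second-reader and 6 concurrent-reader observations.
#' One study (Jacobs) reports the dispersion of its time difference as an
#' IQR rather than a CI; that IQR is not representable in the `diff_ci_*`
#' columns and the difference CI is left missing for that row.
#'
#' @name corpus
NULL

corpus_columns <- c(
  "study_label", "country", "modality", "cad_product", "reading_mode",
  "reader_label",
  "no_cad_central", "no_cad_dispersion_kind", "no_cad_dispersion",
  "no_cad_lo", "no_cad_hi",
  "with_cad_central", "with_cad_dispersion_kind", "with_cad_dispersion",
  "with_cad_lo", "with_cad_hi",
  "diff_seconds", "diff_ci_lo", "diff_ci_hi", "p_value"
)

corpus_col_types <- readr::cols(
  .default = readr::col_guess(),
  study_label = readr::col_character(),
  country = readr::col_character(),
  modality = readr::col_character(),
  cad_product = readr::col_character(),
  reading_mode = readr::col_character(),
  reader_label = readr::col_character(),
  no_cad_central = readr::col_double(),
  no_cad_dispersion_kind = readr::col_character(),
  no_cad_dispersion = readr::col_double(),
  no_cad_lo = readr::col_double(),
  no_cad_hi = readr::col_double(),
  with_cad_central = readr::col_double(),
  with_cad_dispersion_kind = readr::col_character(),
  with_cad_dispersion = readr::col_double(),
  with_cad_lo = readr::col_double(),
  with_cad_hi = readr::col_double(),
  diff_seconds = readr::col_double(),
  diff_ci_lo = readr::col_double(),
  diff_ci_hi = readr::col_double(),
  p_value = readr::col_character()
)

#' Load a reading-time corpus
#'
#' Reads study-level reading-time observations from CSV or JSON (one record
#' per observation, in the documented schema) and validates them. The
#' special locator `"table1"` loads the packaged transcription of the
#' published evidence table.
#'
#' @param locator `"table1"`, or a path to a `.csv` or `.json` file.
#' @return A validated tibble of class `rt_corpus`, one row per observation.
#' @examples
#' corpus <- load_corpus("table1")
#' table(corpus$reading_mode)
#' @export
load_corpus <- function(locator = "table1") {
  path <- if (identical(locator, "table1")) {
    system.file("extdata", "table1.csv", package = "cadbreakeven",
                mustWork = TRUE)
  } else {
    locator
  }
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path)
    if (length(recs) == 0) tibble::tibble() else tibble::as_tibble(recs)
  } else {
    readr::read_csv(path, col_types = corpus_col_types,
                    na = c("", "NA"), progress = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("corpus at '", locator, "' is empty", call. = FALSE)
    raw <- tibble::as_tibble(stats::setNames(
      rep(list(logical(0)), length(corpus_columns)), corpus_columns))
  }
  validate_corpus(raw)
}

#' Write a corpus to CSV or JSON
#'
#' @param corpus An `rt_corpus` tibble (see [load_corpus()]).
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(corpus, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  } else {
    readr::write_csv(corpus, path, na = "")
  }
  invisible(path)
}

#' Validate a reading-time corpus
#'
#' Checks the schema and the domain invariants: positive times, coherent
#' dispersion encodings (`sd` requires a positive dispersion and no bounds;
#' `iqr_bounds` requires lo <= central <= hi), ordered difference CIs, and
#' the sign convention per reading mode (second reader increases reading
#' time, concurrent reader decreases it).
#'
#' @param corpus A data frame in the corpus schema.
#' @return The corpus as an `rt_corpus` tibble.
#' @export
validate_corpus <- function(corpus) {
  corpus <- tibble::as_tibble(corpus)
  missing_cols <- setdiff(corpus_columns, names(corpus))
  if (length(missing_cols) > 0) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # known columns first; extras (e.g. n_scans on simulated corpora) survive
  corpus <- corpus[c(corpus_columns, setdiff(names(corpus), corpus_columns))]
  if (nrow(corpus) == 0) {
    return(structure(corpus, class = c("rt_corpus", class(corpus))))
  }

  fail <- function(i, field, why) {
    stop(sprintf("corpus row %d (%s): invalid `%s`: %s",
                 i, corpus$study_label[i] %||% "?", field, why),
         call. = FALSE)
  }
  for (field in c("study_label", "reading_mode", "no_cad_central",
                  "with_cad_central", "no_cad_dispersion_kind",
                  "with_cad_dispersion_kind")) {
    bad <- which(is.na(corpus[[field]]))
    if (length(bad) > 0) fail(bad[1], field, "mandatory field is missing")
  }
  for (i in seq_len(nrow(corpus))) {
    row <- corpus[i, ]
    if (!row$reading_mode %in% c("second_reader", "concurrent_reader")) {
      fail(i, "reading_mode", paste0("unknown mode '", row$reading_mode, "'"))
    }
    if (!row$modality %in% c("CT", "low_dose_CT", NA)) {
      fail(i, "modality", paste0("unknown modality '", row$modality, "'"))
    }
    for (arm in c("no_cad", "with_cad")) {
      central <- row[[paste0(arm, "_central")]]
      kind <- row[[paste0(arm, "_dispersion_kind")]]
      disp <- row[[paste0(arm, "_dispersion")]]
      lo <- row[[paste0(arm, "_lo")]]
      hi <- row[[paste0(arm, "_hi")]]
      if (central <= 0) fail(i, paste0(arm, "_central"), "must be > 0")
      if (!kind %in% c("sd", "iqr_bounds", "ci_bounds", "none")) {
        fail(i, paste0(arm, "_dispersion_kind"),
             paste0("unknown kind '", kind, "'"))
      }
      if (kind == "sd") {
        if (is.na(disp) || disp <= 0) {
          fail(i, paste0(arm, "_dispersion"), "sd must be present and > 0")
        }
        if (!is.na(lo) || !is.na(hi)) {
          fail(i, paste0(arm, "_lo"), "bounds must be absent when kind is sd")
        }
      } else if (kind %in% c("iqr_bounds", "ci_bounds")) {
        if (is.na(lo) || is.na(hi)) {
          fail(i, paste0(arm, "_lo"), "bounds required for this kind")
        }
        if (!(lo <= central && central <= hi)) {
          fail(i, paste0(arm, "_lo"),
               sprintf("need lo <= central <= hi (got %g, %g, %g)",
                       lo, central, hi))
        }
      }
    }
    if (!is.na(row$diff_ci_lo) != !is.na(row$diff_ci_hi)) {
      fail(i, "diff_ci_lo", "difference CI must have both bounds or neither")
    }
    if (!is.na(row$diff_ci_lo) && row$diff_ci_lo > row$diff_ci_hi) {
      fail(i, "diff_ci_lo", "CI bounds out of order")
    }
    if (!is.na(row$diff_seconds)) {
      expected_sign <- if (row$reading_mode == "second_reader") 1 else -1
      if (sign(row$diff_seconds) != expected_sign) {
        fail(i, "diff_seconds",
             sprintf("%s rows must have a %s time difference",
                     row$reading_mode,
                     if (expected_sign > 0) "positive" else "negative"))
      }
    }
  }
  structure(corpus, class = unique(c("rt_corpus", class(corpus))))
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x

#' Load country, pricing, and scenario settings
#'
#' Reads the YAML (or JSON) configuration that drives the economic model:
#' country salary settings (hourly radiologist cost in local currency plus
#' an exchange rate to EUR), the three pricing models, the pre-screening
#' scenario parameters, and optionally the published pooled reading times
#' used in replication mode. The packaged default (`locator = "default"`)
#' reproduces the published configuration: hourly costs of EUR 196 (USA),
#' 127 (UK) and 45 (Poland); pay-per-use EUR 5.9-8.8 per case; a one-off
#' license of EUR 51,616; a subscription of EUR 20,000/year; nodule
#' prevalence 22-51% with an 80% rule-out of nodule-free scans.
#'
#' Derived EUR hourly costs are rounded half-up to whole euros, matching
#' the published convention (206 USD x 0.9518 = 196.07 -> 196).
#'
#' @param locator `"default"` or a path to a YAML/JSON settings file.
#' @return A list with elements `countries` (tibble: name,
#'   hourly_cost_local, currency_code, eur_per_local_unit, hourly_cost_eur),
#'   `pricing` (tibble: kind, price_eur, price_eur_lo, price_eur_hi),
#'   `scenario` (list: prevalence_lo, prevalence_hi, ruleout_fraction),
#'   `printed_pooled` (named list of [pooled_from_printed()] objects, or
#'   NULL), and `addons` (list or NULL).
#' @export
load_settings <- function(locator = "default") {
  path <- if (identical(locator, "default")) {
    system.file("extdata", "settings.yaml", package = "cadbreakeven",
                mustWork = TRUE)
  } else {
    locator
  }
  if (!file.exists(path)) stop("settings file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }

  countries <- purrr::map_dfr(cfg$countries, function(co) {
    for (f in c("name", "hourly_cost_local", "eur_per_local_unit")) {
      if (is.null(co[[f]])) {
        stop("country entry is missing `", f, "`", call. = FALSE)
      }
    }
    if (co$eur_per_local_unit <= 0) {
      stop("country ", co$name, ": exchange rate must be > 0", call. = FALSE)
    }
    if (co$hourly_cost_local <= 0) {
      stop("country ", co$name, ": hourly cost must be > 0", call. = FALSE)
    }
    tibble::tibble(
      name = co$name,
      hourly_cost_local = co$hourly_cost_local,
      currency_code = co$currency_code %||% "EUR",
      eur_per_local_unit = co$eur_per_local_unit,
      hourly_cost_eur = round_half_up(
        convert_to_eur(co$hourly_cost_local, co$eur_per_local_unit), 0)
    )
  })

  pricing <- purrr::map_dfr(cfg$pricing, function(pm) {
    kind <- pm$kind %||% stop("pricing entry is missing `kind`", call. = FALSE)
    if (!kind %in% c("pay_per_use", "one_off_license", "yearly_subscription")) {
      stop("unknown pricing kind '", kind, "'", call. = FALSE)
    }
    if (kind == "pay_per_use") {
      lo <- pm$price_eur_lo; hi <- pm$price_eur_hi
      if (is.null(lo) || is.null(hi) || lo <= 0 || hi <= 0 || lo > hi) {
        stop("pay_per_use needs 0 < price_eur_lo <= price_eur_hi",
             call. = FALSE)
      }
      tibble::tibble(kind = kind, price_eur = NA_real_,
                     price_eur_lo = lo, price_eur_hi = hi)
    } else {
      p <- pm$price_eur
      if (is.null(p) || p <= 0) {
        stop(kind, " needs a positive `price_eur`", call. = FALSE)
      }
      tibble::tibble(kind = kind, price_eur = p,
                     price_eur_lo = NA_real_, price_eur_hi = NA_real_)
    }
  })

  scenario <- cfg$scenario
  if (!is.null(scenario)) {
    assert_proportion(scenario$prevalence_lo, "prevalence_lo")
    assert_proportion(scenario$prevalence_hi, "prevalence_hi")
    assert_proportion(scenario$ruleout_fraction, "ruleout_fraction")
    if (scenario$prevalence_lo > scenario$prevalence_hi) {
      stop("scenario: prevalence_lo must be <= prevalence_hi", call. = FALSE)
    }
  }

  printed <- NULL
  if (!is.null(cfg$printed_pooled)) {
    printed <- purrr::map(cfg$printed_pooled, function(p) {
      pooled_from_printed(p$mean, p$ci_lo, p$ci_hi, k_studies = p$k %||% 1L)
    })
  }

  list(countries = countries, pricing = pricing, scenario = scenario,
       printed_pooled = printed, addons = cfg$addons)
}

#' Convert an amount in local currency to EUR
#'
#' @param amount Amount(s) in local currency units.
#' @param eur_per_local_unit Exchange rate: euros per one local unit.
#' @return `amount * eur_per_local_unit`, in EUR.
#' @examples
#' convert_to_eur(44000, 1.1731) # 51616.4
#' @export
convert_to_eur <- function(amount, eur_per_local_unit) {
  assert_scalar_number(eur_per_local_unit, "eur_per_local_unit")
  if (eur_per_local_unit <= 0) {
    stop("`eur_per_local_unit` must be > 0", call. = FALSE)
  }
  amount * eur_per_local_unit
}
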