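#' Break-even cost per case
#'
#' The monetary value of the radiologist time a CAD system saves on one
#' scan: `C = S * dt`, with the hourly salary cost `S` in EUR/h and the
#' saved time `dt` expressed in hours (`saved_time_s / 3600`). A
#' pay-per-use price at or below `C` is cost-saving.
#'
#' @param hourly_cost_eur Gross radiologist salary cost, EUR per hour.
#' @param saved_time_s Time saved per scan, seconds (0 allowed).
#' @return Break-even price per case, EUR.
#' @examples
#' per_case_cost(196, 77) # 4.19 EUR
#' @export
per_case_cost <- function(hourly_cost_eur, saved_time_s) {
  assert_scalar_number(hourly_cost_eur, "hourly_cost_eur", lower = 0)
  assert_scalar_number(saved_time_s, "saved_time_s", lower = 0)
  hourly_cost_eur * saved_time_s / 3600
}

#' Minimum workload to recoup a fixed price
#'
#' For a one-off license or a yearly subscription, break-even requires
#' enough CAD-assisted readings that the saved radiologist time pays for
#' the price: `W = P / (S * dt)`, i.e. the price divided by the per-case
#' saving. For a subscription, `W` is per year against the annual fee.
#'
#' @param price_eur Price `P` of the CAD system, EUR.
#' @param hourly_cost_eur Radiologist salary cost, EUR per hour.
#' @param saved_time_s Time saved per scan, seconds; must be > 0.
#' @return Minimum number of CT scans for break-even.
#' @examples
#' min_workload(51616, 196, 77) # ~12313 scans
#' @export
min_workload <- function(price_eur, hourly_cost_eur, saved_time_s) {
  assert_scalar_number(price_eur, "price_eur", lower = 0)
  if (price_eur == 0) stop("`price_eur` must be > 0", call. = FALSE)
  if (saved_time_s <= 0) {
    stop("break-even unreachable: saved time per scan must be > 0",
         call. = FALSE)
  }
  price_eur / per_case_cost(hourly_cost_eur, saved_time_s)
}

#' Propagate a saved-time confidence interval to cost or workload
#'
#' Both transforms are monotone in the saved time `dt`, so the CI maps
#' bound-to-bound: cost `C = S dt / 3600` is increasing (image keeps the
#' order), workload `W = P / (S dt)` is decreasing (bounds swap). The
#' interval is always returned ascending, so the point estimate computed
#' from the central `dt` lies inside it.
#'
#' @param transform `"cost"` or `"workload"`.
#' @param hourly_cost_eur Radiologist salary cost, EUR/h.
#' @param saved_time_ci Length-2 numeric: the 95% CI of saved time, seconds.
#' @param price_eur Price in EUR (required for `"workload"`).
#' @return Named numeric of length 2: `ci_lo`, `ci_hi`.
#' @examples
#' propagate_ci("cost", 196, c(47, 107))
#' propagate_ci("workload", 196, c(47, 107), price_eur = 51616)
#' @export
propagate_ci <- function(transform = c("cost", "workload"), hourly_cost_eur,
                         saved_time_ci, price_eur = NULL) {
  transform <- match.arg(transform)
  stopifnot(length(saved_time_ci) == 2)
  lo <- saved_time_ci[[1]]; hi <- saved_time_ci[[2]]
  if (lo > hi) stop("saved-time CI bounds out of order", call. = FALSE)
  if (transform == "cost") {
    out <- c(per_case_cost(hourly_cost_eur, lo),
             per_case_cost(hourly_cost_eur, hi))
  } else {
    if (is.null(price_eur)) {
      stop("`price_eur` is required for the workload transform",
           call. = FALSE)
    }
    if (lo <= 0) {
      stop("workload CI needs a strictly positive saved-time lower bound",
           call. = FALSE)
    }
    out <- c(min_workload(price_eur, hourly_cost_eur, hi),
             min_workload(price_eur, hourly_cost_eur, lo))
  }
  stats::setNames(sort(out), c("ci_lo", "ci_hi"))
}

#' Assemble the scenario rows of the break-even grid
#'
#' Builds the reading-mode/scenario table the grid is evaluated over: the
#' concurrent-reader pooled saving, the two pre-screening scenarios, and a
#' second-reader row carrying the (negative) saving implied by the
#' published range of reading-time increases.
#'
#' @param saved_concurrent A `pooled_estimate` of concurrent-reader saved
#'   time (positive seconds).
#' @param scenarios A `prescreen_scenario` tibble
#'   (see [prescreen_scenarios()]).
#' @param second_reader Optional list with `min_increase`/`max_increase`
#'   from [summarize_second_reader()]; represented as a negative saving.
#' @return A tibble with columns `scenario`, `saved_time_s`, `ci_lo`,
#'   `ci_hi` (unrounded seconds) and `display`, `display_lo`,
#'   `display_hi` (integer seconds used under the display-rounded
#'   policy; carries any display override set on the scenarios, such as
#'   the published worst-case 64 s).
#' @export
breakeven_rows <- function(saved_concurrent, scenarios,
                           second_reader = NULL) {
  stopifnot(inherits(saved_concurrent, "pooled_estimate"))
  rows <- tibble::tibble(
    scenario = "concurrent",
    saved_time_s = saved_concurrent$mean,
    ci_lo = saved_concurrent$ci_lo,
    ci_hi = saved_concurrent$ci_hi,
    display = round_half_up(saved_concurrent$mean, 0),
    display_lo = round_half_up(saved_concurrent$ci_lo, 0),
    display_hi = round_half_up(saved_concurrent$ci_hi, 0)
  )
  if (!is.null(scenarios)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      scenario = paste0("prescreen_",
                        sub("_case$", "", scenarios$label)),
      saved_time_s = scenarios$saved_time_s,
      ci_lo = scenarios$ci_lo,
      ci_hi = scenarios$ci_hi,
      display = scenarios$saved_time_display,
      display_lo = scenarios$ci_lo_display,
      display_hi = scenarios$ci_hi_display
    ))
  }
  if (!is.null(second_reader)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      scenario = "second_reader",
      saved_time_s = -second_reader$max_increase,
      ci_lo = -second_reader$max_increase,
      ci_hi = -second_reader$min_increase,
      display = round_half_up(-second_reader$max_increase, 0),
      display_lo = round_half_up(-second_reader$max_increase, 0),
      display_hi = round_half_up(-second_reader$min_increase, 0)
    ))
  }
  rows
}

#' Evaluate the full break-even grid
#'
#' One result per country x pricing model x reading-mode/scenario cell.
#' Pay-per-use cells report the break-even cost per case; one-off-license
#' and yearly-subscription cells report the minimum workload (total scans,
#' or scans per year for the subscription). Rows with non-positive saved
#' time (CAD as a second reader) are flagged `cost_saving = FALSE` and
#' carry no break-even value.
#'
#' @param countries Country tibble from [load_settings()].
#' @param pricing Pricing tibble from [load_settings()].
#' @param rows Scenario rows from [breakeven_rows()].
#' @param saved_time_policy `"display_rounded"` (default) feeds the
#'   display-rounded integer saved times into the arithmetic, matching how
#'   the published break-even table was computed from its printed saved
#'   times; `"unrounded"` uses full precision throughout.
#' @return A tibble of class `breakeven_grid`: one row per cell with
#'   columns `country`, `scenario`, `pricing_kind`, `price_eur`,
#'   `saved_time_s`, `cost_saving`, `cost_eur`/`cost_ci_lo`/`cost_ci_hi`,
#'   `workload_scans`/`workload_ci_lo`/`workload_ci_hi`, and
#'   `workload_period` (`"total"` or `"per_year"`).
#' @examples
#' s <- load_settings()
#' rows <- breakeven_rows(s$printed_pooled$saved_time_concurrent,
#'                        prescreen_scenarios(s$printed_pooled$no_cad,
#'                                            s$scenario))
#' grid <- evaluate_grid(s$countries, s$pricing, rows)
#' @export
evaluate_grid <- function(countries, pricing, rows,
                          saved_time_policy = c("display_rounded",
                                                "unrounded")) {
  saved_time_policy <- match.arg(saved_time_policy)
  if (nrow(countries) == 0 || nrow(pricing) == 0 || nrow(rows) == 0) {
    stop("countries, pricing, and rows must all be non-empty", call. = FALSE)
  }
  if (!all(c("display", "display_lo", "display_hi") %in% names(rows))) {
    rows$display <- round_half_up(rows$saved_time_s, 0)
    rows$display_lo <- round_half_up(rows$ci_lo, 0)
    rows$display_hi <- round_half_up(rows$ci_hi, 0)
  }
  cells <- tidyr::expand_grid(
    country = countries$name,
    scenario = rows$scenario,
    pricing_kind = pricing$kind
  )
  out <- purrr::pmap_dfr(cells, function(country, scenario, pricing_kind) {
    co <- countries[countries$name == country, ]
    pm <- pricing[pricing$kind == pricing_kind, ]
    rw <- rows[rows$scenario == scenario, ]
    if (saved_time_policy == "display_rounded") {
      dt <- rw$display; dlo <- rw$display_lo; dhi <- rw$display_hi
    } else {
      dt <- rw$saved_time_s; dlo <- rw$ci_lo; dhi <- rw$ci_hi
    }
    base <- tibble::tibble(
      country = country, scenario = scenario, pricing_kind = pricing_kind,
      price_eur = pm$price_eur, saved_time_s = dt,
      saved_time_ci_lo = dlo, saved_time_ci_hi = dhi,
      cost_saving = dt > 0,
      cost_eur = NA_real_, cost_ci_lo = NA_real_, cost_ci_hi = NA_real_,
      workload_scans = NA_real_, workload_ci_lo = NA_real_,
      workload_ci_hi = NA_real_, workload_period = NA_character_
    )
    if (dt <= 0) return(base)  # second reader: no break-even exists
    if (pricing_kind == "pay_per_use") {
      ci <- propagate_ci("cost", co$hourly_cost_eur, c(dlo, dhi))
      base$cost_eur <- per_case_cost(co$hourly_cost_eur, dt)
      base$cost_ci_lo <- ci[["ci_lo"]]; base$cost_ci_hi <- ci[["ci_hi"]]
    } else {
      ci <- propagate_ci("workload", co$hourly_cost_eur, c(dlo, dhi),
                         price_eur = pm$price_eur)
      base$workload_scans <- min_workload(pm$price_eur, co$hourly_cost_eur,
                                          dt)
      base$workload_ci_lo <- ci[["ci_lo"]]; base$workload_ci_hi <- ci[["ci_hi"]]
      base$workload_period <- if (pricing_kind == "yearly_subscription") {
        "per_year"
      } else {
        "total"
      }
    }
    base
  })
  structure(out, class = unique(c("breakeven_grid", class(out))))
}

#' Break-even workload as a function of saved time
#'
#' Evaluates `W(dt) = P / (S dt / 3600)` over a grid of saved times, the
#' curve underlying the published figure: the workload needed for
#' break-even falls as the per-scan saving grows, and lower-salary
#' settings need more scans at every saving.
#'
#' @param price_eur Price of the CAD system, EUR.
#' @param hourly_cost_eur Radiologist salary cost, EUR/h.
#' @param saved_time_grid Strictly positive saved times, seconds.
#' @return A tibble with columns `saved_time_s`, `min_workload_scans`.
#' @export
breakeven_curve <- function(price_eur, hourly_cost_eur, saved_time_grid) {
  if (length(saved_time_grid) == 0 || any(saved_time_grid <= 0)) {
    stop("`saved_time_grid` must contain only positive values",
         call. = FALSE)
  }
  tibble::tibble(
    saved_time_s = saved_time_grid,
    min_workload_scans = vapply(
      saved_time_grid,
      function(dt) min_workload(price_eur, hourly_cost_eur, dt),
      numeric(1))
  )
}
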