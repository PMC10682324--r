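#' Render the break-even results table in the published layout
#'
#' Formats a [evaluate_grid()] result with the published display
#' conventions: per-case costs in EUR to one decimal, workloads in
#' thousands of CT scans to one decimal, all rounding half-up, each cell
#' as `"point (95% CI: lo-hi)"`. Unrounded source values are kept
#' alongside every display string.
#'
#' @param grid A `breakeven_grid` from [evaluate_grid()].
#' @return A tibble with one row per (scenario, pricing model, country)
#'   cell: `scenario`, `pricing_kind`, `quantity` (`"cost_eur"` or
#'   `"workload_thousand"`), `country`, unrounded `value`/`ci_lo`/`ci_hi`
#'   (workloads already in thousands), display-rounded `point_display`/
#'   `ci_lo_display`/`ci_hi_display`, and the formatted `cell`.
#' @export
render_table2 <- function(grid) {
  if (nrow(grid) == 0) stop("no break-even results to render", call. = FALSE)
  rows <- dplyr::filter(grid, .data$cost_saving)
  long <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$pricing_kind == "pay_per_use") {
      tibble::tibble(
        scenario = r$scenario, pricing_kind = r$pricing_kind,
        quantity = "cost_eur", country = r$country,
        value = r$cost_eur, ci_lo = r$cost_ci_lo, ci_hi = r$cost_ci_hi
      )
    } else {
      tibble::tibble(
        scenario = r$scenario, pricing_kind = r$pricing_kind,
        quantity = "workload_thousand", country = r$country,
        value = r$workload_scans / 1000, ci_lo = r$workload_ci_lo / 1000,
        ci_hi = r$workload_ci_hi / 1000
      )
    }
  })
  long |>
    dplyr::mutate(
      point_display = round_half_up(.data$value, 1),
      ci_lo_display = round_half_up(.data$ci_lo, 1),
      ci_hi_display = round_half_up(.data$ci_hi, 1),
      cell = format_ci_cell(.data$value, .data$ci_lo, .data$ci_hi, 1)
    )
}

#' The published break-even table, as printed
#'
#' Returns the checked-in transcription of the published break-even table
#' (display-rounded points and 95% CI bounds for every country x pricing
#' x scenario cell), used as the replication snapshot by
#' [compare_table2()].
#'
#' @return A tibble with columns `scenario`, `pricing_kind`, `quantity`,
#'   `country`, `point`, `ci_lo`, `ci_hi`.
#' @export
table2_printed <- function() {
  path <- system.file("extdata", "table2_printed.csv",
                      package = "cadbreakeven", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccccddd", progress = FALSE)
}

#' Compare a rendered break-even table with the published snapshot
#'
#' Joins the rendered table cell-by-cell with the printed snapshot and
#' reports, for every cell, whether the display-rounded point and CI
#' bounds agree. Cells that differ form the discrepancy report — a
#' first-class output, since a handful of published pre-screening
#' workload cells cannot be reproduced from the published saved times.
#'
#' @param rendered Output of [render_table2()].
#' @param printed Snapshot tibble; defaults to [table2_printed()].
#' @return A tibble with one row per snapshot cell: identifiers, computed
#'   and printed values, and a logical `matches`.
#' @export
compare_table2 <- function(rendered, printed = table2_printed()) {
  merged <- dplyr::left_join(
    printed, rendered,
    by = c("scenario", "pricing_kind", "quantity", "country"),
    suffix = c("_printed", "")
  )
  if (anyNA(merged$point_display)) {
    miss <- merged[is.na(merged$point_display), ]
    stop("rendered table is missing cell(s): ",
         paste(sprintf("%s/%s/%s", miss$scenario, miss$pricing_kind,
                       miss$country), collapse = "; "),
         call. = FALSE)
  }
  merged |>
    dplyr::transmute(
      .data$scenario, .data$pricing_kind, .data$quantity, .data$country,
      computed_point = .data$point_display, printed_point = .data$point,
      computed_ci_lo = .data$ci_lo_display, printed_ci_lo = .data$ci_lo_printed,
      computed_ci_hi = .data$ci_hi_display, printed_ci_hi = .data$ci_hi_printed,
      matches = .data$point_display == .data$point &
        .data$ci_lo_display == .data$ci_lo_printed &
        .data$ci_hi_display == .data$ci_hi_printed
    )
}

#' Break-even workload curves by country
#'
#' Computes, and optionally plots, the minimum workload for break-even as
#' a function of saved reading time for each country (one-off license
#' price by default) — the published figure. Each curve is checked to be
#' strictly decreasing before anything is returned.
#'
#' @param countries Country tibble from [load_settings()].
#' @param price_eur Price the workload must recoup, EUR.
#' @param saved_time_grid Saved-time grid, seconds (positive).
#' @return A list with `data` (tibble: `country`, `saved_time_s`,
#'   `min_workload_scans`) and `plot` (a ggplot).
#' @export
render_fig1 <- function(countries, price_eur, saved_time_grid = 10:180) {
  if (nrow(countries) == 0) stop("no countries to plot", call. = FALSE)
  data <- purrr::map_dfr(seq_len(nrow(countries)), function(i) {
    co <- countries[i, ]
    curve <- breakeven_curve(price_eur, co$hourly_cost_eur, saved_time_grid)
    if (any(diff(curve$min_workload_scans) >= 0)) {
      stop("internal consistency failure: workload curve for ",
           co$name, " is not strictly decreasing", call. = FALSE)
    }
    dplyr::mutate(curve, country = co$name, .before = 1)
  })
  plot <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$saved_time_s,
                 y = .data$min_workload_scans / 1000,
                 colour = .data$country)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Saved reading time per scan (s)",
      y = "Minimum workload for break-even (thousand CT scans)",
      colour = NULL) +
    ggplot2::theme_minimal()
  list(data = data, plot = plot)
}
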