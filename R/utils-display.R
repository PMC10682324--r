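#' Round half away from zero
#'
#' Commercial rounding used for all display values: halves round up
#' (0.9625 EUR -> 1.0 at one decimal; 12,313 scans -> 12.3 thousand), unlike
#' [base::round()]'s round-half-to-even. Internal arithmetic is never rounded;
#' this is applied only when a value is formatted for a table or report.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.9625, 1) # 1.0
#' round_half_up(1.25, 1)   # 1.3 (base::round gives 1.2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge guards against representation error just below .5 (e.g. 49.749999...)
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Format a point estimate with its 95% confidence interval
#'
#' Produces the display convention used throughout the reports:
#' `"point (95% CI: lo-hi)"` with an en dash separating the bounds and all
#' three numbers rounded half-up to `digits` decimals.
#'
#' @param point,ci_lo,ci_hi Numeric scalars (vectors recycle).
#' @param digits Decimal places for display.
#' @return Character vector of formatted cells.
#' @seealso [parse_ci_cell()] for the inverse.
#' @export
format_ci_cell <- function(point, ci_lo, ci_hi, digits = 1) {
  fmt <- function(x) formatC(round_half_up(x, digits), format = "f",
                             digits = digits)
  sprintf("%s (95%% CI: %s–%s)", fmt(point), fmt(ci_lo), fmt(ci_hi))
}

#' Parse a formatted confidence-interval cell
#'
#' Inverse of [format_ci_cell()]: recovers the displayed point estimate and
#' CI bounds from a rendered table cell.
#'
#' @param cell Character vector of cells like `"4.2 (95% CI: 2.6-5.8)"`.
#' @return A tibble with columns `point`, `ci_lo`, `ci_hi`.
#' @export
parse_ci_cell <- function(cell) {
  pat <- "^\\s*(-?[0-9.]+)\\s*\\(95% CI:\\s*(-?[0-9.]+)–(-?[0-9.]+)\\)\\s*$"
  ok <- grepl(pat, cell)
  if (any(!ok)) {
    stop("cannot parse CI cell(s): ", paste(cell[!ok], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    point = as.numeric(sub(pat, "\\1", cell)),
    ci_lo = as.numeric(sub(pat, "\\2", cell)),
    ci_hi = as.numeric(sub(pat, "\\3", cell))
  )
}

# shared input checks ---------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop("`", name, "` must be a single number", call. = FALSE)
  }
  if (x < lower) {
    stop("`", name, "` must be >= ", lower, " (got ", x, ")", call. = FALSE)
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) {
    stop("`", name, "` must lie in [0, 1] (got ", x, ")", call. = FALSE)
  }
  invisible(x)
}
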