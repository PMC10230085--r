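#' Fit standard-curve dilution series
#'
#' Ordinary least squares of mean Ct on log10(concentration), one fit per
#' primer pair. Replicate Cts at the same concentration are averaged to a
#' single point per dilution before fitting.
#'
#' @param dilution_data Tibble with columns `concentration` (> 0) and
#'   `ct`, and optionally `primer_id` (one fit per primer) and
#'   `replicate`.
#' @return A tibble `primer_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @examples
#' d <- tibble::tibble(concentration = c(10, 2.5, 0.625, 0.15625),
#'                     ct = c(20, 22, 24, 26))
#' fit_dilution(d)  # slope -1/log10(2) = -3.3219
#' @export
fit_dilution <- function(dilution_data) {
  needed <- c("concentration", "ct")
  missing_cols <- setdiff(needed, names(dilution_data))
  if (length(missing_cols) > 0) {
    abort_refstab(
      paste0("`dilution_data` is missing column(s): ", toString(missing_cols)),
      "missing_columns"
    )
  }
  if (any(dilution_data$concentration <= 0)) {
    abort_refstab("Concentrations must be positive.", "invalid_concentration")
  }
  if (any(!is.finite(dilution_data$ct))) {
    abort_refstab("Cts must be finite.", "nonfinite_ct")
  }
  if (!"primer_id" %in% names(dilution_data)) {
    dilution_data$primer_id <- "primer1"
  }
  dilution_data %>%
    group_by(.data$primer_id, .data$concentration) %>%
    summarise(ct = mean(.data$ct), .groups = "drop") %>%
    group_by(.data$primer_id) %>%
    summarise(fit = list(fit_dilution_one(.data$concentration, .data$ct)),
              .groups = "drop") %>%
    tidyr::unnest("fit")
}

fit_dilution_one <- function(conc, ct) {
  if (length(unique(conc)) < 2) {
    abort_refstab("Need >= 2 distinct concentrations to fit a slope.",
                  "singular_fit")
  }
  x <- log10(conc)
  fit <- lm(ct ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = length(ct))
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = (10^(-1/m) - 1) * 100`, in percent: 100% means perfect doubling
#' per cycle (slope -3.3219). Vectorised. A non-negative slope is
#' biologically implausible; the value is still returned but a warning is
#' raised.
#'
#' @param slope Slope of Ct on log10(concentration); must be non-zero.
#' @return Efficiency in percent.
#' @examples
#' efficiency_from_slope(-3.321928)  # 100
#' efficiency_from_slope(-3.6)       # ~89.57
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) {
    abort_refstab("Slope must be non-zero.", "invalid_slope")
  }
  if (any(slope >= 0)) {
    warn("Non-negative slope: implausible assay; efficiency returned anyway.")
  }
  (10^(-1 / slope) - 1) * 100
}

#' Flag primer pairs against an efficiency QC band
#'
#' Marks `qc_pass = low <= efficiency_percent <= high` (inclusive
#' boundaries). Failing records are retained, flagged, not deleted.
#'
#' @param records Tibble with an `efficiency_percent` column (e.g. from
#'   [estimate_efficiency()]).
#' @param low,high QC band in percent; default 98–102.
#' @return `records` with a logical `qc_pass` column.
#' @export
qc_filter <- function(records, low = 98, high = 102) {
  if (low >= high) abort_refstab("Need `low` < `high`.", "invalid_band")
  if (!"efficiency_percent" %in% names(records)) {
    abort_refstab("`records` needs an `efficiency_percent` column.",
                  "missing_columns")
  }
  records %>%
    mutate(qc_pass = .data$efficiency_percent >= low &
             .data$efficiency_percent <= high)
}

#' Fit dilution series and QC amplification efficiencies in one step
#'
#' Convenience wrapper: [fit_dilution()], then [efficiency_from_slope()],
#' then [qc_filter()].
#'
#' @inheritParams fit_dilution
#' @inheritParams qc_filter
#' @return A tibble `primer_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`, `efficiency_percent`, `qc_pass`. `r_squared` is reported
#'   but not used as a filter.
#' @export
estimate_efficiency <- function(dilution_data, low = 98, high = 102) {
  fit_dilution(dilution_data) %>%
    mutate(efficiency_percent = efficiency_from_slope(.data$slope)) %>%
    qc_filter(low = low, high = high)
}
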