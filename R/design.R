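#' Harvest intensity
#'
#' Timber volume removed per hectare of net harvest area. Report tables
#' print the intensity rounded to the nearest whole cubic metre per hectare
#' (halves away from zero); the unrounded value is the default return.
#'
#' @param area_ha net harvest area, hectares (> 0).
#' @param volume_m3 total volume removed, cubic metres (>= 0).
#' @param rounded return the report-table integer value.
#' @return Intensity in cubic metres per hectare.
#' @examples
#' harvest_intensity(304, 15480, rounded = TRUE)  # 51
#' @export
harvest_intensity <- function(area_ha, volume_m3, rounded = FALSE) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    stop_invalid("harvest area must be positive (ha)")
  }
  if (any(volume_m3 < 0)) stop_invalid("volume must be non-negative (m3)")
  x <- volume_m3 / area_ha
  if (rounded) round_half_up(x) else x
}

#' Naive occupancy of a detector array
#'
#' Percentage of working detectors with at least one detection over the
#' survey, uncorrected for detection probability. Failed detectors (rows
#' that are entirely missing) are excluded from the denominator.
#'
#' @param counts a [nightly_counts()].
#' @param rounded round to the whole-percent report convention.
#' @return Percentage in `[0, 100]`.
#' @export
naive_occupancy <- function(counts, rounded = FALSE) {
  m <- counts$counts
  working <- rowSums(!is.na(m)) > 0
  if (!any(working)) stop_invalid("all detectors are masked")
  detected <- rowSums(m[working, , drop = FALSE] > 0, na.rm = TRUE) > 0
  x <- 100 * mean(detected)
  if (rounded) round_half_up(x) else x
}

#' Paired BACIPS design
#'
#' Density estimates for control/treatment site pairs before and after an
#' intervention. The replicate observation is the control-minus-treatment
#' density difference at a sampling period.
#'
#' @param pair pair labels.
#' @param control_before,treatment_before,control_after,treatment_after
#'   densities (individuals per ha, >= 0) per pair and period.
#' @return A `paired_design` data frame.
#' @export
paired_design <- function(pair, control_before, treatment_before,
                          control_after, treatment_after) {
  d <- data.frame(pair = as.character(pair),
                  control_before = control_before,
                  treatment_before = treatment_before,
                  control_after = control_after,
                  treatment_after = treatment_after)
  num <- as.matrix(d[, -1])
  if (any(!is.finite(num))) stop_invalid("every pair needs all four densities")
  if (any(num < 0)) stop_invalid("densities must be non-negative")
  structure(d, class = c("paired_design", "data.frame"))
}

#' BACIPS test of an intervention effect
#'
#' Before-After-Control-Impact Paired Series test: per pair, the
#' control-minus-treatment density difference is computed before
#' (`d_before`) and after (`d_after`) the intervention, and the paired t
#' statistic is taken on the per-pair change `d_after - d_before`
#' (df = pairs - 1, two-sided p). Under no intervention effect the paired
#' differences do not change systematically. A two-sample (Welch-free,
#' pooled-variance) comparison of the before and after differences is
#' available as `method = "two-sample"`.
#'
#' @param design a [paired_design()].
#' @param method `"paired"` (default) or `"two-sample"`.
#' @return A `bacips_test` list: `mean_change` (mean of `d_after -
#'   d_before`), `mean_difference` (mean control-minus-treatment difference
#'   across both periods), `t`, `df`, `p`, `n_pairs`, `method`. With zero
#'   variance in the changes the statistic is undefined (`t`, `p` = `NA`),
#'   except in the fully-degenerate no-change case where `t = 0`, `p = 1`.
#' @export
bacips_test <- function(design, method = c("paired", "two-sample")) {
  method <- match.arg(method)
  if (nrow(design) < 2L) stop_invalid("BACIPS test needs >= 2 pairs")
  d_before <- design$control_before - design$treatment_before
  d_after <- design$control_after - design$treatment_after
  delta <- d_after - d_before
  n <- length(delta)
  out <- list(mean_change = mean(delta),
              mean_difference = mean(c(d_before, d_after)),
              mean_diff_before = mean(d_before),
              mean_diff_after = mean(d_after),
              n_pairs = n, method = method)
  if (method == "paired") {
    out$df <- n - 1
    s <- stats::sd(delta)
    if (s == 0) {
      if (all(delta == 0)) { out$t <- 0; out$p <- 1 }
      else { out$t <- NA_real_; out$p <- NA_real_
             out$note <- "identical change in every pair: t undefined" }
    } else {
      out$t <- mean(delta) / (s / sqrt(n))
      out$p <- 2 * stats::pt(-abs(out$t), df = out$df)
    }
  } else {
    out$df <- 2 * n - 2
    v <- stats::var(d_before) + stats::var(d_after)
    if (v == 0) {
      if (mean(d_after) == mean(d_before)) { out$t <- 0; out$p <- 1 }
      else { out$t <- NA_real_; out$p <- NA_real_
             out$note <- "zero variance in both periods: t undefined" }
    } else {
      tt <- stats::t.test(d_after, d_before, var.equal = TRUE)
      out$t <- unname(tt$statistic); out$p <- tt$p.value
    }
  }
  structure(out, class = "bacips_test")
}

#' @export
print.bacips_test <- function(x, ...) {
  cat(sprintf("BACIPS %s t test: %d pairs\n", x$method, x$n_pairs))
  cat(sprintf("  mean control-minus-treatment difference: %.4f per ha\n",
              x$mean_difference))
  cat(sprintf("  mean change (after - before): %.4f per ha\n", x$mean_change))
  if (is.na(x$t)) {
    cat("  t undefined:", x$note, "\n")
  } else {
    cat(sprintf("  t = %.3f, df = %d, two-sided p = %.4f\n", x$t, x$df, x$p))
  }
  invisible(x)
}
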