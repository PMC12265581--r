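#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale; per sample,
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample - dCt_calibrator`, and
#' relative expression is `2^(-ddCt)`. Base 2 is used by default even when a
#' measured efficiency is available; passing per-gene efficiencies switches to
#' the efficiency-corrected ratio
#' `E_target^(dCt_target,cal-sample) / E_ref^(dCt_ref,cal-sample)`.
#'
#' @param ct Ct table: data frame with columns `sample`, `gene`, `ct` (and
#'   optionally `replicate`), e.g. from [simulate_qpcr()].
#' @param target,reference Gene labels for the target and the housekeeping
#'   reference.
#' @param calibrator_sample Sample whose expression defines 1.
#' @param efficiency Optional named numeric `c(target = , reference = )` of
#'   amplification efficiencies for the efficiency-corrected variant.
#' @param drop_outliers If `TRUE`, within each (sample, gene) triple a
#'   technical replicate more than 0.5 cycles from the median is dropped
#'   before averaging (off by default).
#' @return Named numeric vector of relative expression per sample (the
#'   calibrator maps to 1).
#' @export
ddct_expression <- function(ct, target, reference, calibrator_sample,
                            efficiency = NULL, drop_outliers = FALSE) {
  if (!all(c("sample", "gene", "ct") %in% names(ct))) {
    stop("`ct` needs columns sample, gene, ct", call. = FALSE)
  }
  if (!all(c(target, reference) %in% ct$gene)) {
    stop("missing gene: target and reference Cts required", call. = FALSE)
  }
  if (!calibrator_sample %in% ct$sample) {
    stop("calibrator sample not found", call. = FALSE)
  }
  agg <- function(x) {
    if (drop_outliers && length(x) >= 3) {
      x <- x[abs(x - median(x)) <= 0.5]
    }
    mean(x)
  }
  mean_ct <- tapply(ct$ct, list(ct$sample, ct$gene), agg)
  samples <- rownames(mean_ct)
  if (anyNA(mean_ct[, c(target, reference)])) {
    stop("missing gene: every sample needs target and reference Cts",
         call. = FALSE)
  }
  if (is.null(efficiency)) {
    dct <- mean_ct[, target] - mean_ct[, reference]
    ddct <- dct - dct[[calibrator_sample]]
    setNames(2^(-ddct), samples)
  } else {
    e_t <- efficiency[["target"]]
    e_r <- efficiency[["reference"]]
    num <- e_t^(mean_ct[calibrator_sample, target] - mean_ct[, target])
    den <- e_r^(mean_ct[calibrator_sample, reference] - mean_ct[, reference])
    setNames(num / den, samples)
  }
}

#' Amplification efficiency from a standard curve
#'
#' Fits Ct against log10(concentration) over a serial dilution series; the
#' amplification efficiency is `E = 10^(-1/slope)`. Perfect per-cycle doubling
#' gives a slope of `-log2(10) ~ -3.32` and `E = 2`.
#'
#' @param concentration Relative template concentrations (> 0, >= 3 distinct
#'   values). Units are irrelevant: rescaling shifts only the intercept.
#' @param ct Observed Ct values, one per dilution point.
#' @return A list: `efficiency`, `slope`, `r_squared`, and the `lm` fit.
#' @export
standard_curve_efficiency <- function(concentration, ct) {
  if (length(concentration) != length(ct) ||
      length(unique(concentration)) < 3) {
    stop("need >= 3 dilution points with distinct concentrations", call. = FALSE)
  }
  if (any(concentration <= 0)) stop("concentrations must be > 0", call. = FALSE)
  fit <- lm(ct ~ log10(concentration))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("non-amplifying series: slope >= 0", call. = FALSE)
  list(efficiency = 10^(-1 / slope), slope = slope,
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' ChIP enrichment as percent input
#'
#' `%Input = 100 * E^(Ct_input - Ct_ChIP) * input_fraction`: the
#' efficiency-corrected Ct difference between the input aliquot and the ChIP
#' eluate, scaled by the fraction of chromatin kept as input. Equal Cts with a
#' 2% input aliquot give 2% for any efficiency.
#'
#' @param ct_input,ct_chip Ct values of the input and ChIP samples.
#' @param efficiency Amplification efficiency E in (1, 2], e.g. from
#'   [standard_curve_efficiency()].
#' @param input_fraction Fraction of the chromatin lysate used as input
#'   (default 0.02, i.e. 2%).
#' @return Percent input (on the percent scale).
#' @export
percent_input <- function(ct_input, ct_chip, efficiency,
                          input_fraction = 0.02) {
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("`efficiency` must be in (1, 2]", call. = FALSE)
  }
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("`input_fraction` must be in (0, 1]", call. = FALSE)
  }
  100 * efficiency^(ct_input - ct_chip) * input_fraction
}
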