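#' Calibrate activity scores against measured expression
#'
#' Fits the ordinary least squares regression of `log10(expression)` on the
#' activity score. The fit converts FlowFISH scores into pseudo-expression
#' values; regressing log-expression on score (rather than the reverse) makes
#' expression the predicted quantity, matching how the screen's scores are
#' converted downstream. Background fluorescence means the line need not pass
#' through the origin, which is exactly what the intercept absorbs.
#'
#' @param score Numeric vector of activity scores.
#' @param expression Matched relative expression values (> 0), e.g. qPCR
#'   measurements; at least 3 pairs.
#' @return An object of class `flowfish_calibration` with slope `a`,
#'   intercept `b`, Pearson `r`, `n`, and the underlying `lm` fit.
#' @seealso [pseudo_expression()]
#' @export
#' @examples
#' cal <- calibrate(score = c(1, 2, 3, 4), expression = 10^c(-3, -2, -1, 0))
#' coef(cal)
#' predict(cal, newscore = 2.5)
calibrate <- function(score, expression) {
  if (length(score) != length(expression) || length(score) < 3) {
    stop("need >= 3 matched (score, expression) pairs", call. = FALSE)
  }
  if (any(expression <= 0)) stop("expressions must be > 0", call. = FALSE)
  if (sd(score) == 0) {
    stop("degenerate input: scores have zero variance", call. = FALSE)
  }
  fit <- lm(log10(expression) ~ score)
  if (any(!is.finite(coef(fit)))) {
    stop("degenerate calibration fit", call. = FALSE)
  }
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r = cor(score, log10(expression)), n = length(score), fit = fit),
    class = "flowfish_calibration")
}

#' @export
print.flowfish_calibration <- function(x, ...) {
  cat(sprintf("FlowFISH calibration: log10(expression) = %.4g * score + %.4g\n",
              x$a, x$b))
  cat(sprintf("  n = %d pairs, Pearson r = %.4f\n", x$n, x$r))
  invisible(x)
}

#' @export
coef.flowfish_calibration <- function(object, ...) {
  c(slope = object$a, intercept = object$b)
}

#' @export
predict.flowfish_calibration <- function(object, newscore, ...) {
  pseudo_expression(newscore, object)
}

#' Convert an activity score to pseudo-expression
#'
#' `10^(a * score + b)` under a [calibrate()] fit; strictly monotone in the
#' score (for a positive slope).
#'
#' @param score Numeric vector of activity scores.
#' @param cal A `flowfish_calibration`.
#' @return Relative expression values.
#' @export
pseudo_expression <- function(score, cal) {
  stopifnot(inherits(cal, "flowfish_calibration"))
  10^(cal$a * score + cal$b)
}

#' Log-additivity (multiplicative-model) test for double mutants
#'
#' Under the multiplicative null, a double mutant's fold change is the product
#' of its single mutants' fold changes, i.e. its log2 fold change is the sum
#' of the single log2 fold changes. For each label the deviation
#' `d = log2FC_double - (log2FC_e1 + log2FC_e2)` is reported; `d = 0` means
#' perfectly multiplicative. Records whose double-mutant pseudo-expression
#' sits at or below the assay's dynamic-range floor are flagged and excluded
#' from the deviation summary (their scores no longer track expression).
#'
#' @param records Data frame with columns `label`, `score_e1`, `score_e2`,
#'   `score_double` (median activity scores of the single and double mutants);
#'   missing single-mutant scores (`NA`) skip the record with a warning.
#' @param cal A [calibrate()] fit used to convert all scores.
#' @param wt_score Activity score of the wild-type control.
#' @param floor Dynamic-range floor on the pseudo-expression scale; records
#'   with double-mutant pseudo-expression `<= floor` are flagged
#'   `below_dynamic_range`. See [dynamic_range_floor()]. `NULL` disables
#'   flagging.
#' @return An object of class `epistasis_table`: data frame with the three
#'   log2 fold changes vs WT, `deviation`, and `below_dynamic_range`; the
#'   mean absolute deviation over tested records is in attribute
#'   `mean_abs_deviation`.
#' @export
epistasis_test <- function(records, cal, wt_score, floor = NULL) {
  needed <- c("label", "score_e1", "score_e2", "score_double")
  if (!all(needed %in% names(records))) {
    stop("`records` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- is.na(records$score_e1) | is.na(records$score_e2) |
    is.na(records$score_double)
  if (any(incomplete)) {
    warning("skipping record(s) with missing single mutants: ",
            paste(records$label[incomplete], collapse = ", "), call. = FALSE)
    records <- records[!incomplete, , drop = FALSE]
  }
  wt_expr <- pseudo_expression(wt_score, cal)
  lfc <- function(score) log2(pseudo_expression(score, cal) / wt_expr)
  out <- data.frame(
    label = records$label,
    log2fc_e1 = lfc(records$score_e1),
    log2fc_e2 = lfc(records$score_e2),
    log2fc_double = lfc(records$score_double),
    stringsAsFactors = FALSE)
  out$deviation <- out$log2fc_double - (out$log2fc_e1 + out$log2fc_e2)
  out$below_dynamic_range <- if (is.null(floor)) FALSE else
    pseudo_expression(records$score_double, cal) <= floor
  out$deviation[out$below_dynamic_range] <- NA_real_
  structure(out, class = c("epistasis_table", "data.frame"),
            mean_abs_deviation = mean(abs(out$deviation), na.rm = TRUE))
}

#' Dynamic-range floor from control pseudo-expressions
#'
#' The assay floor below which scores stop tracking expression, taken as the
#' 2.5th percentile of the pseudo-expressions of an enhancer-null control
#' (e.g. the deleted-enhancer barcodes).
#'
#' @param control_scores Barcode scores of the null control element.
#' @param cal A [calibrate()] fit.
#' @param prob Percentile (default 0.025).
#' @return The floor on the pseudo-expression scale.
#' @export
dynamic_range_floor <- function(control_scores, cal, prob = 0.025) {
  unname(quantile(pseudo_expression(control_scores, cal), probs = prob))
}

#' Power-law fit of facilitator buffering
#'
#' Quantifies how a facilitator element amplifies partner enhancers: with
#' intrinsic (facilitator-less) activity `A` and fold-change gain
#' `G = expression(+facilitator) / expression(-facilitator)`, a buffering
#' facilitator shows `G = c * A^m` with `m < 0` (weak enhancers boosted more
#' than strong ones), i.e. a straight line on log-log axes. The fit is OLS of
#' `log10(G)` on `log10(A)`, with `A` computed after subtracting the
#' facilitator-only baseline; elements at or below baseline are flagged and
#' excluded.
#'
#' @param expr_without,expr_with Expression of each element without / with the
#'   facilitator (same length, >= 3 elements after exclusions).
#' @param baseline Facilitator-only baseline expression subtracted from
#'   `expr_without` to obtain intrinsic activity (default 0).
#' @param labels Optional element labels.
#' @return An object of class `buffering_fit` with `slope`, `intercept`
#'   (log10 scale), Pearson `r`, the per-element table, flagged elements, and
#'   the underlying `lm` fit.
#' @export
buffering_fit <- function(expr_without, expr_with, baseline = 0,
                          labels = NULL) {
  if (length(expr_without) != length(expr_with)) {
    stop("expression vectors must have equal length", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("element_%02d", seq_along(expr_with))
  if (any(expr_without <= 0) || any(expr_with <= 0)) {
    stop("expressions must be > 0", call. = FALSE)
  }
  A <- expr_without - baseline
  G <- expr_with / expr_without
  flagged <- A <= 0
  if (sum(!flagged) < 3) {
    stop("need >= 3 elements above baseline", call. = FALSE)
  }
  tab <- data.frame(label = labels, intrinsic_activity = A, gain = G,
                    flagged = flagged, stringsAsFactors = FALSE)
  fit <- lm(log10(G[!flagged]) ~ log10(A[!flagged]))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = cor(log10(A[!flagged]), log10(G[!flagged])),
         table = tab, baseline = baseline, fit = fit),
    class = "buffering_fit")
}

#' @export
print.buffering_fit <- function(x, ...) {
  cat(sprintf("facilitator buffering fit: log10(G) = %.4g * log10(A) + %.4g\n",
              x$slope, x$intercept))
  cat(sprintf("  n = %d elements (%d flagged at/below baseline), Pearson r = %.4f\n",
              sum(!x$table$flagged), sum(x$table$flagged), x$r))
  invisible(x)
}

#' @export
coef.buffering_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.buffering_fit <- function(object, new_activity, ...) {
  if (any(new_activity <= 0)) stop("activity must be > 0", call. = FALSE)
  10^(object$intercept + object$slope * log10(new_activity))
}

#' Estimate the true recombinant fraction from BFP-loss percentages
#'
#' The sorted BFP-negative population contains a basal fraction of
#' non-recombinant cells; the true recombinant fraction is estimated as
#' `f = (p_payload - p_control) / p_payload`, where the percentages are the
#' BFP-negative fractions with and without the payload.
#'
#' @param p_payload Percent BFP-negative in the recombinase + payload
#'   transfection (0-100, > 0).
#' @param p_control Percent BFP-negative in the no-payload control
#'   (`0 <= p_control <= p_payload`).
#' @return The recombinant fraction `f` in (0, 1].
#' @export
recombinant_fraction <- function(p_payload, p_control) {
  if (any(p_payload <= 0)) stop("`p_payload` must be > 0", call. = FALSE)
  if (any(p_control < 0) || any(p_control > p_payload) || any(p_payload > 100)) {
    stop("require 0 <= p_control <= p_payload <= 100", call. = FALSE)
  }
  f <- (p_payload - p_control) / p_payload
  if (any(f <= 0)) stop("recombinant fraction must be > 0", call. = FALSE)
  f
}

#' Correct a bulk expression measurement for the recombinant fraction
#'
#' Inverts the mixing model `measured = f * corrected + (1 - f) * baseline`
#' (non-recombinant cells express at the baseline), giving
#' `corrected = baseline + (measured - baseline) / f`.
#'
#' @param measured Bulk expression measured on the sorted population.
#' @param f Recombinant fraction from [recombinant_fraction()] (in (0, 1]).
#' @param baseline Expression of non-recombinant cells (default 0).
#' @return The corrected (pure-recombinant) expression.
#' @export
corrected_expression <- function(measured, f, baseline = 0) {
  if (any(f <= 0) || any(f > 1)) stop("`f` must be in (0, 1]", call. = FALSE)
  baseline + (measured - baseline) / f
}
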