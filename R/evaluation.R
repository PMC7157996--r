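#' Support-recovery confusion counts
#'
#' Compares the supports (exact-zero test) of an estimated and a true
#' loading vector: a feature is "selected" when its estimated coefficient
#' is nonzero, "truly active" when its true coefficient is nonzero.
#'
#' @param estimate,truth Numeric vectors of equal length.
#' @return Named integer vector with `tp`, `tn`, `fp`, `fn`
#'   (summing to the number of features).
#' @export
selection_confusion <- function(estimate, truth) {
  if (length(estimate) != length(truth)) stop("length mismatch")
  est <- estimate != 0
  tru <- truth != 0
  c(tp = sum(est & tru), tn = sum(!est & !tru),
    fp = sum(est & !tru), fn = sum(!est & tru))
}

#' Sensitivity, specificity and Matthews correlation of a selection
#'
#' \deqn{SENS = TP/(TP+FN), \quad SPEC = TN/(FP+TN),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' When any factor of the MCC denominator is zero the MCC is reported as
#' 0 (the usual convention for degenerate tables).
#'
#' @param counts Output of [selection_confusion()], or an estimated
#'   vector (then `truth` must be given and counts are computed first).
#' @param truth Optional true loading vector.
#' @return Named numeric vector `sens`, `spec`, `mcc`.
#' @export
#' @examples
#' selection_metrics(c(tp = 2, tn = 3, fp = 1, fn = 1))
selection_metrics <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- selection_confusion(counts, truth)
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(sens = sens, spec = spec, mcc = mcc)
}

#' Absolute cosine between estimated and true loading vectors
#'
#' \eqn{|\hat a^\top a^*| / (\|\hat a\|_2 \|a^*\|_2)}: 1 when the vectors
#' are collinear, 0 when orthogonal.  The absolute value is taken because
#' eigenvector-type solutions are sign-ambiguous.
#'
#' @param estimate,truth Nonzero numeric vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
loading_angle <- function(estimate, truth) {
  if (length(estimate) != length(truth)) stop("length mismatch")
  ne <- sqrt(sum(estimate^2)); nt <- sqrt(sum(truth^2))
  if (ne == 0 || nt == 0) stop("both vectors must be nonzero")
  abs(sum(estimate * truth)) / (ne * nt)
}
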