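#' Confusion counts for binary predictions
#'
#' Positive class is 1.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return An object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("entries must be 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Scalar metrics from confusion counts
#'
#' Standard closed forms; any ratio with a zero denominator is reported as 0
#' and flagged in the `degenerate` attribute so batch evaluation never
#' aborts on degenerate folds. `g_mean = sqrt(sensitivity * specificity)`;
#' `mcc` uses the four-cell correlation form with a zero denominator
#' mapping to 0.
#'
#' @param c A `confusion_counts`.
#' @return Named numeric vector with accuracy, sensitivity, specificity,
#'   precision, f1, g_mean, mcc.
#' @export
scalar_metrics <- function(c) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- character()
  note <- function(nm, den) if (den == 0) degenerate <<- c(degenerate, nm)
  n <- c$TP + c$TN + c$FP + c$FN
  sens <- safe(c$TP, c$TP + c$FN); note("sensitivity", c$TP + c$FN)
  spec <- safe(c$TN, c$TN + c$FP); note("specificity", c$TN + c$FP)
  prec <- safe(c$TP, c$TP + c$FP); note("precision", c$TP + c$FP)
  f1 <- safe(2 * prec * sens, prec + sens); note("f1", prec + sens)
  mcc_den <- sqrt(prod(as.numeric(c(c$TP + c$FP, c$TP + c$FN,
                                    c$TN + c$FP, c$TN + c$FN))))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) / mcc_den
  out <- c(accuracy = safe(c$TP + c$TN, n), sensitivity = sens,
           specificity = spec, precision = prec, f1 = f1,
           g_mean = sqrt(sens * spec), mcc = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' Rank-based AUC-ROC
#'
#' The normalized Mann-Whitney U statistic: the probability that a random
#' positive scores above a random negative, ties counting one half.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Joint-correctness table for two classifiers
#'
#' @param y_true True labels.
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @return A `pairwise_agreement` with counts N11 (both correct), N00
#'   (both wrong), N10 (only A correct), N01 (only B correct).
#' @export
pairwise_agreement <- function(y_true, pred_a, pred_b) {
  a <- as.integer(pred_a) == as.integer(y_true)
  b <- as.integer(pred_b) == as.integer(y_true)
  structure(list(N11 = sum(a & b), N00 = sum(!a & !b),
                 N10 = sum(a & !b), N01 = sum(!a & b)),
            class = "pairwise_agreement")
}

#' Yule Q-statistic of two classifiers
#'
#' `(N11 N00 - N01 N10) / (N11 N00 + N01 N10)`; 0 when the denominator is
#' 0. Lower values indicate more diverse errors.
#'
#' @param p A `pairwise_agreement`.
#' @return Value in \[-1, 1\].
#' @export
q_statistic <- function(p) {
  num <- p$N11 * p$N00 - p$N01 * p$N10
  den <- p$N11 * p$N00 + p$N01 * p$N10
  if (den == 0) 0 else num / den
}

#' Disagreement measure of two classifiers
#'
#' Share of samples on which exactly one of the two classifiers is correct.
#'
#' @param p A `pairwise_agreement`.
#' @return Value in \[0, 1\].
#' @export
disagreement <- function(p) {
  n <- p$N11 + p$N00 + p$N10 + p$N01
  if (n == 0) stop("empty agreement table")
  (p$N01 + p$N10) / n
}

#' Kuncheva entropy diversity of an ensemble
#'
#' `E = (1/n) sum_j min(l_j, L - l_j) / (L - ceiling(L/2))` where `l_j` is
#' the number of members correct on sample j; 0 when members always agree,
#' 1 at maximal disagreement.
#'
#' @param correctness L x n logical matrix (members x samples).
#' @return Value in \[0, 1\].
#' @export
entropy_diversity <- function(correctness) {
  correctness <- as.matrix(correctness)
  L <- nrow(correctness)
  if (L < 2) stop("entropy diversity needs >= 2 members")
  lj <- colSums(correctness)
  mean(pmin(lj, L - lj) / (L - ceiling(L / 2)))
}

#' Ensemble variance index
#'
#' Mean over samples of the population variance of the member
#' probabilities; a stability diagnostic bounded by 0.25 for probabilities.
#'
#' @param member_probs K x n matrix of member probabilities.
#' @return Nonnegative scalar.
#' @export
ensemble_variance_index <- function(member_probs) {
  member_probs <- as.matrix(member_probs)
  if (nrow(member_probs) < 2) stop("EVI needs >= 2 members")
  mu <- colMeans(member_probs)
  mean(colMeans(sweep(member_probs, 2, mu)^2))
}

#' Robustness index: relative percentage drop under perturbation
#'
#' `100 * (clean - perturbed) / clean`, rounded half-up to two decimals;
#' negative when the perturbed value exceeds the clean one.
#'
#' @param clean_value Clean-condition metric (> 0).
#' @param perturbed_value Metric under perturbation.
#' @return Percentage, 2 decimals.
#' @export
robustness_index <- function(clean_value, perturbed_value) {
  if (any(clean_value <= 0)) stop("clean value must be positive")
  round_half_up(100 * (clean_value - perturbed_value) / clean_value, 2)
}

#' Ablation degradation: relative percentage drop versus the full model
#'
#' The same functional as [robustness_index()], reported for
#' component-ablation comparisons.
#'
#' @param full_value Full-model metric (> 0).
#' @param ablated_value Ablated-model metric.
#' @return Percentage, 2 decimals.
#' @export
degradation_pct <- function(full_value, ablated_value) {
  if (any(full_value <= 0)) stop("full-model value must be positive")
  round_half_up(100 * (full_value - ablated_value) / full_value, 2)
}
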