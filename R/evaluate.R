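#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed from ranks, with tied scores counting
#' one half, equal to the probability that a random case outscores a random
#' control.  Implemented directly from midranks because it sits in the
#' cross-validation inner loop; a brute-force pair-concordance oracle
#' verifies it in the test suite.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a probability cutoff
#'
#' A sample is called a case when its probability is at least `cutoff`
#' (default 0.5).  If a class is absent its rate is undefined and reported
#' as `NaN` with a warning.
#'
#' @param probs predicted case probabilities in \[0, 1\].
#' @param labels 0/1 outcome vector.
#' @param cutoff classification threshold.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(probs, labels, cutoff = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)),
            all(probs >= 0 & probs <= 1))
  pred <- as.integer(probs >= cutoff)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    warning("single-class labels: the undefined rate is reported as NaN")
  sens <- if (n1 == 0) NaN else sum(pred == 1 & labels == 1) / n1
  spec <- if (n0 == 0) NaN else sum(pred == 0 & labels == 0) / n0
  c(sensitivity = sens, specificity = spec)
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently and deals its members to the `k`
#' folds round-robin, so per-fold class counts differ from perfect
#' proportionality by at most one sample.  Deterministic given `seed`.
#'
#' @param labels 0/1 outcome vector; each class must have at least `k`
#'   members.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, same length as `labels`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  stopifnot(all(labels %in% c(0, 1)), k >= 2)
  for (cl in c(0, 1)) {
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    # deal the two classes in opposite fold orders so the remainder
    # samples land on different folds and overall sizes differ by <= 1
    fold[sample(which(labels == 1))] <-
      rep_len(seq_len(k), sum(labels == 1))
    fold[sample(which(labels == 0))] <-
      rep_len(rev(seq_len(k)), sum(labels == 0))
  })
  fold
}

#' Evaluation report for a set of predicted probabilities
#'
#' @inheritParams sens_spec
#' @return list with `auc`, `sensitivity`, `specificity`, `cutoff`, `n`
#'   and the per-sample scores.
#' @export
evaluate_predictions <- function(probs, labels, cutoff = 0.5) {
  ss <- sens_spec(probs, labels, cutoff)
  list(auc = auc(probs, labels),
       sensitivity = unname(ss["sensitivity"]),
       specificity = unname(ss["specificity"]),
       cutoff = cutoff, n = length(labels),
       scores = as.numeric(probs))
}
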