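#' Per-feature abundance association p-values (Welch t-test)
#'
#' Runs a two-sided Welch two-sample t-test per column of `features`
#' comparing the two label groups, vectorized across features.  Features
#' with zero within-group variance in both groups carry no usable signal
#' for a t-test and get p = 1.
#'
#' @param features samples x features numeric matrix (abundances or branch
#'   profiles).
#' @param labels 0/1 vector, both classes present, at least 2 per class.
#' @return named vector of p-values in (0, 1].
#' @export
abundance_pvalues <- function(features, labels) {
  check_two_classes(labels, nrow(features))
  g1 <- features[labels == 1, , drop = FALSE]
  g0 <- features[labels == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  if (n1 < 2 || n0 < 2) stop("need at least 2 samples per class")
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- colSums(sweep(g1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(g0, 2, m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tval <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  p[v1 == 0 & v0 == 0] <- 1
  p[!is.finite(p)] <- 1
  names(p) <- colnames(features)
  p
}

#' Per-feature presence/absence association p-values
#'
#' Builds the 2x2 table of presence (value > 0) against label for each
#' feature and tests independence: Fisher's exact test (two-sided, via the
#' hypergeometric distribution) whenever any expected cell count is 5 or
#' less, Pearson's chi-squared test without continuity correction
#' otherwise.
#' Features present in all samples or absent from all samples get p = 1.
#'
#' @inheritParams abundance_pvalues
#' @return named vector of p-values in (0, 1].
#' @export
presence_pvalues <- function(features, labels) {
  check_two_classes(labels, nrow(features))
  pres <- features > 0
  n1 <- sum(labels == 1); n0 <- sum(labels == 0); n <- n1 + n0
  k <- colSums(pres)                       # total present
  a <- colSums(pres[labels == 1, , drop = FALSE])  # present among cases
  p <- vapply(seq_along(k), function(r) {
    kk <- k[r]; aa <- a[r]
    if (kk == 0 || kk == n) return(1)
    # expected counts of the 2x2 (presence x label) table
    expected <- outer(c(kk, n - kk), c(n1, n0)) / n
    if (any(expected <= 5)) fisher_2x2(aa, kk, n1, n0)
    else chisq_2x2(aa, kk, n1, n0)
  }, numeric(1))
  p <- pmin(p, 1)
  names(p) <- colnames(features)
  p
}

# Two-sided Fisher exact p for the 2x2 table with `x` present cases, `k`
# present overall, class sizes n1/n0: sum of hypergeometric probabilities
# not exceeding the observed one (with the customary relative tolerance).
fisher_2x2 <- function(x, k, n1, n0) {
  supp <- max(0, k - n0):min(k, n1)
  d <- dhyper(supp, n1, n0, k)
  sum(d[d <= d[supp == x] * (1 + 1e-7)])
}

# Pearson chi-squared (1 df, no continuity correction) for the same table.
chisq_2x2 <- function(x, k, n1, n0) {
  n <- n1 + n0
  b <- k - x; c <- n1 - x; d <- n0 - b
  stat <- n * (x * d - b * c)^2 / (k * (n - k) * n1 * n0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

check_two_classes <- function(labels, n) {
  stopifnot(length(labels) == n)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("labels contain a single class; association tests need both")
  invisible(TRUE)
}

#' Association boosting weights from p-values
#'
#' Converts per-feature association p-values into non-negative boosting
#' weights `a_r = -log10(p_r)`, normalized to mean 1.  The normalization
#' constant is a pure convention: it cancels exactly in the UniFrac ratios
#' and through the bandwidth of the Gaussian kernels for the other metrics
#' (see the kernel scale-invariance property), so only relative weights
#' matter.  When all p-values equal 1 (no signal anywhere) the weights fall
#' back to uniform 1 with a warning.
#'
#' @param pvalues named vector of p-values in (0, 1]; values below 1e-300
#'   are floored there before taking logs.
#' @return named non-negative weight vector with mean 1, with attribute
#'   `normalization = "mean1"`.
#' @export
pvalues_to_weights <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p <- pmax(pvalues, 1e-300)
  raw <- -log10(p)
  if (all(raw == 0)) {
    warning("all p-values equal 1; falling back to uniform boosting weights")
    w <- rep(1, length(p))
  } else {
    w <- raw / mean(raw)
  }
  names(w) <- names(pvalues)
  attr(w, "normalization") <- "mean1"
  w
}
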