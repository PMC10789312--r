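#' Boosted microbiome distance matrices
#'
#' The four distances share one structure: a weighted L1 comparison of
#' per-feature values (abundances or presence indicators), optionally
#' "boosted" by non-negative per-feature association weights `a_r`
#' (see [pvalues_to_weights()]).  With `weights = NULL` every `a_r` is 1
#' and each function reduces exactly to its classical counterpart.
#'
#' * `weighted_unifrac`: features are branches of a rooted tree with
#'   branch lengths `b_r` and per-sample branch abundance profiles
#'   `p_ir`; `d(i,j) = sum_r b_r a_r |p_ir - p_jr| / sum_r b_r a_r (p_ir + p_jr)`.
#' * `unweighted_unifrac`: same ratio on presence indicators,
#'   `d(i,j) = sum_r b_r a_r |I(p_ir>0) - I(p_jr>0)| / sum_r b_r a_r I(p_ir + p_jr > 0)`.
#' * `bray_curtis`: OTU-level `d(i,j) = sum_r a_r |p_ir - p_jr| / 2`
#'   (rows of `rel` sum to 1, so the classical denominator is the
#'   constant 2).
#' * `hamming`: OTU-level count of presence mismatches,
#'   `d(i,j) = sum_r a_r |I(p_ir>0) - I(p_jr>0)|`.
#'
#' Pairs for which a UniFrac denominator is zero (two entirely empty
#' samples) are assigned distance 0.
#'
#' @param bp a [branch_profiles()] object (training samples).
#' @param rel samples x OTUs relative-abundance matrix.
#' @param weights named non-negative boosting weights aligned to the branch
#'   ids (`weighted_unifrac`, `unweighted_unifrac`) or OTU ids
#'   (`bray_curtis`, `hamming`); `NULL` for the un-boosted metric.
#' @param newdata optional second set of samples (a `branch_profiles`
#'   object or abundance matrix over the same features); when supplied the
#'   result is the rectangular matrix of distances from `newdata` rows to
#'   the training rows.
#' @return distance matrix with sample ids as dimnames and attributes
#'   `metric` and `boosted`; square, symmetric and zero-diagonal when
#'   `newdata` is `NULL`.
#' @name boosted_distances
NULL

align_boost_weights <- function(weights, feature_ids, what) {
  if (is.null(weights)) return(rep(1, length(feature_ids)))
  if (is.null(names(weights)) || !all(feature_ids %in% names(weights)))
    stop("boosting weights are misaligned with the ", what, " ids")
  a <- as.numeric(weights[feature_ids])
  if (any(!is.finite(a)) || any(a < 0))
    stop("boosting weights must be finite and non-negative")
  a
}

ratio_distance <- function(num, den) {
  d <- num / den
  d[den == 0] <- 0
  d
}

dist_result <- function(d, rows, cols, metric, boosted, square) {
  dimnames(d) <- list(rows, cols)
  if (square) {
    diag(d) <- 0
    d <- (d + t(d)) / 2
  }
  attr(d, "metric") <- metric
  attr(d, "boosted") <- boosted
  d
}

unifrac_core <- function(X, Y, cw, presence, metric, boosted) {
  if (presence) {
    Xv <- (X > 0) * 1
    Yv <- if (is.null(Y)) NULL else (Y > 0) * 1
  } else {
    Xv <- X; Yv <- Y
  }
  square <- is.null(Yv)
  if (square) Yv <- Xv
  num <- if (square) self_weighted_l1(Xv, cw) else cross_weighted_l1(Yv, Xv, cw)
  if (presence) {
    # denominator sum_r cw_r I(either present) = cw.I_i + cw.I_j - cw.(I_i & I_j)
    Wx <- sweep(Xv, 2, cw, "*")
    cx <- rowSums(Wx)
    cy <- if (square) cx else rowSums(sweep(Yv, 2, cw, "*"))
    shared <- Yv %*% t(Wx)
    den <- outer(cy, cx, "+") - shared
    if (square) num <- cross_or_self_num_fix(num)
  } else {
    cx <- as.vector(Xv %*% cw)
    cy <- if (square) cx else as.vector(Yv %*% cw)
    den <- outer(cy, cx, "+")
  }
  d <- ratio_distance(num, den)
  dist_result(d, if (square) rownames(X) else rownames(Y), rownames(X),
              metric, boosted, square)
}

# self_weighted_l1 already returns a full symmetric matrix; nothing to fix,
# kept as a seam for clarity of the presence branch above.
cross_or_self_num_fix <- function(num) num

#' @rdname boosted_distances
#' @export
weighted_unifrac <- function(bp, weights = NULL, newdata = NULL) {
  stopifnot(inherits(bp, "branch_profiles"))
  a <- align_boost_weights(weights, colnames(bp$profiles), "branch")
  cw <- bp$branch_length * a
  Y <- NULL
  if (!is.null(newdata)) {
    check_same_branches(bp, newdata)
    Y <- newdata$profiles
  }
  unifrac_core(bp$profiles, Y, cw, presence = FALSE,
               metric = "weighted_unifrac", boosted = !is.null(weights))
}

#' @rdname boosted_distances
#' @export
unweighted_unifrac <- function(bp, weights = NULL, newdata = NULL) {
  stopifnot(inherits(bp, "branch_profiles"))
  a <- align_boost_weights(weights, colnames(bp$profiles), "branch")
  cw <- bp$branch_length * a
  Y <- NULL
  if (!is.null(newdata)) {
    check_same_branches(bp, newdata)
    Y <- newdata$profiles
  }
  unifrac_core(bp$profiles, Y, cw, presence = TRUE,
               metric = "unweighted_unifrac", boosted = !is.null(weights))
}

check_same_branches <- function(bp, newdata) {
  if (!inherits(newdata, "branch_profiles"))
    stop("newdata must be a branch_profiles object")
  if (!identical(colnames(bp$profiles), colnames(newdata$profiles)))
    stop("newdata branch ids are misaligned with the training branch ids")
  invisible(TRUE)
}

l1_otu_distance <- function(rel, weights, newdata, presence, halve, metric) {
  a <- align_boost_weights(weights, colnames(rel), "OTU")
  X <- if (presence) (rel > 0) * 1 else rel
  square <- is.null(newdata)
  if (!square) {
    if (!identical(colnames(rel), colnames(newdata)))
      stop("newdata OTU ids are misaligned with the training OTU ids")
    Y <- if (presence) (newdata > 0) * 1 else newdata
    num <- cross_weighted_l1(Y, X, a)
  } else {
    num <- self_weighted_l1(X, a)
  }
  d <- if (halve) num / 2 else num
  dist_result(d, if (square) rownames(rel) else rownames(newdata),
              rownames(rel), metric, !is.null(weights), square)
}

#' @rdname boosted_distances
#' @export
bray_curtis <- function(rel, weights = NULL, newdata = NULL) {
  l1_otu_distance(rel, weights, newdata, presence = FALSE, halve = TRUE,
                  metric = "bray_curtis")
}

#' @rdname boosted_distances
#' @export
hamming <- function(rel, weights = NULL, newdata = NULL) {
  l1_otu_distance(rel, weights, newdata, presence = TRUE, halve = FALSE,
                  metric = "hamming")
}
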