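#' Case-control agreement matrix
#'
#' `CC(i,j)` is 0 on the diagonal, +1 when samples i and j share a label
#' and -1 otherwise.  It drives the kernel-alignment scores: a kernel
#' whose similarities are large within classes and small between classes
#' scores high.
#'
#' @param labels 0/1 vector with both classes present.
#' @return integer matrix over \{-1, 0, 1\}.
#' @export
cc_matrix <- function(labels) {
  check_two_classes(labels, length(labels))
  cc <- outer(labels, labels, function(a, b) ifelse(a == b, 1L, -1L))
  diag(cc) <- 0L
  cc
}

#' Kernel-alignment score
#'
#' `S_l = sum_ij K_l(i,j) CC(i,j)`, the full double sum over ordered
#' pairs; the linear coefficient of kernel l in the weight-learning
#' objective.
#'
#' @param K square kernel matrix.
#' @param CC matching [cc_matrix()].
#' @return scalar score.
#' @export
kernel_score <- function(K, CC) {
  if (!all(dim(K) == dim(CC)))
    stop("kernel and CC matrix shapes differ")
  sum(K * CC)
}

#' Closed-form entropy-regularized kernel weights
#'
#' Minimizes `-sum_l w_l S_l + rho * sum_l w_l log w_l` over the
#' probability simplex.  For `rho > 0` the stationarity conditions give a
#' softmax, `w_l = exp(S_l / rho) / sum_m exp(S_m / rho)`, computed with
#' max-subtraction for overflow safety.  At `rho = 0` the objective is
#' linear and all mass goes to the top-scoring kernel (split equally over
#' exact ties).
#'
#' @param S numeric vector of kernel-alignment scores.
#' @param rho non-negative regularization strength.
#' @return non-negative weights summing to 1, named like `S`.
#' @export
solve_weights <- function(S, rho) {
  stopifnot(is.numeric(S), length(S) >= 1, is.finite(rho), rho >= 0)
  if (rho == 0) {
    w <- numeric(length(S))
    top <- which(S >= max(S))
    w[top] <- 1 / length(top)
  } else {
    e <- exp((S - max(S)) / rho)
    w <- e / sum(e)
  }
  names(w) <- names(S)
  w
}

weight_entropy <- function(w) -sum(ifelse(w > 0, w * log(w), 0))

#' Largest useful regularization strength
#'
#' The maximum-entropy solution `w_l = 1/L` is only reached as
#' `rho -> Inf`, so the grid endpoint is taken as the smallest value in a
#' doubling search (start 1, factor 2) whose closed-form weights reach at
#' least `(1 - 1e-3) * log(L)` entropy.  Equal scores are already at
#' maximum entropy for any `rho`; then 1 is returned.
#'
#' @param S kernel-alignment scores (at least 2).
#' @param n_kernels number of kernels (defaults to `length(S)`).
#' @return positive scalar `rho_max`.
#' @export
rho_max <- function(S, n_kernels = length(S)) {
  stopifnot(n_kernels >= 2)
  if (diff(range(S)) == 0) return(1.0)
  target <- (1 - 1e-3) * log(n_kernels)
  rho <- 1
  while (weight_entropy(solve_weights(S, rho)) < target) {
    rho <- rho * 2
    if (rho > 2^60)
      stop("rho doubling search exceeded 2^60: pathological score spread")
  }
  rho
}

rho_grid_from_max <- function(rmax) c(0, rmax * (1:10) / 10)

#' Similarity t-score of one sample against training cases and controls
#'
#' Welch two-sample t-statistic comparing the sample's combined-kernel
#' similarities with the training cases against those with the training
#' controls (cases minus controls, so larger t means more case-like).
#' For a training sample, pass its own position as `self_index` so it is
#' excluded from the comparison groups.
#'
#' @param sims numeric vector of similarities to the training samples.
#' @param labels training 0/1 labels, aligned with `sims`.
#' @param self_index position of the sample itself in `sims`, or `NULL`
#'   for a test sample.
#' @return the t-statistic (0 with a warning when both groups have zero
#'   variance).
#' @export
similarity_tscore <- function(sims, labels, self_index = NULL) {
  stopifnot(length(sims) == length(labels))
  if (!is.null(self_index)) {
    sims <- sims[-self_index]
    labels <- labels[-self_index]
  }
  s1 <- sims[labels == 1]
  s0 <- sims[labels == 0]
  if (length(s1) < 2 || length(s0) < 2)
    stop("similarity t-score needs at least 2 training cases and 2 controls")
  v1 <- var(s1); v0 <- var(s0)
  se2 <- v1 / length(s1) + v0 / length(s0)
  if (se2 == 0) {
    warning("zero variance in both similarity groups; t-score set to 0")
    return(0)
  }
  (mean(s1) - mean(s0)) / sqrt(se2)
}

training_tscores <- function(Kcomb, labels) {
  vapply(seq_along(labels),
         function(i) similarity_tscore(Kcomb[i, ], labels, self_index = i),
         numeric(1))
}

# Maximum-likelihood logistic fit of y on the scalar t-score (IRLS via
# glm).  Complete separation inflates the slope without bound; it is
# clamped at |beta1| = 30 with a warning and the intercept refit by offset.
logistic_tscore_fit <- function(t, y) {
  fit <- suppressWarnings(glm(y ~ t, family = binomial(),
                              control = list(maxit = 100, epsilon = 1e-8)))
  b <- coef(fit)
  if (anyNA(b)) b[is.na(b)] <- 0
  if (!fit$converged && !all(is.finite(b)))
    stop("logistic fit did not converge: coefficients ",
         paste(signif(b, 4), collapse = ", "))
  if (abs(b[2]) > 30) {
    warning("near-separation in the t-score logistic fit; slope clamped at 30")
    b1 <- sign(b[2]) * 30
    b0 <- coef(suppressWarnings(
      glm(y ~ 1, offset = b1 * t, family = binomial())))[1]
    b <- c(b0, b1)
  }
  list(beta0 = unname(b[1]), beta1 = unname(b[2]))
}

#' Tune the entropy-regularization strength by stratified cross-validation
#'
#' Evaluates the 11-point grid `\{0, rho_max/10, ..., rho_max\}` by k-fold
#' stratified cross-validation: on each fold's training part the kernel
#' weights are solved in closed form, the similarity t-score logistic
#' classifier is fit, and the held-out fold is scored; the `rho` with the
#' best mean AUC wins, with ties broken towards the largest `rho` (more
#' even weights are more stable out of sample).
#'
#' Pass either precomputed training `kernels` (which are simply subset per
#' fold) or a `make_fold(train_idx, test_idx)` function returning
#' `list(K = <list of square fold-training kernels>, Kc = <list of
#' heldout x training kernels>)`; the latter is what [mkbmc_fit()] uses so
#' boosting weights and bandwidths are re-learned inside each fold.
#'
#' @param kernels optional list of square training kernel matrices.
#' @param labels training 0/1 labels.
#' @param make_fold optional fold-builder function (see Details).
#' @param rho_grid optional explicit grid; defaults to the grid derived
#'   from [rho_max()] on `kernels`.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold draw; folds are re-drawn (up to
#'   10 attempts) if any fold lacks a class.
#' @return the selected `rho`, with attributes `grid` and `mean_auc`.
#' @export
tune_rho <- function(kernels = NULL, labels, make_fold = NULL,
                     rho_grid = NULL, folds = 5, seed = 1) {
  check_two_classes(labels, length(labels))
  if (is.null(make_fold)) {
    if (is.null(kernels)) stop("supply kernels or make_fold")
    make_fold <- function(tr, te) list(
      K = lapply(kernels, function(K) K[tr, tr, drop = FALSE]),
      Kc = lapply(kernels, function(K) K[te, tr, drop = FALSE]))
  }
  if (is.null(rho_grid)) {
    if (is.null(kernels)) stop("supply rho_grid when using make_fold")
    S <- vapply(kernels, kernel_score, numeric(1), CC = cc_matrix(labels))
    rho_grid <- rho_grid_from_max(rho_max(S))
  }
  fold <- NULL
  for (attempt in seq_len(10)) {
    cand <- stratified_folds(labels, folds, seed + attempt - 1)
    ok <- all(vapply(seq_len(folds), function(f) {
      ytr <- labels[cand != f]
      sum(ytr == 1) >= 2 && sum(ytr == 0) >= 2 &&
        length(unique(labels[cand == f])) == 2
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold))
    stop("could not draw stratified folds with both classes in every fold")
  aucs <- matrix(NA_real_, folds, length(rho_grid))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    kit <- make_fold(tr, te)
    ytr <- labels[tr]
    S <- vapply(kit$K, kernel_score, numeric(1), CC = cc_matrix(ytr))
    for (g in seq_along(rho_grid)) {
      w <- solve_weights(S, rho_grid[g])
      Ktr <- Reduce(`+`, Map(`*`, kit$K, w))
      Kte <- Reduce(`+`, Map(`*`, kit$Kc, w))
      ts <- training_tscores(Ktr, ytr)
      bb <- logistic_tscore_fit(ts, ytr)
      tte <- apply(Kte, 1, similarity_tscore, labels = ytr)
      aucs[f, g] <- auc(plogis(bb$beta0 + bb$beta1 * tte), labels[te])
    }
  }
  mean_auc <- colMeans(aucs)
  best <- max(which(mean_auc >= max(mean_auc) - 1e-12))
  structure(rho_grid[best], grid = rho_grid, mean_auc = mean_auc)
}

# Internal: boosting weights + kernels for a training index set, and cross
# kernels for an optional test index set / external test data.  Everything
# test-side reuses training-derived quantities only.
build_kernel_set <- function(rel, bp, labels, cov_df, covariates,
                             train_idx, test_idx = NULL,
                             boost_level = "branch") {
  rel_tr <- rel[train_idx, , drop = FALSE]
  bp_tr <- bp_subset(bp, train_idx)
  y_tr <- labels[train_idx]
  bc_w <- pvalues_to_weights(abundance_pvalues(rel_tr, y_tr))
  hm_w <- pvalues_to_weights(presence_pvalues(rel_tr, y_tr))
  if (boost_level == "branch") {
    wu_w <- pvalues_to_weights(abundance_pvalues(bp_tr$profiles, y_tr))
    uu_w <- pvalues_to_weights(presence_pvalues(bp_tr$profiles, y_tr))
  } else {
    wu_w <- otu_weights_to_branches(bc_w, bp_tr)
    uu_w <- otu_weights_to_branches(hm_w, bp_tr)
  }
  boost <- list(weighted_unifrac = wu_w, unweighted_unifrac = uu_w,
                bray_curtis = bc_w, hamming = hm_w)
  bp_te <- if (!is.null(test_idx)) bp_subset(bp, test_idx) else NULL
  rel_te <- if (!is.null(test_idx)) rel[test_idx, , drop = FALSE] else NULL
  D <- list(
    weighted_unifrac = weighted_unifrac(bp_tr, wu_w),
    unweighted_unifrac = unweighted_unifrac(bp_tr, uu_w),
    bray_curtis = bray_curtis(rel_tr, bc_w),
    hamming = hamming(rel_tr, hm_w))
  K <- lapply(D, gaussian_kernel)
  Kc <- NULL
  if (!is.null(test_idx)) {
    Dc <- list(
      weighted_unifrac = weighted_unifrac(bp_tr, wu_w, newdata = bp_te),
      unweighted_unifrac = unweighted_unifrac(bp_tr, uu_w, newdata = bp_te),
      bray_curtis = bray_curtis(rel_tr, bc_w, newdata = rel_te),
      hamming = hamming(rel_tr, hm_w, newdata = rel_te))
    Kc <- Map(function(d, k) cross_kernel(d, attr(k, "sigma")), Dc, K)
  }
  for (cv in covariates) {
    x_tr <- cov_df[train_idx, cv]
    K[[paste0("cov:", cv)]] <- covariate_kernel(x_tr, name = cv)
    if (!is.null(test_idx))
      Kc[[paste0("cov:", cv)]] <-
        covariate_kernel(x_tr, newdata = cov_df[test_idx, cv], name = cv)
  }
  list(K = K, Kc = Kc, boost = boost)
}

# OTU-level boosting variant for the tree metrics: leaf branches inherit
# the OTU weight, internal branches stay at 1, then re-normalize to mean 1.
otu_weights_to_branches <- function(w_otu, bp) {
  ids <- colnames(bp$profiles)
  a <- rep(1, length(ids))
  names(a) <- ids
  hit <- intersect(ids, names(w_otu))
  a[hit] <- w_otu[hit]
  a / mean(a)
}

#' Fit the multi-kernel boosted classifier
#'
#' End-to-end training pipeline: counts are converted to relative
#' abundances and aligned with the tree; per-feature association boosting
#' weights are learned from the training labels (branch-level tests for
#' the tree metrics, OTU-level for Bray-Curtis/Hamming); the four boosted
#' distances are turned into Gaussian kernels (plus one kernel per
#' covariate); kernel weights are solved in closed form under the
#' entropy-regularized alignment objective with `rho` tuned by stratified
#' cross-validation (boosting weights and bandwidths re-learned inside
#' each fold); finally every training sample gets a leave-self-out
#' similarity t-score on the combined kernel and a logistic model of the
#' label on the t-score is fit as the classifier.
#'
#' @param counts samples x OTUs matrix of non-negative counts or
#'   proportions, rownames = sample ids.
#' @param tree rooted `phylo` covering (a superset of) the OTUs.
#' @param meta data.frame with rownames = sample ids and a 0/1 `label`
#'   column (see [read_metadata()]).
#' @param covariates character vector of numeric metadata columns to add
#'   as covariate kernels.
#' @param rho fixed regularization strength, or `NULL` (default) to tune
#'   on the 11-point grid by `folds`-fold cross-validation.
#' @param folds number of cross-validation folds for tuning.
#' @param seed integer seed controlling the fold draw.
#' @param boost_level `"branch"` (default: tree-metric boosting weights
#'   are learned per branch profile) or `"otu"` (leaf-only heuristic).
#' @return an object of class `mkbmc`; see [predict.mkbmc()].
#' @export
mkbmc_fit <- function(counts, tree, meta, covariates = character(),
                      rho = NULL, folds = 5, seed = 1,
                      boost_level = c("branch", "otu")) {
  boost_level <- match.arg(boost_level)
  stopifnot(is.matrix(counts), inherits(tree, "phylo"), is.data.frame(meta))
  if (!all(rownames(counts) %in% rownames(meta)))
    stop("metadata is missing some samples of the OTU table")
  meta <- meta[rownames(counts), , drop = FALSE]
  labels <- as.numeric(meta$label)
  check_two_classes(labels, nrow(counts))
  for (cv in covariates) {
    if (!cv %in% colnames(meta)) stop("covariate '", cv, "' not in metadata")
    if (!is.numeric(meta[[cv]])) stop("covariate '", cv, "' is not numeric")
  }
  t0 <- Sys.time()
  rel <- to_relative_abundance(counts)
  al <- align_tree_and_table(tree, rel)
  bp <- branch_profiles(al$tree, al$rel)
  log_stage("features", n = nrow(al$rel), otus = ncol(al$rel),
            branches = ncol(bp$profiles))
  n <- nrow(al$rel)
  full <- build_kernel_set(al$rel, bp, labels, meta, covariates,
                           seq_len(n), boost_level = boost_level)
  S <- vapply(full$K, kernel_score, numeric(1), CC = cc_matrix(labels))
  rho_details <- NULL
  if (is.null(rho)) {
    grid <- rho_grid_from_max(rho_max(S))
    rho <- tune_rho(labels = labels, rho_grid = grid, folds = folds,
                    seed = seed,
                    make_fold = function(tr, te) {
                      ks <- build_kernel_set(al$rel, bp, labels, meta,
                                             covariates, tr, te,
                                             boost_level = boost_level)
                      list(K = ks$K, Kc = ks$Kc)
                    })
    rho_details <- list(grid = attr(rho, "grid"),
                        mean_auc = attr(rho, "mean_auc"))
    rho <- as.numeric(rho)
  }
  w <- solve_weights(S, rho)
  Kcomb <- Reduce(`+`, Map(`*`, full$K, w))
  tsc <- training_tscores(Kcomb, labels)
  bb <- logistic_tscore_fit(tsc, labels)
  log_stage("fit", rho = rho, elapsed = round(
    as.numeric(difftime(Sys.time(), t0, units = "secs")), 2), seed = seed)
  cov_stats <- lapply(covariates, function(cv) {
    K <- full$K[[paste0("cov:", cv)]]
    list(values = meta[[cv]], center = attr(K, "center"),
         scale = attr(K, "scale"), sigma = attr(K, "sigma"))
  })
  names(cov_stats) <- covariates
  structure(list(
    kernel_weights = w,
    rho = rho, rho_details = rho_details,
    scores = S,
    sigmas = vapply(full$K, function(K) attr(K, "sigma"), numeric(1)),
    boost = full$boost,
    boost_level = boost_level,
    beta0 = bb$beta0, beta1 = bb$beta1,
    tscores = tsc,
    labels = labels,
    sample_ids = rownames(al$rel),
    otu_ids = colnames(al$rel),
    tree = al$tree,
    rel = al$rel,
    covariates = cov_stats,
    folds = folds, seed = seed),
    class = "mkbmc")
}

#' @export
print.mkbmc <- function(x, ...) {
  cat("Multi-kernel boosted microbiome classifier\n")
  cat(sprintf("  %d training samples (%d cases / %d controls), %d OTUs\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              length(x$otu_ids)))
  cat(sprintf("  rho = %.4g; logistic beta0 = %.3f, beta1 = %.3f\n",
              x$rho, x$beta0, x$beta1))
  cat("  kernel weights:\n")
  for (l in names(x$kernel_weights))
    cat(sprintf("    %-20s %.4f\n", l, x$kernel_weights[l]))
  invisible(x)
}

#' Predict case probabilities for new samples
#'
#' Aligns the test table to the training OTU space (missing training OTUs
#' are zero-filled, extra OTUs dropped; an empty overlap is an error),
#' recomputes branch profiles on the training tree, builds the four
#' boosted cross-distance matrices with the frozen training boosting
#' weights, applies the frozen training bandwidths, combines kernels with
#' the learned weights, scores each test sample with a similarity t-score
#' against the training cases and controls, and maps the t-score through
#' the fitted logistic classifier.  Each prediction depends only on that
#' sample and the training set.
#'
#' @param object a fitted [mkbmc_fit()] model.
#' @param counts test samples x OTUs matrix (counts or proportions).
#' @param meta test metadata data.frame (required only when the model uses
#'   covariate kernels).
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `tscore`, `prob`.
#' @export
predict.mkbmc <- function(object, counts, meta = NULL, ...) {
  stopifnot(is.matrix(counts))
  validate_otu_table(counts)
  common <- intersect(colnames(counts), object$otu_ids)
  if (length(common) == 0)
    stop("test OTU ids have empty overlap with the training OTU set")
  m <- matrix(0, nrow(counts), length(object$otu_ids),
              dimnames = list(rownames(counts), object$otu_ids))
  m[, common] <- counts[, common]
  dropped <- ncol(counts) - length(common)
  if (dropped > 0 || length(common) < length(object$otu_ids))
    message(sprintf(
      "predict: %d test OTU(s) dropped, %d training OTU(s) zero-filled",
      dropped, length(object$otu_ids) - length(common)))
  rel_te <- to_relative_abundance(m)
  bp_tr <- branch_profiles(object$tree, object$rel)
  bp_te <- branch_profiles(object$tree, rel_te)
  Dc <- list(
    weighted_unifrac = weighted_unifrac(bp_tr, object$boost$weighted_unifrac,
                                        newdata = bp_te),
    unweighted_unifrac = unweighted_unifrac(
      bp_tr, object$boost$unweighted_unifrac, newdata = bp_te),
    bray_curtis = bray_curtis(object$rel, object$boost$bray_curtis,
                              newdata = rel_te),
    hamming = hamming(object$rel, object$boost$hamming, newdata = rel_te))
  Kc <- Map(function(nm) cross_kernel(Dc[[nm]], object$sigmas[[nm]]),
            names(Dc))
  names(Kc) <- names(Dc)
  for (cv in names(object$covariates)) {
    if (is.null(meta) || !cv %in% colnames(meta))
      stop("test metadata with covariate '", cv, "' is required")
    st <- object$covariates[[cv]]
    x_tr <- st$values
    Kc[[paste0("cov:", cv)]] <-
      covariate_kernel(x_tr, newdata = meta[rownames(counts), cv], name = cv)
  }
  w <- object$kernel_weights
  Kcomb <- Reduce(`+`, Map(`*`, Kc[names(w)], w))
  tsc <- apply(Kcomb, 1, similarity_tscore, labels = object$labels)
  prob <- plogis(object$beta0 + object$beta1 * tsc)
  data.frame(sample_id = rownames(counts), tscore = as.numeric(tsc),
             prob = as.numeric(prob), row.names = NULL)
}

#' Serialize / restore a fitted model as JSON (+ optional kernel TSVs)
#'
#' Stores everything prediction needs -- kernel weights, bandwidths,
#' boosting weights, logistic coefficients, tuned `rho`, training labels,
#' the training relative-abundance matrix and the (Newick-encoded)
#' training tree -- in a single JSON file.
#'
#' @param model a fitted `mkbmc` object.
#' @param path output JSON path.
#' @param kernel_dir optional directory into which the training kernel
#'   matrices are written as TSV for inspection.
#' @return `path`, invisibly.
#' @export
write_mkbmc <- function(model, path, kernel_dir = NULL) {
  stopifnot(inherits(model, "mkbmc"))
  obj <- list(
    format = "mkbmc-model-1",
    kernel_weights = as.list(model$kernel_weights),
    rho = model$rho,
    scores = as.list(model$scores),
    sigmas = as.list(model$sigmas),
    boost = lapply(model$boost, function(w) {
      as.list(stats::setNames(as.numeric(w), names(w)))
    }),
    boost_level = model$boost_level,
    beta0 = model$beta0, beta1 = model$beta1,
    labels = model$labels,
    sample_ids = model$sample_ids,
    otu_ids = model$otu_ids,
    tree_newick = write_newick(model$tree),
    rel = apply(model$rel, 1, as.numeric, simplify = FALSE),
    covariates = model$covariates,
    folds = model$folds, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(kernel_dir)) {
    dir.create(kernel_dir, showWarnings = FALSE, recursive = TRUE)
    bp <- branch_profiles(model$tree, model$rel)
    ks <- build_kernel_set(model$rel, bp, model$labels,
                           NULL, character(), seq_along(model$labels),
                           boost_level = model$boost_level)
    for (nm in names(ks$K))
      write_distance_matrix(ks$K[[nm]],
                            file.path(kernel_dir, paste0(nm, ".tsv")))
  }
  invisible(path)
}

#' @rdname write_mkbmc
#' @export
read_mkbmc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mkbmc-model-1"))
    stop("not an mkbmc model file: ", path)
  rel <- do.call(rbind, obj$rel)
  dimnames(rel) <- list(obj$sample_ids, obj$otu_ids)
  covs <- lapply(obj$covariates, function(st) {
    list(values = as.numeric(st$values), center = st$center,
         scale = st$scale, sigma = st$sigma)
  })
  structure(list(
    kernel_weights = unlist(obj$kernel_weights),
    rho = obj$rho, rho_details = NULL,
    scores = unlist(obj$scores),
    sigmas = unlist(obj$sigmas),
    boost = lapply(obj$boost, unlist),
    boost_level = obj$boost_level,
    beta0 = obj$beta0, beta1 = obj$beta1,
    tscores = NULL,
    labels = as.numeric(obj$labels),
    sample_ids = obj$sample_ids,
    otu_ids = obj$otu_ids,
    tree = read_newick(obj$tree_newick),
    rel = rel,
    covariates = covs,
    folds = obj$folds, seed = obj$seed),
    class = "mkbmc")
}
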