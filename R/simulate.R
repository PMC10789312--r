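#' Default synthetic Dirichlet-multinomial parameters
#'
#' Generates a synthetic stand-in for the Dirichlet-multinomial parameter
#' set (tree, baseline proportions, over-dispersion) that the simulation
#' design expects: a random coalescent-shaped rooted tree with `q` leaves,
#' baseline proportions drawn from a log-normal (sdlog = 2, giving the
#' heavy rank-abundance skew typical of 16S surveys) normalized to sum 1,
#' and over-dispersion `theta = 0.02`.  A parameter set estimated from real
#' data can be supplied instead via [load_dm_parameters()].
#'
#' @param q number of OTUs (at least 20).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with `tree` (`phylo`), `pi` (named proportions summing to
#'   1) and `theta`.
#' @export
default_parameters <- function(q = 856, seed = NULL) {
  stopifnot(q >= 20)
  gen <- function() {
    tree <- ape::rcoal(q, tip.label = paste0("OTU", seq_len(q)))
    pi <- exp(rnorm(q, 0, 2))
    pi <- pi / sum(pi)
    names(pi) <- tree$tip.label
    list(tree = label_internal_nodes(tree), pi = pi, theta = 0.02)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Load Dirichlet-multinomial parameters from files
#'
#' Reads baseline OTU proportions from a two-column TSV (`otu_id`,
#' `proportion`, with header) and the matching rooted tree from a Newick
#' file, for reproducing simulations with parameters estimated from real
#' data instead of the synthetic defaults.
#'
#' @param pi_path TSV path of baseline proportions.
#' @param tree_path Newick file path.
#' @param theta over-dispersion parameter in (0, 1).
#' @return list with `tree`, `pi`, `theta` (as [default_parameters()]).
#' @export
load_dm_parameters <- function(pi_path, tree_path, theta) {
  stopifnot(is.numeric(theta), theta > 0, theta < 1)
  df <- read.delim(pi_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  pi <- as.numeric(df[[2]])
  names(pi) <- as.character(df[[1]])
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6)
    stop("proportions must be non-negative and sum to 1")
  pi <- pi / sum(pi)
  tree <- read_newick(tree_path)
  if (!setequal(tree$tip.label, names(pi)))
    stop("tree tips and proportion ids differ")
  list(tree = tree, pi = pi[tree$tip.label], theta = theta)
}

#' Simulate over-dispersed OTU count tables
#'
#' Per-sample totals are negative binomial with mean `mean_total` and size
#' `size` (variance `mu + mu^2/size`); given a total, OTU counts are
#' Dirichlet-multinomial with baseline proportions `pi` and
#' over-dispersion `theta`, using the standard concentration
#' `alpha = pi (1 - theta) / theta` (so `theta -> 0` recovers the plain
#' multinomial).
#'
#' @param n number of samples.
#' @param pi named baseline proportions summing to 1.
#' @param theta over-dispersion in (0, 1).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @param mean_total,size negative-binomial total-count parameters.
#' @return samples x OTUs count matrix.
#' @export
dm_counts <- function(n, pi, theta, seed = NULL, mean_total = 1000,
                      size = 25) {
  stopifnot(theta > 0, theta < 1, abs(sum(pi) - 1) < 1e-6)
  q <- length(pi)
  gen <- function() {
    totals <- rnbinom(n, size = size, mu = mean_total)
    alpha <- pi * (1 - theta) / theta
    g <- matrix(rgamma(n * q, shape = rep(alpha, each = n)), n, q)
    rs <- rowSums(g)
    rs[rs == 0] <- 1
    p <- g / rs
    counts <- t(vapply(seq_len(n),
                       function(i) rmultinom(1, totals[i], p[i, ])[, 1],
                       numeric(q)))
    dimnames(counts) <- list(paste0("S", seq_len(n)), names(pi))
    counts
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Partition tree leaves by PAM on the cophenetic distance
#'
#' Classic partitioning-around-medoids (build + swap) on the leaf-to-leaf
#' path-length (cophenetic) distance matrix, used to define
#' phylogenetically related clusters of OTUs.  Deterministic for a given
#' tree.
#'
#' @param tree rooted `phylo`.
#' @param k number of clusters (2 .. number of leaves).
#' @return integer cluster id per leaf, named by tip label.
#' @export
pam_clusters <- function(tree, k = 20) {
  stopifnot(inherits(tree, "phylo"))
  if (k < 2) stop("k must be at least 2")
  nleaf <- length(tree$tip.label)
  if (k > nleaf) stop("k exceeds the number of leaves")
  if (k == nleaf)  # every leaf its own (medoid) cluster, total cost 0
    return(stats::setNames(seq_len(nleaf), tree$tip.label))
  coph <- ape::cophenetic.phylo(tree)
  cl <- cluster::pam(stats::as.dist(coph), k, diss = TRUE,
                     cluster.only = TRUE)
  names(cl) <- rownames(coph)
  cl
}

#' Select signal OTU sets by scenario
#'
#' * Scenario `"I"` (phylogenetically related): all OTUs of the cluster(s)
#'   at the requested total-abundance rank(s).
#' * Scenario `"II"` (phylogenetically unrelated): walking OTUs in
#'   descending abundance, the top OTU of each of `n_unrelated` distinct
#'   clusters.
#' * Scenario `"III"`: both -- a related set `G1` (by `ranks`) and an
#'   unrelated set `G2` drawn from the remaining clusters, disjoint by
#'   construction.
#'
#' Abundance ranks are taken from the baseline composition (the expected
#' relative abundances), so the signal sets are a fixed property of the
#' parameter set rather than of one realized sample pool -- training and
#' testing replicates of the same configuration share the same signal
#' OTUs.
#'
#' @param clusters named cluster assignment from [pam_clusters()].
#' @param abundance baseline per-OTU relative abundances: a named vector
#'   (e.g. the Dirichlet-multinomial proportions) or a samples x OTUs
#'   matrix whose column means are used.
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param ranks abundance rank(s) of the signal cluster(s) for scenarios
#'   I/III.
#' @param n_unrelated number of scattered signal OTUs for scenarios
#'   II/III.
#' @return list with element `G` (scenarios I/II) or elements `G1`, `G2`
#'   (scenario III); character OTU ids.
#' @export
select_signals <- function(clusters, abundance,
                           scenario = c("I", "II", "III"),
                           ranks = 2, n_unrelated = 9) {
  scenario <- match.arg(scenario)
  otus <- names(clusters)
  if (is.matrix(abundance)) abundance <- colMeans(abundance)
  stopifnot(all(otus %in% names(abundance)))
  ab <- abundance[otus]
  cluster_ab <- tapply(ab, clusters, sum)
  ranked <- as.integer(names(sort(cluster_ab, decreasing = TRUE)))
  pick_related <- function(rks) {
    if (any(rks > length(ranked))) stop("cluster rank exceeds k")
    otus[clusters %in% ranked[rks]]
  }
  pick_unrelated <- function(m, exclude = integer()) {
    ord <- otus[order(ab, decreasing = TRUE)]
    sel <- character(0)
    used <- exclude
    for (o in ord) {
      cl <- clusters[[o]]
      if (cl %in% used) next
      sel <- c(sel, o)
      used <- c(used, cl)
      if (length(sel) == m) break
    }
    if (length(sel) < m)
      stop("not enough distinct clusters for ", m, " unrelated signal OTUs")
    sel
  }
  switch(scenario,
         I = list(G = pick_related(ranks)),
         II = list(G = pick_unrelated(n_unrelated)),
         III = {
           G1 <- pick_related(ranks)
           G2 <- pick_unrelated(n_unrelated,
                                exclude = unique(clusters[G1]))
           list(G1 = G1, G2 = G2)
         })
}

# Linear predictor of the outcome models.  For scenarios I/II `model` is
# "A" (abundance: sum of signal relative abundances) or "B" (presence:
# count of present signal OTUs); for scenario III `model` is a combination
# id 1..4 pairing a term on the related set G1 with one on the unrelated
# set G2.  scale() standardizes over the generated pool.
linear_predictor <- function(rel, signals, model, beta) {
  term <- function(G, type) {
    v <- if (type == "A") rowSums(rel[, G, drop = FALSE])
         else rowSums(rel[, G, drop = FALSE] > 0)
    if (sd(v) <= 1e-12 * max(1, abs(mean(v))))
      stop("signal predictor is constant over the pool; scale() undefined")
    as.numeric(scale(v))
  }
  if (model %in% c("A", "B")) {
    stopifnot(length(beta) == 1)
    beta * term(signals$G, model)
  } else {
    combo <- as.integer(model)
    stopifnot(combo %in% 1:4, length(beta) == 2,
              !is.null(signals$G1), !is.null(signals$G2))
    types <- list(c("B", "B"), c("B", "A"), c("A", "B"), c("A", "A"))[[combo]]
    beta[1] * term(signals$G1, types[1]) + beta[2] * term(signals$G2, types[2])
  }
}

#' Simulate balanced case-control labels from a pool of samples
#'
#' Computes the scenario's linear predictor over the pool (with `scale()`
#' standardizing over the whole pool), draws `y ~ Bernoulli(expit(eta))`,
#' and subsamples exactly `n_cases` cases and `n_controls` controls
#' without replacement, emulating a balanced retrospective design.
#'
#' @param rel pool relative-abundance matrix.
#' @param signals signal sets from [select_signals()].
#' @param model `"A"`, `"B"`, or a scenario-III combination id 1..4.
#' @param beta effect size (length 2 for scenario III).
#' @param n_cases,n_controls target class sizes.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return list with `index` (selected pool rows), `label` (0/1) and
#'   `eta` (pool linear predictor); errors with condition class
#'   `mkbmc_pool_exhausted` when the pool lacks a class.
#' @export
simulate_outcome <- function(rel, signals, model, beta, n_cases,
                             n_controls, seed = NULL) {
  eta <- linear_predictor(rel, signals, model, beta)
  gen <- function() {
    y <- rbinom(length(eta), 1, plogis(eta))
    i1 <- which(y == 1); i0 <- which(y == 0)
    if (length(i1) < n_cases || length(i0) < n_controls) {
      cond <- structure(
        class = c("mkbmc_pool_exhausted", "error", "condition"),
        list(message = "pool does not contain enough cases or controls",
             call = sys.call(-1)))
      stop(cond)
    }
    sel1 <- sample(i1, n_cases)
    sel0 <- sample(i0, n_controls)
    list(index = c(sel1, sel0),
         label = rep(c(1, 0), c(n_cases, n_controls)),
         eta = eta)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate one balanced case-control microbiome dataset
#'
#' Full data-generating process: Dirichlet-multinomial counts over a
#' sample pool, PAM clustering of the tree, scenario-specific signal-OTU
#' selection, logistic outcome model, and balanced subsampling of `n/2`
#' cases and `n/2` controls.  The pool is grown (doubling, starting at
#' `pool_factor * n`) until both classes are large enough, up to `100 * n`
#' draws.
#'
#' Default signal clusters for scenario I follow the simulation design:
#' abundance rank 2 for model A and rank 8 for model B (and for the
#' related set of scenario III).
#'
#' @param n samples in the emitted dataset (even; `n/2` per class).
#' @param q number of OTUs when generating default parameters.
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param model `"A"`, `"B"` (scenarios I/II) or combination id 1..4
#'   (scenario III).
#' @param beta effect size(s); length 2 for scenario III.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @param params parameter list from [default_parameters()] or
#'   [load_dm_parameters()]; generated from `seed` when `NULL`.
#' @param k_clusters number of PAM clusters.
#' @param ranks signal-cluster abundance rank(s); `NULL` for the
#'   model-specific default.
#' @param n_unrelated number of scattered signal OTUs (scenarios II/III).
#' @param pool_factor initial pool size multiplier.
#' @return list with `counts`, `rel`, `meta` (data.frame with `label`),
#'   `tree`, `signals`, `eta` (true linear predictor of the selected
#'   samples), `params` and `config`.
#' @export
simulate_dataset <- function(n = 500, q = 856,
                             scenario = c("I", "II", "III"), model = "A",
                             beta = 2, seed = NULL, params = NULL,
                             k_clusters = 20, ranks = NULL,
                             n_unrelated = 9, pool_factor = 3) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 4, n %% 2 == 0)
  if (is.null(ranks))
    ranks <- if (identical(model, "B")) 8 else 2
  gen <- function() {
    if (is.null(params)) params <- default_parameters(q)
    clusters <- pam_clusters(params$tree, k_clusters)
    signals <- select_signals(clusters, params$pi, scenario, ranks,
                              n_unrelated)
    m <- pool_factor * n
    out <- NULL
    repeat {
      counts <- dm_counts(m, params$pi, params$theta)
      rel <- to_relative_abundance(counts)
      out <- tryCatch(
        simulate_outcome(rel, signals, model, beta, n / 2, n / 2),
        mkbmc_pool_exhausted = function(e) NULL)
      if (!is.null(out)) break
      m <- m * 2
      if (m > 100 * n)
        stop("pool exhausted after 100x target draws; ",
             "check the outcome model for degeneracy")
    }
    idx <- out$index
    counts <- counts[idx, , drop = FALSE]
    rel <- rel[idx, , drop = FALSE]
    ids <- paste0("S", seq_along(idx))
    rownames(counts) <- rownames(rel) <- ids
    meta <- data.frame(label = out$label, row.names = ids)
    list(counts = counts, rel = rel, meta = meta, tree = params$tree,
         signals = signals, eta = out$eta[idx], params = params,
         config = list(n = n, q = length(params$pi), scenario = scenario,
                       model = model, beta = beta, k_clusters = k_clusters,
                       ranks = ranks, n_unrelated = n_unrelated,
                       seed = seed))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Mean oracle AUC under the standard-normal surrogate predictor
#'
#' The summed signal abundance is standardized by `scale()`, so the
#' oracle's standardized predictor is approximately standard normal.  This
#' helper draws `z ~ N(0, 1)` pools, labels
#' `y ~ Bernoulli(expit(beta * z))`, subsamples balanced testing sets, and
#' scores each sample by its true linear predictor, giving the
#' distribution of the best achievable (oracle) testing AUC.
#'
#' @param beta effect size.
#' @param n_cases,n_controls testing-set class sizes.
#' @param reps number of testing sets.
#' @param seed integer seed.
#' @param pool_factor pool size multiplier per testing set.
#' @return list with `mean_auc`, `q025`, `q975` and the per-replicate
#'   `aucs`.
#' @export
oracle_auc <- function(beta = 2, n_cases = 250, n_controls = 250,
                       reps = 1000, seed = 1, pool_factor = 5) {
  gen <- function() {
    aucs <- vapply(seq_len(reps), function(r) {
      m <- pool_factor * (n_cases + n_controls)
      repeat {
        z <- rnorm(m)
        y <- rbinom(m, 1, plogis(beta * z))
        if (sum(y == 1) >= n_cases && sum(y == 0) >= n_controls) break
        m <- m * 2
      }
      sel <- c(sample(which(y == 1), n_cases),
               sample(which(y == 0), n_controls))
      auc(beta * z[sel], y[sel])
    }, numeric(1))
    list(mean_auc = mean(aucs),
         q025 = unname(quantile(aucs, 0.025)),
         q975 = unname(quantile(aucs, 0.975)),
         aucs = aucs)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Run a simulation scenario end to end over replicates
#'
#' For each replicate, draws an independent training and testing set from
#' the same parameter set, fits the multi-kernel classifier on the
#' training set, predicts the testing set, and records the testing AUC
#' (plus sensitivity/specificity at 0.5 and the fitted kernel weights).
#'
#' @inheritParams simulate_dataset
#' @param reps number of replicates.
#' @param rho fixed regularization strength, or `NULL` to tune per
#'   replicate by cross-validation.
#' @param folds cross-validation folds when tuning.
#' @return list with `results` (one row per replicate: auc, sensitivity,
#'   specificity), `weights` (replicates x kernels matrix) and `summary`
#'   (mean AUC with 0.025/0.975 quantiles).
#' @export
mkbmc_replicate <- function(reps = 10, n = 500, q = 856, scenario = "I",
                            model = "A", beta = 2, seed = 1, params = NULL,
                            rho = NULL, folds = 5, k_clusters = 20,
                            ranks = NULL, n_unrelated = 9) {
  run <- function() {
    if (is.null(params)) params <- default_parameters(q)
    res <- vector("list", reps)
    for (r in seq_len(reps)) {
      train <- simulate_dataset(n, q, scenario, model, beta, params = params,
                                k_clusters = k_clusters, ranks = ranks,
                                n_unrelated = n_unrelated)
      test <- simulate_dataset(n, q, scenario, model, beta, params = params,
                               k_clusters = k_clusters, ranks = ranks,
                               n_unrelated = n_unrelated)
      fit_seed <- sample.int(2^30, 1)
      model_fit <- suppressWarnings(
        mkbmc_fit(train$counts, train$tree, train$meta, rho = rho,
                  folds = folds, seed = fit_seed))
      pred <- suppressMessages(predict(model_fit, test$counts))
      ss <- sens_spec(pred$prob, test$meta$label)
      res[[r]] <- list(auc = auc(pred$prob, test$meta$label),
                       sensitivity = unname(ss[1]),
                       specificity = unname(ss[2]),
                       weights = model_fit$kernel_weights)
      log_stage("replicate", r = r, auc = round(res[[r]]$auc, 4))
    }
    aucs <- vapply(res, `[[`, numeric(1), "auc")
    list(results = data.frame(
           replicate = seq_len(reps),
           auc = aucs,
           sensitivity = vapply(res, `[[`, numeric(1), "sensitivity"),
           specificity = vapply(res, `[[`, numeric(1), "specificity")),
         weights = do.call(rbind, lapply(res, `[[`, "weights")),
         summary = list(mean_auc = mean(aucs),
                        q025 = unname(quantile(aucs, 0.025)),
                        q975 = unname(quantile(aucs, 0.975)),
                        reps = reps))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
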