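test_that("default parameters are reproducible and well-formed", {
  p1 <- default_parameters(40, seed = 5)
  p2 <- default_parameters(40, seed = 5)
  expect_equal(sum(p1$pi), 1, tolerance = 1e-12)
  expect_length(p1$tree$tip.label, 40)
  expect_gte(nrow(p1$tree$edge), 40)
  expect_identical(p1$pi, p2$pi)
  expect_identical(write_newick(p1$tree), write_newick(p2$tree))
  expect_error(default_parameters(10), "q >= 20")
})

test_that("Dirichlet-multinomial counts have the designed totals and means", {
  withr::with_seed(9, {
    pi <- exp(rnorm(30, 0, 1)); pi <- pi / sum(pi)
    names(pi) <- paste0("OTU", 1:30)
  })
  counts <- dm_counts(10000, pi, theta = 0.02, seed = 10)
  totals <- rowSums(counts)
  # negative binomial with mean 1000, size 25
  se <- sqrt(1000 + 1000^2 / 25) / sqrt(10000)
  expect_lt(abs(mean(totals) - 1000) / se, 2)
  # column relative-abundance means converge to pi
  rel <- suppressWarnings(to_relative_abundance(counts))
  keep <- totals > 0
  mc_se <- apply(rel[keep, ], 2, sd) / sqrt(sum(keep))
  expect_true(all(abs(colMeans(rel[keep, ]) - pi) < 5 * mc_se + 1e-4))
  # reproducible given a seed
  expect_identical(counts, dm_counts(10000, pi, theta = 0.02, seed = 10))
})

test_that("over-dispersion behaves as theta prescribes", {
  withr::with_seed(12, {
    pi <- rep(1 / 20, 20)
    names(pi) <- paste0("OTU", 1:20)
  })
  n <- 4000
  rel_od <- suppressWarnings(
    to_relative_abundance(dm_counts(n, pi, theta = 0.02, seed = 1)))
  rel_mn <- suppressWarnings(
    to_relative_abundance(dm_counts(n, pi, theta = 1e-6, seed = 2)))
  # multinomial benchmark: Var(p_hat) ~= pi (1 - pi) E[1/N]
  Ndraws <- mkbmc:::with_seed(3, rnbinom(20000, size = 25, mu = 1000))
  e_inv_n <- mean(1 / Ndraws[Ndraws > 0])
  v_mult <- pi[1] * (1 - pi[1]) * e_inv_n
  v_od <- mean(apply(rel_od, 2, var))
  v_mn <- mean(apply(rel_mn, 2, var))
  expect_gt(v_od / v_mult, 5)          # strong extra-multinomial variance
  expect_lt(abs(v_mn / v_mult - 1), 0.1)  # theta -> 0 recovers multinomial
})

test_that("PAM clustering recovers well-separated clades", {
  tree <- read_newick(paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):100,((E:1,F:1):1,(G:1,H:1):1):100);"))
  cl <- pam_clusters(tree, k = 2)
  expect_length(unique(cl), 2)
  expect_length(unique(cl[c("A", "B", "C", "D")]), 1)
  expect_length(unique(cl[c("E", "F", "G", "H")]), 1)
  expect_false(cl[["A"]] == cl[["E"]])
  # k = number of leaves: singletons
  expect_equal(sort(unname(pam_clusters(tree, k = 8))), 1:8)
  expect_error(pam_clusters(tree, k = 1), "at least 2")
  expect_error(pam_clusters(tree, k = 9), "exceeds")
})

test_that("signal selection follows the scenario definitions", {
  params <- default_parameters(60, seed = 31)
  cl <- pam_clusters(params$tree, k = 6)
  # rank 1: all OTUs of the most abundant cluster
  s1 <- select_signals(cl, params$pi, "I", ranks = 1)
  cl_ab <- tapply(params$pi[names(cl)], cl, sum)
  top <- as.integer(names(which.max(cl_ab)))
  expect_setequal(s1$G, names(cl)[cl == top])
  expect_error(select_signals(cl, params$pi, "I", ranks = 9), "rank")
  # scenario II: scattered OTUs, one per cluster, descending abundance
  s2 <- select_signals(cl, params$pi, "II", n_unrelated = 5)
  expect_length(s2$G, 5)
  expect_length(unique(cl[s2$G]), 5)
  # scenario III: related and unrelated sets are disjoint
  s3 <- select_signals(cl, params$pi, "III", ranks = 2, n_unrelated = 4)
  expect_length(intersect(s3$G1, s3$G2), 0)
  expect_false(any(cl[s3$G2] %in% cl[s3$G1]))
  # selection is a function of the parameters, not of a realized pool
  expect_identical(s1, select_signals(cl, params$pi, "I", ranks = 1))
})

test_that("outcome simulation is balanced and null at beta = 0", {
  params <- default_parameters(50, seed = 41)
  cl <- pam_clusters(params$tree, k = 5)
  rel <- suppressWarnings(
    to_relative_abundance(dm_counts(10000, params$pi, 0.02, seed = 42)))
  sig <- select_signals(cl, params$pi, "I", ranks = 1)
  out <- simulate_outcome(rel, sig, "A", beta = 0, 500, 500, seed = 43)
  expect_equal(sum(out$label), 500)
  expect_length(out$index, 1000)
  pred <- rowSums(rel[out$index, sig$G, drop = FALSE])
  expect_lt(abs(auc(pred, out$label) - 0.5), 0.05)
  # predictor constant over the pool: scale() undefined
  all_sig <- list(G = colnames(rel))
  expect_error(simulate_outcome(rel, all_sig, "A", 2, 10, 10), "constant")
})

test_that("datasets are balanced, deterministic and carry detectable signal", {
  sim1 <- simulate_dataset(n = 100, q = 60, scenario = "I", model = "A",
                           beta = 2, seed = 51)
  sim2 <- simulate_dataset(n = 100, q = 60, scenario = "I", model = "A",
                           beta = 2, seed = 51)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$meta, sim2$meta)
  expect_equal(sum(sim1$meta$label), 50)
  # scenario I model A, beta = 3, n = 500: the summed signal abundance
  # separates the groups strongly enough for the boosting stage to see it
  sim <- simulate_dataset(n = 500, q = 856, scenario = "I", model = "A",
                          beta = 3, seed = 52)
  sig_ab <- rowSums(sim$rel[, sim$signals$G, drop = FALSE])
  expect_lt(t.test(sig_ab ~ sim$meta$label)$p.value, 1e-6)
})

test_that("scenario III combinations build two-term predictors", {
  params <- default_parameters(80, seed = 61)
  sim <- simulate_dataset(n = 60, q = 80, scenario = "III", model = 2,
                          beta = c(2, 2), seed = 62, params = params,
                          k_clusters = 8, n_unrelated = 4)
  expect_length(intersect(sim$signals$G1, sim$signals$G2), 0)
  expect_equal(sum(sim$meta$label), 30)
})
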