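test_that("CC matrix encodes pairwise class agreement", {
  cc <- cc_matrix(c(1, 1, 0))
  expect_equal(unname(cc),
               rbind(c(0, 1, -1), c(1, 0, -1), c(-1, -1, 0)))
  expect_equal(sum(cc), -2)
  withr::with_seed(2, {
    y <- rbinom(15, 1, 0.5); y[1] <- 1; y[2] <- 0
    expect_equal(cc_matrix(y), t(cc_matrix(y)))
  })
  expect_error(cc_matrix(c(1, 1, 1)), "single class")
})

test_that("kernel-alignment score is the full double sum and linear", {
  y <- c(1, 1, 0)
  cc <- cc_matrix(y)
  expect_equal(kernel_score(diag(3), cc), 0)
  expect_equal(kernel_score(matrix(1, 3, 3), cc), -2)
  withr::with_seed(8, {
    K <- matrix(runif(9), 3, 3); K <- (K + t(K)) / 2
    s0 <- kernel_score(K, cc)
    Kshift <- K + 0.3; diag(Kshift) <- diag(K)
    expect_equal(kernel_score(Kshift, cc), s0 + 0.3 * sum(cc),
                 tolerance = 1e-12)
  })
  expect_error(kernel_score(diag(2), cc), "shape")
})

test_that("closed-form weights match softmax limits and the rho = 0 rule", {
  expect_equal(unname(solve_weights(c(5, 5), 2)), c(0.5, 0.5))
  w <- solve_weights(c(1, 0), 1)
  expect_equal(unname(w), c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
               tolerance = 1e-12)
  expect_equal(unname(solve_weights(c(1, 0), 1e9)), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(unname(solve_weights(c(3, 7, 7), 0)), c(0, 0.5, 0.5))
  expect_equal(unname(solve_weights(c(3, 7, 2), 0)), c(0, 1, 0))
  # overflow safety for scores of the magnitude the double sum produces
  w_big <- solve_weights(c(2e5, 1e5, -3e5), 10)
  expect_true(all(is.finite(w_big)) && abs(sum(w_big) - 1) < 1e-12)
})

test_that("closed-form weights minimize the entropy-regularized objective", {
  withr::with_seed(13, {
    for (L in c(2, 3, 5)) {
      S <- rnorm(L, sd = 2)
      for (rho in c(0.3, 1, 5)) {
        w <- solve_weights(S, rho)
        obj <- mk_objective(w, S, rho)
        for (i in 1:200) {
          r <- rexp(L); r <- r / sum(r)
          expect_gte(mk_objective(r, S, rho), obj - 1e-10)
        }
      }
    }
  })
})

test_that("weights order with scores and flatten as rho grows", {
  withr::with_seed(17, {
    S <- c(a = 2.3, b = -1, c = 0.4, d = 2.1)
    ent <- sapply(c(0.1, 0.5, 1, 5, 20, 100), function(r) {
      w <- solve_weights(S, r)
      expect_equal(order(w), order(S))  # S_a > S_b => w_a > w_b
      mkbmc:::weight_entropy(w)
    })
    expect_true(all(diff(ent) >= -1e-12))
  })
})

test_that("rho_max doubling search meets its entropy target", {
  expect_equal(rho_max(c(4, 4, 4)), 1.0)
  expect_equal(rho_max(c(1, 0)), 16)
  # entropy bracketing at the returned value
  target <- (1 - 1e-3) * log(2)
  expect_lt(mkbmc:::weight_entropy(solve_weights(c(1, 0), 8)), target)
  expect_gte(mkbmc:::weight_entropy(solve_weights(c(1, 0), 16)), target)
  # nondecreasing in the score spread
  spreads <- seq(0.5, 20, by = 0.5)
  rhos <- sapply(spreads, function(s) rho_max(c(s, 0)))
  expect_true(all(diff(rhos) >= 0))
})

test_that("similarity t-scores follow the Welch formula", {
  sims <- c(0.9, 0.8, 0.1, 0.2)
  y <- c(1, 1, 0, 0)
  expect_equal(similarity_tscore(sims, y), 0.7 / sqrt(0.005),
               tolerance = 1e-9)
  # identical similarity sets in the two groups
  expect_equal(similarity_tscore(c(0.3, 0.7, 0.3, 0.7), y), 0)
  # label swap negates the score
  expect_equal(similarity_tscore(sims, 1 - y), -similarity_tscore(sims, y))
  # leave-self-out drops the indexed entry
  s5 <- c(1, 0.9, 0.8, 0.1, 0.2)
  y5 <- c(1, 1, 1, 0, 0)
  expect_equal(similarity_tscore(s5, y5, self_index = 1),
               similarity_tscore(s5[-1], y5[-1]))
  expect_error(similarity_tscore(c(1, 0, 1), c(1, 0, 1)), "at least 2")
  expect_warning(t0 <- similarity_tscore(rep(0.5, 8), rep(c(1, 0), 4)),
                 "zero variance")
  expect_equal(t0, 0)
})

test_that("rho tuning has an 11-point grid and prefers informative kernels", {
  withr::with_seed(23, {
    n <- 120
    y <- rep(c(1, 0), n / 2)
    x_inf <- y + rnorm(n, sd = 0.6)
    x_noise <- rnorm(n)
    mkK <- function(x) {
      D <- abs(outer(x, x, "-"))
      gaussian_kernel(D)
    }
    kernels <- list(inf = mkK(x_inf), noise = mkK(x_noise))
    rho <- tune_rho(kernels, y, seed = 9)
    grid <- attr(rho, "grid")
    expect_length(grid, 11)
    expect_equal(grid[1], 0)
    S <- vapply(kernels, kernel_score, numeric(1), CC = cc_matrix(y))
    w <- solve_weights(S, max(as.numeric(rho), grid[2]))
    expect_gt(w[["inf"]], 0.5)
    # two identical kernels: every rho ties, the largest wins
    rho_tie <- tune_rho(list(kernels$inf, kernels$inf), y, seed = 9)
    expect_equal(as.numeric(rho_tie), max(attr(rho_tie, "grid")))
  })
})

test_that("fitted models have simplex weights and sane training state", {
  toy <- separable_toy(n_per = 10)
  fit <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta, rho = 1,
                                    seed = 2))
  expect_s3_class(fit, "mkbmc")
  expect_equal(sum(fit$kernel_weights), 1, tolerance = 1e-12)
  expect_true(all(fit$kernel_weights >= 0))
  expect_length(fit$kernel_weights, 4)
  probs <- plogis(fit$beta0 + fit$beta1 * fit$tscores)
  expect_gt(auc(probs, fit$labels), 0.9)  # separable by construction
})

test_that("fitting is invariant to sample order", {
  toy <- separable_toy(n_per = 8)
  fit1 <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta, rho = 2))
  perm <- withr::with_seed(3, sample(nrow(toy$counts)))
  fit2 <- suppressWarnings(mkbmc_fit(toy$counts[perm, ], toy$tree,
                                     toy$meta[perm, , drop = FALSE], rho = 2))
  expect_equal(fit2$kernel_weights, fit1$kernel_weights, tolerance = 1e-9)
  p1 <- suppressMessages(predict(fit1, toy$counts))
  p2 <- suppressMessages(predict(fit2, toy$counts))
  expect_equal(p2$prob, p1$prob, tolerance = 1e-9)
})

test_that("prediction separates duplicated cases from duplicated controls", {
  toy <- separable_toy(n_per = 10)
  fit <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta, rho = 1))
  case_row <- toy$counts[which(toy$meta$label == 1)[1], , drop = FALSE]
  ctrl_row <- toy$counts[which(toy$meta$label == 0)[1], , drop = FALSE]
  test_counts <- rbind(case_row, ctrl_row)
  rownames(test_counts) <- c("T_case", "T_ctrl")
  pred <- suppressMessages(predict(fit, test_counts))
  expect_true(all(pred$prob > 0 & pred$prob < 1))
  expect_gt(pred$prob[pred$sample_id == "T_case"],
            pred$prob[pred$sample_id == "T_ctrl"])
})

test_that("predictions do not depend on other test samples", {
  toy <- separable_toy(n_per = 8)
  fit <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta, rho = 1))
  withr::with_seed(4, {
    batch <- matrix(rexp(5 * ncol(toy$counts)), 5,
                    dimnames = list(paste0("T", 1:5), colnames(toy$counts)))
  })
  p_all <- suppressMessages(predict(fit, batch))
  p_one <- suppressMessages(predict(fit, batch[2, , drop = FALSE]))
  expect_equal(p_one$prob, p_all$prob[2], tolerance = 1e-12)
})

test_that("models survive a JSON round trip", {
  toy <- separable_toy(n_per = 8)
  fit <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta, rho = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_mkbmc(fit, f)
  fit2 <- read_mkbmc(f)
  expect_equal(fit2$kernel_weights, fit$kernel_weights, tolerance = 1e-12)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-12)
  p1 <- suppressMessages(predict(fit, toy$counts))
  p2 <- suppressMessages(predict(fit2, toy$counts))
  expect_equal(p2$prob, p1$prob, tolerance = 1e-9)
})

test_that("covariate kernels enter the model and prediction", {
  toy <- separable_toy(n_per = 8)
  withr::with_seed(6, {
    toy$meta$age <- toy$meta$label * 2 + rnorm(nrow(toy$meta))
  })
  fit <- suppressWarnings(mkbmc_fit(toy$counts, toy$tree, toy$meta,
                                    covariates = "age", rho = 1))
  expect_length(fit$kernel_weights, 5)
  expect_true("cov:age" %in% names(fit$kernel_weights))
  pred <- suppressMessages(predict(fit, toy$counts, meta = toy$meta))
  expect_true(all(is.finite(pred$prob)))
  expect_error(suppressMessages(predict(fit, toy$counts)), "age")
})
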