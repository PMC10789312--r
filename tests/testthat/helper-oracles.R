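# Shared fixtures and independent oracles for the test suite.  The oracles
# deliberately use a different algorithmic route than the package: branch
# profiles by per-branch descendant enumeration, UniFrac by explicit
# per-pair loops over branches, AUC by all-pairs concordance counting.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# Random rooted tree with positive branch lengths and q tips.
random_tree <- function(q, tip_prefix = "OTU") {
  tree <- ape::rtree(q, tip.label = paste0(tip_prefix, seq_len(q)))
  tree$edge.length <- tree$edge.length + 0.05
  mkbmc:::label_internal_nodes(tree)
}

# Random relative-abundance table over the tree's tips with sparse zeros.
random_rel <- function(n, tree, zero_frac = 0.3) {
  q <- length(tree$tip.label)
  m <- matrix(rexp(n * q), n, q)
  m[matrix(runif(n * q) < zero_frac, n, q)] <- 0
  for (i in seq_len(n)) if (sum(m[i, ]) == 0) m[i, 1] <- 1
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("S", seq_len(n)), tree$tip.label)
  m
}

# Brute-force branch profiles: for each branch, enumerate the descendant
# leaves by recursion on the edge table and sum their abundances.
oracle_branch_profiles <- function(tree, rel) {
  ntip <- length(tree$tip.label)
  descend <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descend))
  }
  children <- tree$edge[, 2]
  out <- vapply(children, function(ch) {
    rowSums(rel[, descend(ch), drop = FALSE])
  }, numeric(nrow(rel)))
  labels <- c(tree$tip.label, tree$node.label)
  colnames(out) <- labels[children]
  rownames(out) <- rownames(rel)
  out
}

# Explicit pairwise UniFrac from oracle profiles (a = boosting weights).
oracle_unifrac <- function(tree, rel, a = NULL, presence = FALSE) {
  prof <- oracle_branch_profiles(tree, rel)
  b <- tree$edge.length
  if (is.null(a)) a <- rep(1, length(b))
  else a <- a[colnames(prof)]
  n <- nrow(prof)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pi <- prof[i, ]; pj <- prof[j, ]
    if (presence) {
      num <- sum(b * a * abs((pi > 0) - (pj > 0)))
      den <- sum(b * a * ((pi + pj) > 0))
    } else {
      num <- sum(b * a * abs(pi - pj))
      den <- sum(b * a * (pi + pj))
    }
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# Textbook Bray-Curtis with its explicit denominator.
oracle_bray_curtis <- function(rel) {
  n <- nrow(rel)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- sum(rel[i, ] + rel[j, ])
    d[i, j] <- if (den == 0) 0 else sum(abs(rel[i, ] - rel[j, ])) / den
  }
  d
}

# Presence-mismatch count via XOR.
oracle_hamming <- function(rel) {
  pres <- rel > 0
  n <- nrow(rel)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(xor(pres[i, ], pres[j, ]))
  d
}

# All-pairs concordance AUC with half-credit ties.
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  conc <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(conc)
}

# Entropy-regularized objective of the kernel-weight problem.
mk_objective <- function(w, S, rho) {
  -sum(w * S) + rho * sum(ifelse(w > 0, w * log(w), 0))
}

# Brute-force minimizer over a simplex grid with the given step.
oracle_simplex_min <- function(S, rho, step = 1e-3) {
  L <- length(S)
  if (L == 2) {
    w1 <- seq(0, 1, by = step)
    obj <- -(w1 * S[1] + (1 - w1) * S[2]) +
      rho * (ifelse(w1 > 0, w1 * log(w1), 0) +
               ifelse(w1 < 1, (1 - w1) * log(1 - w1), 0))
    best <- which.min(obj)
    c(w1[best], 1 - w1[best])
  } else if (L == 3) {
    g <- seq(0, 1, by = step)
    grid <- expand.grid(w1 = g, w2 = g)
    grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
    w3 <- pmax(1 - grid$w1 - grid$w2, 0)
    ent <- function(x) ifelse(x > 0, x * log(x), 0)
    obj <- -(grid$w1 * S[1] + grid$w2 * S[2] + w3 * S[3]) +
      rho * (ent(grid$w1) + ent(grid$w2) + ent(w3))
    best <- which.min(obj)
    c(grid$w1[best], grid$w2[best], w3[best])
  } else stop("oracle supports L = 2 or 3")
}

# Small planted-signal dataset for classifier tests: two groups with
# disjoint dominant OTU support.
separable_toy <- function(n_per = 10, q = 12, seed = 99) {
  mkbmc:::with_seed(seed, {
    tree <- random_tree(q)
    n <- 2 * n_per
    m <- matrix(rexp(n * q) * 0.05, n, q)
    m[matrix(runif(n * q) < 0.6, n, q)] <- 0  # sparse background
    half <- q %/% 2
    for (i in seq_len(n_per)) m[i, seq_len(half)] <- rexp(half) + 2
    for (i in (n_per + 1):n) m[i, (half + 1):q] <- rexp(q - half) + 2
    dimnames(m) <- list(paste0("S", seq_len(n)), tree$tip.label)
    meta <- data.frame(label = rep(c(1, 0), each = n_per),
                       row.names = rownames(m))
    list(counts = m, tree = tree, meta = meta)
  })
}

# Compare numeric matrices ignoring dimnames and metadata attributes.
expect_mat_equal <- function(actual, expected, tol = 1e-12) {
  testthat::expect_equal(unname(actual), unname(expected), tolerance = tol,
                         ignore_attr = TRUE)
}
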