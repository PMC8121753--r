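test_that("PCA matches the SVD oracle and reconstructs the data", {
  set.seed(14)
  # rank-1 matrix: PC1 carries all variance
  u <- rnorm(12)
  v <- rnorm(30)
  X1 <- outer(u, v)
  p1 <- pca_fit(X1, 2, scaling = "center")
  expect_equal(p1$explained[1], 1)
  # full-rank reconstruction
  X <- matrix(rnorm(10 * 6), 10, 6)
  pf <- pca_fit(X, 6, scaling = "center")
  Xs <- sweep(X, 2, colMeans(X))
  expect_equal(pf$scores %*% t(pf$loadings), Xs, tolerance = 1e-8)
  # random matrices vs direct SVD
  for (i in 1:5) {
    Y <- matrix(rnorm(20 * 50), 20, 50)
    Ys <- sweep(Y, 2, colMeans(Y))
    sv <- svd(Ys)
    pp <- pca_fit(Y, 4, scaling = "center")
    for (k in 1:4) {
      oracle <- sv$u[, k] * sv$d[k]
      expect_lt(min(max(abs(pp$scores[, k] - oracle)),
                    max(abs(pp$scores[, k] + oracle))), 1e-8)
    }
    expect_true(all(diff(pp$explained) <= 1e-12))
  }
  const <- cbind(X, 5)
  expect_error(pca_fit(const, 2, scaling = "uv"), "constant")
})

test_that("single-block MB-HPCA reproduces PCA; identical blocks share weights", {
  set.seed(15)
  X <- matrix(rnorm(18 * 40), 18, 40)
  m1 <- mbhpca_fit(list(a = X), 3, block_scaling = "none")
  p <- pca_fit(X, 3, scaling = "center")
  for (k in 1:3) {
    expect_lt(min(max(abs(m1$super_scores[, k] - p$scores[, k])),
                  max(abs(m1$super_scores[, k] + p$scores[, k]))), 1e-6)
  }
  # consensus scores orthogonal across components
  expect_lt(abs(sum(m1$consensus_scores[, 1] * m1$consensus_scores[, 2])),
            1e-8)
  # two identical blocks: equal super weights, identical block loadings
  m2 <- mbhpca_fit(list(a = X, b = X), 2)
  expect_equal(m2$super_weights[1, ], m2$super_weights[2, ], tolerance = 1e-8)
  expect_equal(m2$block_loadings$a, m2$block_loadings$b, tolerance = 1e-8)
  expect_true(all(m2$converged))
  # unit-length block loadings
  expect_equal(colSums(m2$block_loadings$a^2), rep(1, 2), tolerance = 1e-10)
  expect_error(mbhpca_fit(list(a = X, b = X[1:5, ])), "identical dimensions")
})

test_that("MB-HPCA ranks nitrogen-responsive features above null features", {
  # common nitrogen trend injected in every variety block
  hit_rates <- vapply(1:3, function(s) {
    set.seed(s)
    n_feat <- 60
    n_resp <- 10
    doses <- rep(c(0, 60, 120, 180, 230, 280), each = 3)
    meta <- expand.grid(replicate = 1:3, n_level = unique(doses),
                        variety = c("V1", "V2", "V3", "V4"))
    X <- matrix(rnorm(nrow(meta) * n_feat), nrow(meta), n_feat)
    for (j in seq_len(n_resp)) {
      X[, j] <- X[, j] + 0.02 * meta$n_level
    }
    blocks <- make_blocks(X, meta, "variety")
    # component 2 of near-null data converges only slowly (power-method
    # rate ~ 1 for nearly degenerate singular values); only PC1 is asserted
    m <- suppressWarnings(mbhpca_fit(blocks, 2))
    load1 <- abs(m$avg_loadings[, 1])
    null_cut <- quantile(load1[-seq_len(n_resp)], 0.95)
    mean(load1[seq_len(n_resp)] > null_cut)
  }, 0)
  expect_gte(mean(hit_rates), 0.95)
})

test_that("spearman screen matches a rank-then-Pearson oracle", {
  dose <- rep(c(0, 50, 100, 150, 200), each = 3)
  up <- 2 * dose + 1     # strictly increasing in dose (ties aligned)
  down <- -up
  X <- rbind(up, down)
  rho <- spearman_screen(X, dose)
  expect_equal(unname(rho), c(1, -1))
  # monotone-transform invariance
  expect_equal(unname(spearman_screen(rbind(exp(up / 100)), dose)[1]), 1)
  set.seed(16)
  for (i in 1:20) {
    x <- sample(1:5, length(dose), replace = TRUE)  # plenty of ties
    mine <- unname(spearman_screen(matrix(x, 1), dose))
    oracle <- cor(rank(x), rank(dose))
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
  cc <- matrix(rep(1, length(dose)), 1)
  expect_true(is.na(spearman_screen(cc, dose)[1]))
})

test_that("friedman statistic matches closed-form rank arithmetic", {
  # identical treatment order in 4 blocks of 3 treatments: Fr = 8
  X <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), nrow = 1)
  fr <- friedman_screen(X, treatment = rep(1:3, 4), block = rep(1:4, each = 3))
  expect_equal(unname(fr$statistic), 8)
  expect_equal(unname(fr$df), 2)
  # all equal -> no evidence
  fr0 <- friedman_screen(matrix(1, 1, 12), rep(1:3, 4), rep(1:4, each = 3))
  expect_equal(unname(fr0$statistic), 0)
  expect_equal(unname(fr0$p_value), 1)
  # replicates are cell-averaged first
  Xr <- matrix(c(1, 3, 2, 2, 5, 5, 1, 1, 4, 4, 9, 9), nrow = 1)
  frr <- friedman_screen(Xr, treatment = rep(rep(1:3, each = 2), 2),
                         block = rep(1:2, each = 6))
  m <- rbind(c(2, 2, 5), c(1, 4, 9))
  expect_equal(unname(frr$statistic),
               unname(friedman.test(m)$statistic))
  expect_error(
    friedman_screen(matrix(1:6, 1), treatment = c(1, 2, 3, 1, 2, 2),
                    block = c(1, 1, 1, 2, 2, 2)),
    "incomplete"
  )
})

test_that("friedman statistic equals an independent rank-formula oracle", {
  # Conover's mid-rank form computed from first principles:
  # T = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (sum r_ij^2 - n k (k+1)^2 / 4)
  oracle_stat <- function(m) {
    n <- nrow(m)
    k <- ncol(m)
    r <- t(apply(m, 1, rank))
    Rj <- colSums(r)
    A <- sum(r^2)
    C <- n * k * (k + 1)^2 / 4
    (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  }
  set.seed(17)
  for (i in 1:50) {
    m <- matrix(sample(1:4, 9, replace = TRUE), 3, 3)
    if (any(apply(m, 1, function(x) length(unique(x))) == 1)) next
    mine <- friedman_screen(matrix(t(m), nrow = 1),
                            treatment = rep(1:3, 3),
                            block = rep(1:3, each = 3))$statistic
    expect_equal(unname(mine), oracle_stat(m), tolerance = 1e-10)
  }
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_false(any(bh_fdr(rep(1, 10))$reject))
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$reject))
  brute_q <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(m * p[o[i:m]] / rank(p)[o[i:m]]))
    }
    q
  }
  set.seed(18)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_fdr(p)$q_value, brute_q(p), tolerance = 1e-12)
  }
})

test_that("clustergram uses Spearman distance and clips the display", {
  base <- seq(1, 12)
  X <- rbind(f1 = base, f2 = base * 2, f3 = -base, f4 = rnorm(12))
  cg <- clustergram(X)
  # identical-rank features merge first at height 0
  expect_equal(cg$hclust$height[1], 0, tolerance = 1e-12)
  first_pair <- rownames(X)[-cg$hclust$merge[1, ]]
  expect_setequal(first_pair, c("f1", "f2"))
  # a feature and its negation sit at the maximum distance 2
  d <- as.matrix(1 - cor(t(X), method = "spearman"))
  expect_equal(d["f1", "f3"], 2)
  expect_true(all(cg$display >= -3 & cg$display <= 3))
  # dendrogram invariant under strictly monotone transforms
  Xm <- exp(X / 4)
  cg2 <- clustergram(Xm)
  expect_equal(cg$order, cg2$order)
  expect_equal(cg$hclust$merge, cg2$hclust$merge)
  expect_warning(clustergram(rbind(X, f5 = rep(1, 12))), "constant")
  expect_error(clustergram(X[1, , drop = FALSE]), ">= 2")
})

test_that("heatmap matrix log-transforms, standardises and clips", {
  X <- rbind(a = c(1, 10, 100, 1000), b = rep(5, 4))
  h <- heatmap_matrix(X)
  expect_true(all(h >= -3 & h <= 3))
  expect_equal(unname(h["b", ]), rep(0, 4))  # constant row maps to 0
  # an extreme outlier clips to exactly 3
  Xy <- matrix(10^c(rep(1, 20), 9), 1)
  hy <- heatmap_matrix(Xy)
  expect_equal(max(hy), 3)
  # zeros are imputed at half the minimal positive value
  Xz <- matrix(c(0, 2, 4, 8), 1)
  expect_equal(unname(heatmap_matrix(Xz)[1, 1]),
               unname(heatmap_matrix(matrix(c(1, 2, 4, 8), 1))[1, 1]))
  expect_error(heatmap_matrix(matrix(c(-1, 2), 1)), "negative")
})
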