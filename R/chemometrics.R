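#' Principal component analysis via singular value decomposition
#'
#' @param X numeric matrix, samples x features.
#' @param n_components number of components (<= min(dim)).
#' @param scaling `"center"` (mean-centre only), `"uv"` (unit variance;
#'   errors on constant features) or `"pareto"` (divide by sqrt of the
#'   standard deviation). Unit-variance scaling is the usual default for
#'   GC-MS profiles, Pareto for LC-MS.
#' @return list: `scores` (n x k), `loadings` (p x k, orthonormal columns),
#'   `explained` (fraction of total variance per component, non-increasing),
#'   `center`, `scale`, `scaling`. Component signs follow the convention
#'   that each component's largest-magnitude loading is positive.
#' @export
pca_fit <- function(X, n_components = 2,
                    scaling = c("center", "uv", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  ctr <- colMeans(X)
  Xs <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (scaling != "center") {
    s <- apply(X, 2, stats::sd)
    if (any(s == 0)) stop("constant feature under variance scaling")
    scl <- if (scaling == "uv") s else sqrt(s)
    Xs <- sweep(Xs, 2, scl, `/`)
  }
  sv <- svd(Xs, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v
  for (k in seq_len(n_components)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  list(scores = scores, loadings = loadings,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       center = ctr, scale = scl, scaling = scaling)
}

#' Split a sample x feature matrix into design blocks
#'
#' Prepares the block set for [mbhpca_fit()]: rows are split by the blocking
#' factor (varieties for the nitrogen-trend model, nitrogen levels for the
#' variety-difference model) and ordered identically within every block by
#' the remaining design columns, so that row i of each block corresponds to
#' the same (other-factor, replicate) cell.
#'
#' @param X samples x features matrix.
#' @param meta data.frame of sample metadata aligned with `rows(X)`.
#' @param blocking metadata column holding the blocking factor.
#' @param order_by metadata columns used to align rows within blocks.
#' @return named list of matrices with equal dimensions.
#' @export
make_blocks <- function(X, meta, blocking,
                        order_by = setdiff(c("variety", "n_level", "replicate"),
                                           blocking)) {
  stopifnot(nrow(X) == nrow(meta), blocking %in% names(meta))
  lv <- unique(meta[[blocking]])
  blocks <- lapply(lv, function(l) {
    rows <- which(meta[[blocking]] == l)
    sub <- meta[rows, , drop = FALSE]
    ord <- do.call(order, sub[, order_by, drop = FALSE])
    X[rows[ord], , drop = FALSE]
  })
  names(blocks) <- as.character(lv)
  sizes <- vapply(blocks, nrow, 0L)
  if (length(unique(sizes)) != 1) {
    stop("blocks are unbalanced; MB-HPCA requires equal block sizes")
  }
  blocks
}

#' Multiblock hierarchical (consensus) PCA
#'
#' Fits a consensus-PCA model across data blocks sharing a common feature
#' axis (e.g. one block per oat variety, rows aligned on nitrogen level x
#' replicate). Per component the iteration alternates between per-block
#' loadings/scores and a block-weighted consensus score until convergence,
#' then deflates each block by its own score/loading pair:
#' \preformatted{
#'   p_b = X_b' t / (t' t), normalised;  t_b = X_b p_b
#'   T = [t_1 ... t_B];  w = T' t / (t' t), normalised;  t <- T w
#' }
#' The block-weighted average loading (`avg_loadings`) is the surface used
#' for feature selection. With a single block the iteration is the NIPALS
#' power method and reproduces ordinary PCA.
#'
#' @param blocks named list of matrices (equal dimensions), see
#'   [make_blocks()].
#' @param n_components number of components.
#' @param block_scaling `"sqrt_nvar"` divides each centred block by the
#'   square root of its feature count (the package's convention so that no
#'   block dominates when feature counts differ); `"none"` skips it. As all
#'   blocks share one feature axis the choice only rescales scores.
#' @param tol relative convergence tolerance on the consensus score.
#' @param max_iter iteration cap per component; non-convergence is reported
#'   via the `converged` flags and a warning, and the partial model
#'   returned.
#' @return list of class `mbhpca`: `consensus_scores` (rows-per-block x k),
#'   `block_scores`, `block_loadings` (unit columns), `super_weights`
#'   (B x k), `avg_loadings`, `super_scores` (per original sample: its
#'   block score, stacked), `explained` (per block per component),
#'   `converged`, `block_scaling`.
#' @export
mbhpca_fit <- function(blocks, n_components = 2,
                       block_scaling = c("sqrt_nvar", "none"),
                       tol = 1e-10, max_iter = 500) {
  block_scaling <- match.arg(block_scaling)
  stopifnot(length(blocks) >= 1)
  B <- length(blocks)
  dims <- vapply(blocks, function(b) dim(as.matrix(b)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("all blocks must share identical dimensions")
  }
  n_b <- dims[1, 1]
  K <- dims[2, 1]
  if (n_b < 2) stop("each block needs >= 2 samples")
  Xb <- lapply(blocks, function(b) {
    m <- as.matrix(b)
    m <- sweep(m, 2, colMeans(m))
    if (block_scaling == "sqrt_nvar") m / sqrt(K) else m
  })
  ss0 <- vapply(Xb, function(m) sum(m^2), 0)

  k_max <- min(n_components, n_b - 1L, K)
  consensus <- matrix(0, n_b, k_max)
  super_w <- matrix(0, B, k_max, dimnames = list(names(blocks), NULL))
  p_list <- lapply(seq_len(B), function(b) matrix(0, K, k_max))
  t_list <- lapply(seq_len(B), function(b) matrix(0, n_b, k_max))
  expl <- matrix(0, B, k_max, dimnames = list(names(blocks), NULL))
  converged <- logical(k_max)

  for (comp in seq_len(k_max)) {
    Xbar <- Reduce(`+`, Xb) / B
    t_T <- svd(Xbar, nu = 1, nv = 0)$u[, 1] * sqrt(sum(Xbar^2))
    if (all(t_T == 0)) t_T <- stats::rnorm(n_b)
    w <- rep(1 / sqrt(B), B)
    for (it in seq_len(max_iter)) {
      P <- matrix(0, K, B)
      Tm <- matrix(0, n_b, B)
      for (b in seq_len(B)) {
        p <- crossprod(Xb[[b]], t_T) / sum(t_T^2)
        p <- p / sqrt(sum(p^2))
        P[, b] <- p
        Tm[, b] <- Xb[[b]] %*% p
      }
      w <- crossprod(Tm, t_T) / sum(t_T^2)
      w <- as.vector(w / sqrt(sum(w^2)))
      t_new <- Tm %*% w
      delta <- sqrt(sum((t_new - t_T)^2)) / sqrt(sum(t_new^2))
      t_T <- as.vector(t_new)
      if (delta < tol) {
        converged[comp] <- TRUE
        break
      }
    }
    if (!converged[comp]) {
      warning(sprintf("component %d did not converge in %d iterations",
                      comp, max_iter))
    }
    ## sign convention: largest-magnitude average loading positive
    p_avg <- as.vector(P %*% w)
    if (p_avg[which.max(abs(p_avg))] < 0) {
      P <- -P
      Tm <- -Tm
      t_T <- -t_T
    }
    consensus[, comp] <- t_T
    super_w[, comp] <- w
    for (b in seq_len(B)) {
      p_list[[b]][, comp] <- P[, b]
      t_list[[b]][, comp] <- Tm[, b]
      expl[b, comp] <- sum((Tm[, b] %o% P[, b])^2) / ss0[b]
      Xb[[b]] <- Xb[[b]] - Tm[, b] %o% P[, b]
    }
  }

  avg_loadings <- matrix(0, K, k_max)
  for (comp in seq_len(k_max)) {
    pav <- Reduce(`+`, lapply(seq_len(B), function(b) {
      super_w[b, comp] * p_list[[b]][, comp]
    }))
    avg_loadings[, comp] <- pav
  }
  rownames(avg_loadings) <- colnames(as.matrix(blocks[[1]]))

  super_scores <- do.call(rbind, lapply(seq_len(B), function(b) {
    sc <- t_list[[b]]
    rownames(sc) <- rownames(as.matrix(blocks[[b]]))
    sc
  }))
  names(p_list) <- names(blocks)
  names(t_list) <- names(blocks)
  structure(
    list(consensus_scores = consensus, block_scores = t_list,
         block_loadings = p_list, super_weights = super_w,
         avg_loadings = avg_loadings, super_scores = super_scores,
         explained = expl, converged = converged,
         block_scaling = block_scaling),
    class = "mbhpca"
  )
}

#' Spearman correlation of every feature with applied nitrogen
#'
#' Mid-rank tied Spearman rho per feature; invariant under strictly
#' monotone transforms of the intensities. Constant features have undefined
#' rho and are reported as `NA`.
#'
#' @param X features x samples matrix.
#' @param dose applied N (kg/ha) per sample; >= 2 distinct values.
#' @return named numeric vector of rho values.
#' @export
spearman_screen <- function(X, dose) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(dose))
  if (ncol(X) < 4) stop("need at least 4 samples")
  if (length(unique(dose)) < 2) stop("dose needs >= 2 distinct values")
  rho <- suppressWarnings(
    apply(X, 1, function(x) stats::cor(x, dose, method = "spearman"))
  )
  rho[apply(X, 1, function(x) stats::sd(x) == 0)] <- NA
  rho
}

#' Friedman tests per feature for a blocked two-way layout
#'
#' Non-parametric two-way screening: replicates within each
#' (block x treatment) cell are averaged first, then the Friedman rank
#' statistic (with mid-rank tie correction) is computed within blocks and
#' referred to the chi-square distribution with k - 1 degrees of freedom.
#' For the nitrogen effect, blocks are the varieties and treatments the N
#' levels; for the variety effect the roles are swapped.
#'
#' @param X features x samples matrix.
#' @param treatment,block factors of length `ncol(X)`; the design must be
#'   complete after cell averaging.
#' @return data.frame: `feature`, `statistic`, `df`, `p_value`.
#' @export
friedman_screen <- function(X, treatment, block) {
  X <- as.matrix(X)
  treatment <- factor(treatment)
  block <- factor(block)
  stopifnot(ncol(X) == length(treatment), ncol(X) == length(block))
  if (any(table(block, treatment) == 0)) {
    stop("incomplete block x treatment design after aggregation")
  }
  res <- t(apply(X, 1, function(x) {
    m <- tapply(x, list(block, treatment), mean)
    ft <- stats::friedman.test(m)
    ## fully tied layout (all cell means equal): 0/0 in the tie-corrected
    ## statistic; by convention no evidence of any effect
    if (!is.finite(ft$statistic)) {
      c(0, ft$parameter, 1)
    } else {
      c(ft$statistic, ft$parameter, ft$p.value)
    }
  }))
  data.frame(
    feature = rownames(X) %||% seq_len(nrow(X)),
    statistic = res[, 1], df = res[, 2], p_value = res[, 3],
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up q-values (`q_i = min over j >= i of m * p_(j) / j`, capped at 1)
#' and rejection flags at the chosen FDR level.
#'
#' @param pvalues numeric vector in \[0, 1\] (`NA` allowed, never rejected).
#' @param q FDR level (default 0.05).
#' @return data.frame: `p_value`, `q_value`, `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  qv <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p_value = pvalues, q_value = qv,
             reject = !is.na(qv) & qv <= q)
}

#' Spearman-distance clustergram of selected features
#'
#' Hierarchical clustering of features with distance `1 - rho` (Spearman)
#' and the chosen agglomeration, plus the display matrix: per-feature
#' standardised values clipped to \[-3, +3\]. Constant features (undefined
#' rho) are dropped with a warning. Because ranks drive both the distances
#' and the leaf order, the dendrogram is invariant to strictly monotone
#' transforms of the data.
#'
#' @param X features x samples matrix (>= 2 features).
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list: `hclust`, `order` (leaf order, feature names), `display`
#'   (clipped matrix in leaf order), `metric`, `linkage`.
#' @export
clustergram <- function(X, linkage = "average") {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 selected features")
  const <- apply(X, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped (undefined rho)")
    X <- X[!const, , drop = FALSE]
    if (nrow(X) < 2) stop("fewer than 2 non-constant features remain")
  }
  rho <- stats::cor(t(X), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = linkage)
  z <- t(scale(t(X)))
  z[z > 3] <- 3
  z[z < -3] <- -3
  list(hclust = hc, order = rownames(X)[hc$order],
       display = z[hc$order, , drop = FALSE],
       metric = "1 - spearman rho", linkage = linkage)
}

#' Log10 heatmap matrix of normalised intensities
#'
#' log10-transforms positive normalised intensities (zeros imputed with half
#' the smallest positive value in the matrix), standardises per feature
#' (constant rows map to 0), and clips to \[-3, +3\].
#'
#' @param X features x samples matrix of non-negative intensities.
#' @return clipped matrix of the same dimensions.
#' @export
heatmap_matrix <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("negative intensities")
  if (any(X == 0)) {
    pos <- X[X > 0]
    if (!length(pos)) stop("all-zero matrix")
    X[X == 0] <- min(pos) / 2
  }
  L <- log10(X)
  s <- apply(L, 1, stats::sd)
  m <- rowMeans(L)
  z <- (L - m) / ifelse(s == 0, 1, s)
  z[z > 3] <- 3
  z[z < -3] <- -3
  z
}
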