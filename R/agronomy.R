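#' Lodging index
#'
#' Composite 0-100 lodging score: percent plot area lodged (more than 45
#' degrees from vertical) plus half the percent area leaning (10-45
#' degrees).
#'
#' @param pct_lodged,pct_leaning percentages of plot area in \[0, 100\];
#'   their sum must not exceed 100. Vectorised.
#' @return index = lodged + leaning / 2, in \[0, 100\].
#' @export
lodging_index <- function(pct_lodged, pct_leaning) {
  if (any(pct_lodged < 0 | pct_lodged > 100) ||
      any(pct_leaning < 0 | pct_leaning > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  if (any(pct_lodged + pct_leaning > 100)) {
    stop("lodged + leaning cannot exceed 100% of plot area")
  }
  pct_lodged + pct_leaning / 2
}

#' Yield components from grain yield and thousand grain weight
#'
#' Grain number per square metre is derived from grain yield (t/ha at the
#' stated moisture) converted to grams of dry matter per square metre and
#' divided by the single-grain weight:
#' `grains_m2 = yield * 100 * dm_fraction / tgw * 1000`.
#' Grain number per panicle is `grains_m2 / panicles_m2`.
#'
#' @param yield_t_ha grain yield, t/ha.
#' @param tgw thousand grain weight, g (> 0).
#' @param panicles_m2 panicle count per square metre (> 0 when grains per
#'   panicle is wanted; `NA` allowed otherwise).
#' @param dm_fraction dry-matter fraction applied to yield (default 0.85,
#'   matching yield reported at 15% moisture content). The moisture basis
#'   of TGW (as-is vs dry) affects the result by a constant factor; the
#'   conversion used here is recorded in the return value.
#' @return data.frame: `grains_m2`, `grains_per_panicle`, `dm_fraction`.
#' @export
yield_components <- function(yield_t_ha, tgw, panicles_m2 = NA,
                             dm_fraction = 0.85) {
  if (any(tgw <= 0)) stop("tgw must be > 0")
  if (any(!is.na(panicles_m2) & panicles_m2 <= 0)) {
    stop("panicles_m2 must be > 0")
  }
  grains_m2 <- yield_t_ha * 100 * dm_fraction / tgw * 1000
  data.frame(grains_m2 = grains_m2,
             grains_per_panicle = grains_m2 / panicles_m2,
             dm_fraction = dm_fraction)
}

#' Fit the linear-plus-exponential nitrogen dose-response model
#'
#' Least-squares fit of `y(N) = a + b * r^N + c * N` with `r` constrained to
#' (0, 1). For fixed `r` the model is linear in (a, b, c), so the fit
#' profiles the residual sum of squares over a grid of `r` values and then
#' refines the best region by golden-section search; this is globally robust
#' and exact on noiseless data.
#'
#' @param doses applied N, kg N/ha; >= 4 distinct values including a low or
#'   zero control.
#' @param yields grain yields, t/ha, same length.
#' @return object of class `linexp_fit`: `a`, `b`, `r`, `c`, `residual_sd`,
#'   `fitted`, `n`.
#' @export
fit_linexp <- function(doses, yields) {
  stopifnot(length(doses) == length(yields))
  if (length(unique(doses)) < 4) {
    stop("need >= 4 distinct doses to identify 4 parameters")
  }
  sse_for <- function(r) {
    Xd <- cbind(1, r^doses, doses)
    fit <- stats::lm.fit(Xd, yields)
    sum(fit$residuals^2)
  }
  grid <- c(seq(0.05, 0.95, by = 0.05), seq(0.955, 0.9995, by = 0.0015))
  sse <- vapply(grid, sse_for, 0)
  i <- which.min(sse)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse_for, c(lo, hi), tol = 1e-10)
  r <- opt$minimum
  Xd <- cbind(1, r^doses, doses)
  fit <- stats::lm.fit(Xd, yields)
  coefs <- fit$coefficients
  ## polish the profiled solution with a full 4-parameter least-squares step
  polished <- tryCatch({
    nl <- suppressWarnings(stats::nls(
      y ~ a + b * r^N + c * N,
      data = data.frame(y = yields, N = doses),
      start = list(a = coefs[1], b = coefs[2], r = r, c = coefs[3]),
      algorithm = "port", lower = c(-Inf, -Inf, 1e-9, -Inf),
      upper = c(Inf, Inf, 1 - 1e-9, Inf),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
    ))
    cf <- stats::coef(nl)
    if (sum(stats::residuals(nl)^2) <= sum(fit$residuals^2)) cf else NULL
  }, error = function(e) NULL)
  if (!is.null(polished)) {
    r <- unname(polished["r"])
    Xd <- cbind(1, r^doses, doses)
    fit <- stats::lm.fit(Xd, yields)
    coefs <- fit$coefficients
  }
  dof <- length(yields) - 4
  structure(
    list(a = unname(coefs[1]), b = unname(coefs[2]), r = r,
         c = unname(coefs[3]),
         residual_sd = sqrt(sum(fit$residuals^2) / max(1, dof)),
         fitted = as.vector(Xd %*% coefs), n = length(yields)),
    class = "linexp_fit"
  )
}

#' @export
print.linexp_fit <- function(x, ...) {
  cat(sprintf(
    "linear-plus-exponential fit: y = %.4g + %.4g * %.6g^N + %.4g * N\n",
    x$a, x$b, x$r, x$c
  ))
  cat(sprintf("  residual sd %.4g t/ha on %d observations\n",
              x$residual_sd, x$n))
  invisible(x)
}

#' Economically optimal nitrogen rate
#'
#' Solves the marginal-yield condition `y'(N) = b ln(r) r^N + c = k'`, where
#' `k'` is the breakeven price ratio (kg grain per kg N, default 5:1)
#' expressed in t/ha per kg N/ha (`k / 1000`). The closed form is
#' `N = ln((k' - c) / (b ln r)) / ln(r)` when the argument is positive.
#' When the marginal yield never falls to the breakeven within
#' `[0, n_max]` — e.g. yields still rising at the highest dose tested — the
#' optimum is undefined and returned as `NA` with a reason.
#'
#' @param fit a `linexp_fit` (or any list with `b`, `r`, `c`).
#' @param k breakeven price ratio, kg grain per kg N (default 5).
#' @param n_max upper bound of the economically meaningful dose range,
#'   kg N/ha.
#' @return list: `n_opt` (kg N/ha or `NA`), `reason` (`NA` when defined).
#' @export
economic_optimum <- function(fit, k = 5, n_max = 400) {
  b <- fit$b
  r <- fit$r
  cc <- fit$c
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  kp <- k / 1000  # t/ha per kg N/ha
  arg <- (kp - cc) / (b * log(r))
  if (!is.finite(arg) || arg <= 0) {
    return(list(n_opt = NA_real_,
                reason = "marginal yield never reaches the breakeven ratio"))
  }
  n_opt <- log(arg) / log(r)
  if (n_opt < 0) {
    return(list(n_opt = NA_real_,
                reason = "marginal yield below breakeven at zero N"))
  }
  if (n_opt > n_max) {
    return(list(n_opt = NA_real_,
                reason = "yield still increasing at the top of the dose range"))
  }
  list(n_opt = n_opt, reason = NA_character_)
}

#' Split-plot analysis of variance
#'
#' Classical split-plot decomposition for one trial: blocks; nitrogen on
#' main plots, tested against the block x nitrogen error stratum; variety
#' and the nitrogen x variety interaction on sub-plots, tested against the
#' residual. Requires a balanced complete design (no imputation is
#' attempted).
#'
#' @param plots data.frame of plot records with columns `block`, `variety`,
#'   `applied_n` and the response; a single trial.
#' @param response name of the response column.
#' @return data.frame ANOVA table: `source`, `df`, `ss`, `ms`, `f`, `p`.
#' @export
splitplot_anova <- function(plots, response) {
  stopifnot(response %in% names(plots))
  if ("trial" %in% names(plots) && length(unique(plots$trial)) > 1) {
    stop("splitplot_anova analyses one trial at a time")
  }
  d <- data.frame(
    y = plots[[response]],
    block = factor(plots$block),
    nitrogen = factor(plots$applied_n),
    variety = factor(plots$variety)
  )
  counts <- table(d$block, d$nitrogen, d$variety)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unbalanced design: every block x nitrogen x variety cell must have equal counts")
  }
  fit <- stats::aov(y ~ nitrogen * variety + Error(block / nitrogen), data = d)
  sm <- summary(fit)
  grab <- function(stratum) as.data.frame(sm[[stratum]][[1]])
  s1 <- grab("Error: block")
  s2 <- grab("Error: block:nitrogen")
  s3 <- grab("Error: Within")
  row <- function(source, tab, i) {
    data.frame(source = source, df = tab$Df[i], ss = tab$`Sum Sq`[i],
               ms = tab$`Mean Sq`[i],
               f = if ("F value" %in% names(tab)) tab$`F value`[i] else NA,
               p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)`[i] else NA)
  }
  out <- rbind(
    row("blocks", s1, 1),
    row("nitrogen", s2, 1),
    row("main_plot_error", s2, 2),
    row("variety", s3, 1),
    row("nitrogen_x_variety", s3, 2),
    row("sub_plot_error", s3, 3)
  )
  rownames(out) <- NULL
  out
}

#' Fisher's protected LSD compact letter display
#'
#' Computes the least significant difference
#' `LSD = t(1 - alpha/2, df) * sqrt(2 * ms_error / n)` and assigns letters
#' to means sorted ascending (so the smallest mean carries "a"): maximal
#' runs of means whose range does not exceed the LSD share a letter. The
#' test is protected: letters are only differentiated when the omnibus
#' p-value is at most `alpha`; otherwise all means share "a".
#'
#' @param means named numeric vector of level means.
#' @param ms_error error mean square from the appropriate ANOVA stratum.
#' @param df_error its degrees of freedom (> 0).
#' @param n_per_mean replications per mean (> 1).
#' @param alpha significance level.
#' @param omnibus_p p-value of the omnibus F test for the factor.
#' @return data.frame: `level`, `mean`, `letters`, plus attribute `lsd`.
#' @export
fisher_lsd_letters <- function(means, ms_error, df_error, n_per_mean,
                               alpha = 0.05, omnibus_p) {
  if (df_error <= 0) stop("df_error must be > 0")
  if (n_per_mean <= 1) stop("n_per_mean must be > 1")
  lev <- names(means) %||% as.character(seq_along(means))
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
  out <- data.frame(level = lev, mean = as.numeric(means),
                    stringsAsFactors = FALSE)
  if (omnibus_p > alpha) {
    out$letters <- "a"
    attr(out, "lsd") <- lsd
    return(out)
  }
  ord <- order(out$mean)
  m <- out$mean[ord]
  nm <- length(m)
  ## maximal runs [i, j] with m_j - m_i <= LSD; ends are monotone
  ## non-decreasing in i, so a run is maximal iff its end exceeds the
  ## previous run's end
  ends <- vapply(seq_len(nm), function(i) max(which(m - m[i] <= lsd)), 0L)
  starts <- which(c(TRUE, diff(ends) > 0))
  letters_sorted <- character(nm)
  for (g in seq_along(starts)) {
    span <- starts[g]:ends[starts[g]]
    letters_sorted[span] <- paste0(letters_sorted[span], letters[g])
  }
  out$letters <- ""
  out$letters[ord] <- letters_sorted
  attr(out, "lsd") <- lsd
  out
}

#' Pearson correlation between two plot-level traits
#'
#' @param plots data.frame of plot records (or any table of traits).
#' @param trait_x,trait_y column names; >= 3 pairwise-complete pairs
#'   required.
#' @return Pearson correlation coefficient.
#' @export
trait_correlations <- function(plots, trait_x, trait_y) {
  x <- plots[[trait_x]]
  y <- plots[[trait_y]]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) stop("constant trait")
  stats::cor(x[ok], y[ok])
}

#' Bundled field-trial nitrogen-response means
#'
#' Published mean values by variety and by nitrogen application level for
#' grain yield (t/ha at 15% moisture), lodging index, thousand grain weight
#' (g), grain number per m2, panicles per m2 and grain number per panicle,
#' from three UK winter oat nitrogen-response trials (two sites, harvests
#' 2014 and 2015; 4 varieties; 5-6 applied-N levels; 3 replicates). Applied
#' N doses are given for the nitrogen-level rows.
#'
#' @return data.frame with columns `group_type` (`"variety"` or
#'   `"nitrogen"`), `level`, `trial`, `applied_n`, `grain_yield_t_ha`,
#'   `lodging_index`, `tgw_g`, `grains_m2`, `panicles_m2`,
#'   `grains_per_panicle`.
#' @export
field_trial_means <- function() {
  path <- system.file("extdata", "field_trial_means.csv", package = "groatlab")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
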