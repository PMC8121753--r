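test_that("lodging index follows the composite formula and is monotone", {
  expect_equal(lodging_index(0, 0), 0)
  expect_equal(lodging_index(100, 0), 100)
  expect_equal(lodging_index(10, 20), 20)
  grid <- expand.grid(l = c(0, 10, 40), n = c(0, 10, 40))
  idx <- lodging_index(grid$l, grid$n)
  expect_true(all(diff(idx[order(grid$l)]) >= 0 |
                    diff(grid$n[order(grid$l)]) < 0))
  expect_error(lodging_index(-1, 0), "\\[0, 100\\]")
  expect_error(lodging_index(80, 30), "exceed")
})

test_that("yield components reproduce the published plot-level mean", {
  # variety mean: yield 8.86 t/ha at TGW 43.76 g -> about 17,200 grains/m2,
  # within 1% of the printed 17,129 (printed value is a mean of ratios)
  yc <- yield_components(8.86, 43.76, panicles_m2 = 300.2)
  expect_lt(abs(yc$grains_m2 - 17129) / 17129, 0.01)
  expect_equal(yield_components(0, 40)$grains_m2, 0)
  # algebraic identity
  expect_equal(yc$grains_per_panicle * 300.2, yc$grains_m2)
  expect_error(yield_components(5, 0), "tgw")
  expect_error(yield_components(5, 40, 0), "panicles")
})

test_that("lin+exp fit is exact on noiseless data and location-equivariant", {
  doses <- c(0, 50, 100, 150, 200, 250)
  y <- 11 - 6 * 0.99^doses - 0.003 * doses
  f <- fit_linexp(doses, y)
  expect_equal(f$a, 11, tolerance = 1e-4)
  expect_equal(f$b, -6, tolerance = 1e-4)
  expect_equal(f$r, 0.99, tolerance = 1e-6)
  expect_equal(f$c, -0.003, tolerance = 1e-4)
  expect_lt(f$residual_sd, 1e-8)
  f2 <- fit_linexp(doses, y + 1)
  expect_equal(f2$a, f$a + 1, tolerance = 1e-6)
  expect_equal(f2$b, f$b, tolerance = 1e-6)
  expect_equal(f2$r, f$r, tolerance = 1e-6)
  expect_equal(f2$c, f$c, tolerance = 1e-8)
  expect_error(fit_linexp(c(0, 50, 100), c(1, 2, 3)), "4 distinct")
})

test_that("economic optimum: closed form, undefined cases, grid oracle", {
  fit <- list(a = 11, b = -6, r = 0.99, c = -0.003)
  opt <- economic_optimum(fit, k = 5)
  expect_equal(opt$n_opt, 200.98, tolerance = 0.01)
  # y'(Nopt) equals the breakeven slope in t/ha per kg N
  slope <- fit$b * log(fit$r) * fit$r^opt$n_opt + fit$c
  expect_equal(slope, 0.005, tolerance = 1e-10)
  # linear slope at or above breakeven: marginal yield never falls to it
  expect_true(is.na(economic_optimum(list(a = 11, b = -6, r = 0.99,
                                          c = 0.006))$n_opt))
  # still rising at the top of the dose range
  expect_match(economic_optimum(fit, k = 5, n_max = 100)$reason, "increasing")
  expect_error(economic_optimum(list(a = 1, b = -1, r = 1.5, c = 0)), "0, 1")
  # closed form vs 0.01-step grid search over the profit function
  set.seed(19)
  for (i in 1:20) {
    pars <- list(a = runif(1, 5, 12), b = -runif(1, 2, 8),
                 r = runif(1, 0.97, 0.995), c = -runif(1, 0.001, 0.004))
    o <- economic_optimum(pars, k = 5)
    Ns <- seq(0, 400, by = 0.01)
    profit <- pars$a + pars$b * pars$r^Ns + pars$c * Ns - 0.005 * Ns
    grid_opt <- Ns[which.max(profit)]
    if (!is.na(o$n_opt)) {
      expect_lt(abs(o$n_opt - grid_opt), 0.1)
    } else {
      expect_true(grid_opt %in% c(0, 400))
    }
  }
})

test_that("split-plot ANOVA decomposes sums of squares and finds effects", {
  d <- single_trial_design()
  pl <- generate_agronomy_trials(d, seed = 23)
  sub <- pl[pl$trial == "AD15", ]
  a <- splitplot_anova(sub, "yield_t_ha")
  expect_equal(sum(a$ss), sum((sub$yield_t_ha - mean(sub$yield_t_ha))^2),
               tolerance = 1e-8)
  expect_equal(sum(a$df), nrow(sub) - 1)
  expect_lt(a$p[a$source == "nitrogen"], 1e-6)  # strong built-in N response
  # pure variety shift: variety highly significant, nitrogen not
  set.seed(24)
  sub$flat <- rnorm(nrow(sub), 0, 0.1) +
    c(V1 = 0, Balado = 0, Gerald = 3, Mascani = 6, Tardis = 9)[sub$variety]
  av <- splitplot_anova(sub, "flat")
  expect_lt(av$p[av$source == "variety"], 1e-6)
  expect_gt(av$p[av$source == "nitrogen"], 0.001)
  expect_error(splitplot_anova(sub[-1, ], "yield_t_ha"), "unbalanced")
  multi <- generate_agronomy_trials(study_design(), seed = 2)
  expect_error(splitplot_anova(multi, "yield_t_ha"), "one trial")
})

test_that("split-plot null p-values are uniform", {
  set.seed(25)
  d <- single_trial_design()
  template <- generate_agronomy_trials(d, seed = 1)
  template <- template[template$trial == "AD15", ]
  pn <- replicate(300, {
    template$null_y <- rnorm(nrow(template))
    a <- splitplot_anova(template, "null_y")
    a$p[a$source == "nitrogen"]
  })
  expect_gt(ks.test(pn, "punif")$p.value, 0.01)
})

test_that("protected LSD letters match all-pairs comparisons", {
  # identical means share one letter
  same <- fisher_lsd_letters(c(x = 5, y = 5, z = 5), 0.5, 12, 3,
                             omnibus_p = 0.001)
  expect_equal(same$letters, rep("a", 3))
  # widely separated means get distinct letters
  lsd <- qt(0.975, 12) * sqrt(2 * 0.5 / 3)
  far <- fisher_lsd_letters(c(x = 0, y = 10 * lsd), 0.5, 12, 3,
                            omnibus_p = 0.001)
  expect_equal(far$letters, c("a", "b"))
  # unprotected when the omnibus test is not significant
  prot <- fisher_lsd_letters(c(x = 0, y = 10 * lsd), 0.5, 12, 3,
                             omnibus_p = 0.2)
  expect_equal(prot$letters, c("a", "a"))
  # brute-force oracle: two means share a letter iff |diff| <= LSD
  set.seed(26)
  for (i in 1:30) {
    nm <- sample(3:6, 1)
    means <- round(runif(nm, 0, 4), 2)
    names(means) <- paste0("m", seq_len(nm))
    res <- fisher_lsd_letters(means, ms_error = 1, df_error = 10,
                              n_per_mean = 3, omnibus_p = 0.001)
    lsd_i <- attr(res, "lsd")
    for (p in seq_len(nm - 1)) {
      for (q in (p + 1):nm) {
        share <- length(intersect(strsplit(res$letters[p], "")[[1]],
                                  strsplit(res$letters[q], "")[[1]])) > 0
        expect_equal(share, abs(means[[p]] - means[[q]]) <= lsd_i)
      }
    }
  }
  expect_error(fisher_lsd_letters(c(1, 2), 1, 0, 3, omnibus_p = 0.01), "df")
})

test_that("trait correlations use pairwise-complete Pearson", {
  tab <- field_trial_means()
  nitro <- tab[tab$group_type == "nitrogen", ]
  expect_equal(nrow(nitro), 17)
  expect_equal(trait_correlations(nitro, "grains_m2", "grains_m2"), 1)
  anti <- data.frame(x = 1:5, y = -(1:5))
  expect_equal(trait_correlations(anti, "x", "y"), -1)
  expect_error(trait_correlations(anti[1:2, ], "x", "y"), "3 paired")
  anti$z <- 1
  expect_error(trait_correlations(anti, "x", "z"), "constant")
})
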