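make_pair_table <- function(mz, rt, intens, polarity = "ESI-") {
  n <- length(mz)
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        role = rep("experimental", 6))
  feature_table(
    data.frame(feature_id = paste0("F", seq_len(n)), mz = mz, rt = rt),
    samples, intens, polarity = polarity
  )
}

test_that("correlation grouping partitions features by rt and correlation", {
  base <- c(10, 20, 30, 40, 50, 60)
  # identical intensity profiles at one rt -> one group
  tab <- make_pair_table(c(300, 336), c(5, 5), rbind(base, base * 0.5))
  g <- group_by_correlation(tab)
  expect_length(g, 1)
  expect_setequal(g[[1]]$feature_ids, c("F1", "F2"))
  # perfectly correlated but 5 min apart -> separate groups
  tab2 <- make_pair_table(c(300, 336), c(5, 10), rbind(base, base * 0.5))
  expect_length(group_by_correlation(tab2, rt_tol = 0.1), 2)
  # partition property and invariance to sample column order
  sim <- generate_lcms_dataset(single_trial_design(),
                               example_compounds(8, seed = 3), seed = 4)
  tabs <- drop_sample_role(remove_blank_features(
    exclude_rt_window(sim$table)), "blank")
  g1 <- group_by_correlation(tabs)
  expect_setequal(unlist(lapply(g1, `[[`, "feature_ids")),
                  tabs$features$feature_id)
  expect_equal(sum(lengths(lapply(g1, `[[`, "feature_ids"))),
               nrow(tabs$features))
  perm <- sample(ncol(tabs$intensities))
  tabp <- tabs
  tabp$samples <- tabs$samples[perm, ]
  tabp$intensities <- tabs$intensities[, perm]
  g2 <- group_by_correlation(tabp)
  expect_equal(lapply(g1, `[[`, "feature_ids"), lapply(g2, `[[`, "feature_ids"))
  few <- tabs
  few$samples <- few$samples[1:3, ]
  few$intensities <- few$intensities[, 1:3]
  expect_error(group_by_correlation(few), "at least 4")
})

test_that("neutral mass arithmetic round-trips through every adduct", {
  for (pol in c("ESI+", "ESI-")) {
    adducts <- default_adducts(pol)
    for (a in adducts$name) {
      M <- 299.0794
      expect_equal(neutral_mass(mz_for_adduct(M, a, adducts), a, adducts), M)
    }
  }
  # protonated / deprotonated forms of one neutral mass
  expect_equal(neutral_mass(300.0867, "[M+H]"), 299.0794, tolerance = 1e-6)
  expect_equal(neutral_mass(298.0721, "[M-H]"), 299.0794, tolerance = 1e-6)
  expect_error(neutral_mass(300, "[M+Xe]"), "unknown adduct")
})

test_that("chloride-adduct pair resolves to one avenanthramide-like parent", {
  # deprotonated molecule and its chloride adduct: delta 35.9767 = Cl - H
  M <- 299.0794  # C16H13NO5
  adducts <- default_adducts("ESI-")
  mzs <- c(mz_for_adduct(M, "[M-H]", adducts), mz_for_adduct(M, "[M+Cl]", adducts))
  expect_equal(diff(mzs), 35.97668, tolerance = 1e-4)
  base <- c(10, 20, 30, 40, 50, 60)
  tab <- make_pair_table(mzs, c(8.0, 8.0), rbind(base, base * 0.4))
  g <- group_by_correlation(tab)
  ann <- annotate_adducts_isotopes(g[[1]], tab)
  expect_equal(ann$role[ann$feature_id == "F1"], "parent")
  expect_equal(ann$role[ann$feature_id == "F2"], "adduct:[M+Cl]")
  expect_equal(ann$neutral_mass[1], M, tolerance = 1e-5)
  expect_lt(max(abs(ann$ppm_error)), 5)
})

test_that("isotope spacing assigns +1 to the lighter-intensity heavier peak", {
  base <- c(10, 20, 30, 40, 50, 60)
  mz1 <- 298.0721
  tab <- make_pair_table(c(mz1, mz1 + 1.00336), c(6, 6),
                         rbind(base, base * 0.2))
  ann <- annotate_adducts_isotopes(group_by_correlation(tab)[[1]], tab)
  expect_equal(ann$role, c("parent", "isotope+1"))
  # singleton group: parent by default with no pairwise evidence
  single <- make_pair_table(400.1, 3, matrix(base, 1))
  anns <- annotate_adducts_isotopes(group_by_correlation(single)[[1]], single)
  expect_equal(anns$role, "parent")
  expect_error(
    annotate_adducts_isotopes(group_by_correlation(single)[[1]], single,
                              adducts = default_adducts("ESI-")[0, ]),
    "empty adduct"
  )
})

test_that("ppm library matching has an inclusive boundary and sorted output", {
  lib <- data.frame(name = c("cmpA", "cmpB"),
                    monoisotopic_mass = c(299.0794, 500))
  exact <- ppm_match_library(299.0794, lib)
  expect_equal(exact$name[1], "cmpA")
  expect_equal(exact$ppm_error[1], 0)
  at5 <- ppm_match_library(299.0794 * (1 + 5e-6), lib)
  expect_equal(nrow(at5), 1)
  expect_equal(at5$ppm_error, 5, tolerance = 1e-9)
  expect_equal(nrow(ppm_match_library(299.0794 * (1 + 6e-6), lib)), 0)
})

test_that("ppm matching agrees with a brute-force linear scan", {
  set.seed(31)
  lib <- data.frame(name = sprintf("e%04d", 1:1000),
                    monoisotopic_mass = sort(runif(1000, 100, 900)))
  for (q in runif(25, 100, 900)) {
    fast <- ppm_match_library(q, lib, tol_ppm = 50)
    slow <- lib$name[vapply(seq_len(nrow(lib)), function(i) {
      abs(1e6 * (q - lib$monoisotopic_mass[i]) / lib$monoisotopic_mass[i]) <= 50
    }, TRUE)]
    expect_setequal(fast$name, slow)
  }
})

test_that("collapse keeps the most intense member per group", {
  base <- c(10, 20, 30, 40, 50, 60)
  tab <- make_pair_table(c(300, 322, 338), c(4, 4, 4),
                         rbind(base, base * 10, base * 5))
  g <- group_by_correlation(tab)
  ann <- annotate_groups(g, tab)
  col <- collapse_to_representative(g, ann, tab)
  expect_equal(nrow(col$intensities), 1)
  expect_equal(col$features$feature_id, "F2")
  expect_equal(col$features$n_members, 3)
  # all singletons -> row count unchanged
  tab2 <- make_pair_table(c(300, 500), c(4, 20), rbind(base, rev(base)))
  g2 <- group_by_correlation(tab2)
  col2 <- collapse_to_representative(g2, annotate_groups(g2, tab2), tab2)
  expect_equal(nrow(col2$intensities), 2)
})

test_that("noiseless synthetic annotation recovers all roles exactly", {
  cmp <- example_compounds(15, seed = 11, technical_cv = 0, biological_cv = 0)
  sim <- generate_lcms_dataset(single_trial_design(), cmp, seed = 12)
  tab <- drop_sample_role(remove_blank_features(
    exclude_rt_window(sim$table)), "blank")
  g <- group_by_correlation(tab)
  expect_length(g, 15)
  ann <- annotate_groups(g, tab)
  m <- merge(ann, sim$truth$feature_to_compound, by = "feature_id")
  expect_equal(m$role.x, m$role.y)
  # every annotated neutral mass matches its compound truth
  masses <- vapply(sim$truth$compounds, `[[`, 0, "neutral_mass")
  names(masses) <- vapply(sim$truth$compounds, `[[`, "", "name")
  ok <- !is.na(m$neutral_mass)
  expect_equal(m$neutral_mass[ok], unname(masses[m$compound[ok]]),
               tolerance = 1e-6)
  col <- collapse_to_representative(g, ann, tab)
  expect_equal(nrow(col$intensities), 15)
})
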