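#' Pipeline configuration
#'
#' Collects all tunable parameters of the metabolomics and agronomy
#' pipelines with the defaults used throughout the package: 36-40 min
#' retention exclusion, 3-fold blank threshold, 25% QA RSD, 5 ppm mass
#' tolerance, 0.05 min / 0.8 grouping tolerances, Pareto scaling with
#' variety blocking, 5% FDR, 0.85 dry-matter fraction and a 5:1 breakeven
#' ratio.
#'
#' @param seed RNG seed recorded in every output header.
#' @param out_dir output directory for pipeline runs.
#' @param ... overrides for any default listed above (see the function
#'   body / vignette for the key names).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("groatlab_run_"), ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    rt_exclusion_window = c(36, 40),
    blank_fold = 3,
    rsd_threshold = 25,
    normalisation = "tic",
    is_feature_id = NULL,
    rt_tol = 0.05, r_min = 0.8, mz_tol_ppm = 5,
    scaling = "pareto", blocking = "variety", n_components = 2,
    fdr_q = 0.05,
    dm_fraction = 0.85, breakeven_k = 5,
    ## synthetic demo inputs (used when no CSV paths are supplied); the
    ## metabolomics demo uses a single trial so the blocked model applies
    design = study_design(trials = "AD15",
                          n_levels = list(AD15 = c(0, 60, 120, 180, 230, 280))),
    n_compounds = 30,
    features_csv = NULL, metadata_csv = NULL, plots_csv = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_header <- function(config) {
  c(seed = config$seed, package = "groatlab",
    version = as.character(utils::packageVersion("groatlab")))
}

#' Run the metabolomics pipeline end to end
#'
#' Executes filtering (retention window, blank features), normalisation,
#' the QA RSD filter, correlation grouping with adduct/isotope annotation,
#' collapse to one representative feature per group, PCA and MB-HPCA under
#' the configured blocking, and the nonparametric nitrogen screen (Spearman
#' rho + Friedman tests with BH-FDR). Inputs are read from
#' `config$features_csv` / `config$metadata_csv` when given; otherwise a
#' seeded synthetic dataset is generated. All intermediate tables are
#' written under `config$out_dir` with the seed in a comment header.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: per-stage feature counts (`stages`, with
#'   out = in - removed at every stage), parameter echo, elapsed seconds,
#'   and the result objects (`processed`, `collapsed`, `pca`, `mbhpca`,
#'   `screen`).
#' @export
run_metabolomics <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (!is.null(config$features_csv)) {
    table <- read_feature_csv(config$features_csv, config$metadata_csv)
  } else {
    sim <- generate_lcms_dataset(
      config$design,
      example_compounds(config$n_compounds, seed = config$seed),
      seed = config$seed
    )
    table <- sim$table
  }
  stages <- list()
  note <- function(stage, before, after) {
    stages[[stage]] <<- data.frame(stage = stage, features_in = before,
                                   features_out = after,
                                   removed = before - after)
  }
  n0 <- nrow(table$intensities)
  table <- exclude_rt_window(table, config$rt_exclusion_window)
  note("rt_window", n0, nrow(table$intensities))
  n1 <- nrow(table$intensities)
  table <- remove_blank_features(table, config$blank_fold)
  note("blank_filter", n1, nrow(table$intensities))
  table <- drop_sample_role(table, "blank")
  ## grouping/annotation on raw EIC areas; normalisation afterwards
  n2 <- nrow(table$intensities)
  groups <- group_by_correlation(table, config$rt_tol, config$r_min)
  annotations <- annotate_groups(groups, table, mz_tol_ppm = config$mz_tol_ppm)
  collapsed <- collapse_to_representative(groups, annotations, table)
  note("collapse", n2, nrow(collapsed$intensities))
  collapsed <- if (identical(config$normalisation, "tic")) {
    tic_normalise(collapsed)
  } else {
    is_normalise(collapsed, config$is_feature_id)
  }
  n3 <- nrow(collapsed$intensities)
  rsd <- qa_rsd_filter(collapsed, config$rsd_threshold)
  collapsed <- rsd$table
  note("qa_rsd", n3, nrow(collapsed$intensities))
  table <- collapsed

  exp_cols <- collapsed$samples$role == "experimental"
  X <- t(collapsed$intensities[, exp_cols, drop = FALSE])
  meta <- collapsed$samples[exp_cols, ]
  pca <- pca_fit(X, config$n_components, scaling = config$scaling)
  mb <- NULL
  if (length(unique(meta$trial)) == 1) {
    blocking_col <- if (config$blocking == "variety") "variety" else "n_level"
    blocks <- make_blocks(X, meta, blocking_col)
    mb <- mbhpca_fit(blocks, config$n_components)
  }
  rho <- spearman_screen(t(X), meta$n_level)
  fr_n <- friedman_screen(t(X), treatment = meta$n_level, block = meta$variety)
  fr_v <- friedman_screen(t(X), treatment = meta$variety, block = meta$n_level)
  screen <- data.frame(
    feature_id = collapsed$features$feature_id,
    rho = rho,
    friedman_n_stat = fr_n$statistic, friedman_n_p = fr_n$p_value,
    friedman_v_stat = fr_v$statistic, friedman_v_p = fr_v$p_value
  )
  screen$q_n <- bh_fdr(screen$friedman_n_p, config$fdr_q)$q_value
  screen$q_v <- bh_fdr(screen$friedman_v_p, config$fdr_q)$q_value
  screen$sig_n <- screen$q_n <= config$fdr_q
  screen$sig_v <- screen$q_v <= config$fdr_q

  hdr <- config_header(config)
  write_feature_csv(table,
                    file.path(config$out_dir, "processed_features.csv"),
                    file.path(config$out_dir, "sample_metadata.csv"),
                    header = hdr)
  write_csv_with_header(annotations, file.path(config$out_dir, "annotations.csv"), hdr)
  write_csv_with_header(rsd$report, file.path(config$out_dir, "qa_report.csv"), hdr)
  write_csv_with_header(screen, file.path(config$out_dir, "nitrogen_screen.csv"), hdr)
  write_csv_with_header(as.data.frame(pca$scores),
                        file.path(config$out_dir, "pca_scores.csv"), hdr)

  structure(
    list(stages = do.call(rbind, stages), config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         processed = table, collapsed = collapsed, groups = groups,
         annotations = annotations, pca = pca, mbhpca = mb, screen = screen),
    class = "run_report"
  )
}

#' Run the agronomy pipeline end to end
#'
#' Per trial and trait: split-plot ANOVA and protected-LSD letter displays
#' for the nitrogen means; per variety: the linear-plus-exponential yield
#' response with its economic optimum N (an undefined optimum — marginal
#' yield still above breakeven at the top dose — is recorded with its
#' reason, not an error).
#'
#' @param config a [pipeline_config()]; plots are read from
#'   `config$plots_csv` when given, otherwise generated synthetically.
#' @return a `run_report` list with `anova` (per trial), `letters`,
#'   `fits` (per trial x variety: parameters + `n_opt` + reason).
#' @export
run_agronomy <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  plots <- if (!is.null(config$plots_csv)) {
    utils::read.csv(config$plots_csv, comment.char = "#")
  } else {
    generate_agronomy_trials(config$design, seed = config$seed)
  }
  plots$lodging_index <- lodging_index(plots$pct_lodged, plots$pct_leaning)
  yc <- yield_components(plots$yield_t_ha, plots$tgw_g, plots$panicles_m2,
                         config$dm_fraction)
  plots <- cbind(plots, yc[, c("grains_m2", "grains_per_panicle")])

  anovas <- list()
  letters_tabs <- list()
  fits <- list()
  for (tr in unique(plots$trial)) {
    sub <- plots[plots$trial == tr, ]
    a <- splitplot_anova(sub, "yield_t_ha")
    anovas[[tr]] <- cbind(trial = tr, a)
    mse <- a$ms[a$source == "main_plot_error"]
    dfe <- a$df[a$source == "main_plot_error"]
    nmeans <- tapply(sub$yield_t_ha, sub$applied_n, mean)
    npm <- sum(sub$applied_n == sub$applied_n[1]) # plots per N level
    lt <- fisher_lsd_letters(nmeans, mse, dfe, npm,
                             omnibus_p = a$p[a$source == "nitrogen"])
    letters_tabs[[tr]] <- cbind(trial = tr, lt)
    for (v in unique(sub$variety)) {
      vs <- sub[sub$variety == v, ]
      fit <- fit_linexp(vs$applied_n, vs$yield_t_ha)
      opt <- economic_optimum(fit, k = config$breakeven_k,
                              n_max = max(vs$applied_n))
      fits[[paste(tr, v, sep = "_")]] <- data.frame(
        trial = tr, variety = v, a = fit$a, b = fit$b, r = fit$r, c = fit$c,
        residual_sd = fit$residual_sd, n_opt = opt$n_opt,
        n_opt_reason = ifelse(is.na(opt$n_opt), opt$reason, NA)
      )
    }
  }
  anova_tab <- do.call(rbind, anovas)
  letters_tab <- do.call(rbind, letters_tabs)
  fit_tab <- do.call(rbind, fits)
  rownames(anova_tab) <- rownames(letters_tab) <- rownames(fit_tab) <- NULL

  hdr <- config_header(config)
  write_csv_with_header(anova_tab, file.path(config$out_dir, "anova_yield.csv"), hdr)
  write_csv_with_header(letters_tab, file.path(config$out_dir, "nitrogen_means_letters.csv"), hdr)
  write_csv_with_header(fit_tab, file.path(config$out_dir, "n_response_fits.csv"), hdr)
  jsonlite::write_json(fit_tab, file.path(config$out_dir, "n_response_fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  structure(
    list(config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         plots = plots, anova = anova_tab, letters = letters_tab,
         fits = fit_tab),
    class = "run_report"
  )
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(paste0("# ", names(header), "=", header), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE)
  close(con)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<groatlab run report>\n")
  if (!is.null(x$stages)) {
    print(x$stages, row.names = FALSE)
  }
  cat(sprintf("  elapsed: %.1f s; outputs in %s\n",
              x$elapsed_s, x$config$out_dir))
  invisible(x)
}
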