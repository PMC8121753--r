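## Synthetic LC-MS / GC-MS dataset generation with known ground truth.
##
## Intensity model (multiplicative, positive by construction):
##   true(compound, sample)   = base * variety_factor * exp(n_effect * appliedN)
##   true(feature,  sample)   = true(compound, sample) * rel_ab(form)
##   observed                 = true(feature, sample) * exp(rnorm(0, sdlog))
## with sdlog = sqrt(log(1 + cv^2)) so that the theoretical RSD of the
## log-normal noise equals the requested technical CV exactly.

sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

build_sample_sheet <- function(design, randomise_run_order = TRUE) {
  qa <- design$qa_schedule
  rows <- list()
  order_counter <- 0L
  nxt <- function() {
    order_counter <<- order_counter + 1L
    order_counter
  }
  for (tr in design$trials) {
    doses <- design$n_levels[[tr]]
    exp_grid <- expand.grid(variety = design$varieties, n_level = doses,
                            replicate = seq_len(design$replicates),
                            stringsAsFactors = FALSE)
    if (randomise_run_order) {
      exp_grid <- exp_grid[sample(nrow(exp_grid)), , drop = FALSE]
    }
    add <- function(id, role, qa_kind = NA, variety = NA, n_level = NA,
                    replicate = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = id, trial = tr, variety = variety, n_level = n_level,
        replicate = replicate, role = role, qa_kind = qa_kind,
        run_order = nxt(), stringsAsFactors = FALSE
      )
    }
    n_blank_start <- ceiling(design$blank_count / 2)
    for (b in seq_len(n_blank_start)) {
      add(sprintf("%s_BLK%02d", tr, b), "blank")
    }
    qa_i <- 0L
    add_qa <- function(kind) {
      qa_i <<- qa_i + 1L
      add(sprintf("%s_QA%02d", tr, qa_i), "qa", qa_kind = kind)
    }
    for (i in seq_len(qa$conditioning)) add_qa("conditioning")
    for (i in seq_len(qa$lead_in)) add_qa("lead_in")
    for (i in seq_len(nrow(exp_grid))) {
      g <- exp_grid[i, ]
      add(sprintf("%s_%s_N%03d_R%d", tr, g$variety, g$n_level, g$replicate),
          "experimental", variety = g$variety, n_level = g$n_level,
          replicate = g$replicate)
      if (i %% qa$every == 0 && i < nrow(exp_grid)) add_qa("periodic")
    }
    for (i in seq_len(qa$terminal)) add_qa("terminal")
    for (b in seq_len(design$blank_count - n_blank_start)) {
      add(sprintf("%s_BLK%02d", tr, n_blank_start + b), "blank")
    }
  }
  do.call(rbind, rows)
}

## One feature row per compound x ion form (parent, adducts, isotopologues).
compound_feature_rows <- function(compounds, adducts) {
  rows <- list()
  for (cmp in compounds) {
    shift_of <- function(a) adducts$shift_da[match(a, adducts$name)]
    parent_mz <- cmp$neutral_mass + shift_of(cmp$parent_adduct)
    for (j in seq_len(nrow(cmp$adduct_family))) {
      a <- cmp$adduct_family$adduct[j]
      role <- if (a == cmp$parent_adduct) "parent" else paste0("adduct:", a)
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp$name, role = role,
        mz = cmp$neutral_mass + shift_of(a),
        rt = cmp$rt + stats::rnorm(1, 0, 0.002),
        rel_ab = cmp$adduct_family$rel_ab[j], stringsAsFactors = FALSE
      )
    }
    parent_rel <- cmp$adduct_family$rel_ab[
      cmp$adduct_family$adduct == cmp$parent_adduct]
    for (k in seq_along(cmp$isotope_abundances)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cmp$name, role = sprintf("isotope+%d", k),
        mz = parent_mz + k * ISOTOPE_SPACING,
        rt = cmp$rt + stats::rnorm(1, 0, 0.002),
        rel_ab = parent_rel * cmp$isotope_abundances[k],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

## Per-compound noiseless intensity for one experimental sample.
compound_true_level <- function(cmp, variety, n_level) {
  vf <- cmp$variety_effects[[variety]]
  if (is.null(vf) || is.na(vf)) vf <- 1
  cmp$base_intensity * vf * exp(cmp$n_effect * n_level)
}

#' Generate a synthetic LC-MS feature table with known ground truth
#'
#' Emulates the deconvolved output of an untargeted LC-MS run over a
#' split-plot nitrogen-response field trial: one feature per compound x ion
#' form (parent, adducts, +1/+2 isotopologues), plus nuisance features
#' dominant in blank extracts and void/equilibration features eluting in the
#' column re-equilibration window. Pooled-QA injections are drawn from the
#' mean of all experimental samples with technical noise only; run order is
#' recorded for every injection.
#'
#' @param design a [study_design()].
#' @param compounds list of [compound_truth()] (unique names, >= 1).
#' @param seed RNG seed; identical inputs and seed give bit-identical output.
#' @param n_blank_features,n_void_features counts of nuisance features.
#' @param nuisance_cv technical CV of the nuisance features.
#' @param drift optional linear intensity drift per run-order unit on the log
#'   scale (0 = none, the default: no drift is simulated).
#' @param rt_void_window retention window (minutes) in which void features
#'   elute.
#' @return list with elements `table` (a [feature_table()]) and `truth`
#'   (a `synthetic_truth` list: `compounds`, `feature_to_compound`,
#'   `blank_feature_ids`, `void_feature_ids`).
#' @export
generate_lcms_dataset <- function(design, compounds, seed,
                                  n_blank_features = 20,
                                  n_void_features = 10,
                                  nuisance_cv = 0.3,
                                  drift = 0,
                                  rt_void_window = c(36, 40)) {
  stopifnot(inherits(design, "study_design"), length(compounds) >= 1)
  nms <- vapply(compounds, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate compound names")
  polarity <- if (compounds[[1]]$parent_adduct %in% c("[M-H]")) "ESI-" else "ESI+"
  adducts <- default_adducts(polarity)
  set.seed(seed)
  samples <- build_sample_sheet(design)

  feat <- compound_feature_rows(compounds, adducts)
  n_cf <- nrow(feat)
  blank_rows <- if (n_blank_features > 0) data.frame(
    compound = NA, role = "blank",
    mz = round(stats::runif(n_blank_features, 100, 900), 4),
    rt = round(stats::runif(n_blank_features, 1, 35), 3),
    rel_ab = 1
  ) else NULL
  void_rows <- if (n_void_features > 0) data.frame(
    compound = NA, role = "void",
    mz = round(stats::runif(n_void_features, 100, 900), 4),
    rt = round(stats::runif(n_void_features, rt_void_window[1] + 0.01,
                            rt_void_window[2] - 0.01), 3),
    rel_ab = 1
  ) else NULL
  feat <- rbind(feat, blank_rows, void_rows)
  feat$feature_id <- sprintf("F%04d", seq_len(nrow(feat)))
  nuisance_base <- 10^stats::runif(nrow(feat) - n_cf, 4.5, 6)

  n_feat <- nrow(feat)
  n_samp <- nrow(samples)
  X <- matrix(0, n_feat, n_samp)
  cmp_index <- match(feat$compound, nms)
  sdlog_n <- sdlog_from_cv(nuisance_cv)

  ## technical-noise-free per-feature intensity for each experimental
  ## sample: design effects plus the per-(compound, plot) biological
  ## factor shared by all ion forms of a compound
  exp_cols <- which(samples$role == "experimental")
  bio <- matrix(1, length(compounds), length(exp_cols))
  for (ci in seq_along(compounds)) {
    bcv <- compounds[[ci]]$biological_cv
    if (!is.null(bcv) && bcv > 0) {
      bio[ci, ] <- exp(stats::rnorm(length(exp_cols), 0, sdlog_from_cv(bcv)))
    }
  }
  true_exp <- matrix(0, n_feat, length(exp_cols))
  for (j in seq_along(exp_cols)) {
    s <- samples[exp_cols[j], ]
    for (i in seq_len(n_cf)) {
      cmp <- compounds[[cmp_index[i]]]
      true_exp[i, j] <- compound_true_level(cmp, s$variety, s$n_level) *
        feat$rel_ab[i] * bio[cmp_index[i], j]
    }
  }
  pooled <- rowMeans(true_exp)

  for (j in seq_len(n_samp)) {
    role <- samples$role[j]
    for (i in seq_len(n_feat)) {
      if (i <= n_cf) {
        cmp <- compounds[[cmp_index[i]]]
        sdlog <- sdlog_from_cv(cmp$technical_cv)
        base_val <- switch(role,
          experimental = true_exp[i, match(j, exp_cols)],
          qa = pooled[i],
          blank = 0
        )
      } else {
        b <- nuisance_base[i - n_cf]
        is_blank_feature <- feat$role[i] == "blank"
        sdlog <- sdlog_n
        base_val <- if (is_blank_feature) {
          if (role == "blank") b else b / 20
        } else {
          b
        }
      }
      if (base_val > 0) {
        noise <- if (sdlog > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
        X[i, j] <- base_val * noise
      }
    }
  }
  if (drift != 0) {
    d <- exp(drift * (samples$run_order - mean(samples$run_order)))
    X <- sweep(X, 2, d, `*`)
  }

  features <- feat[, c("feature_id", "mz", "rt")]
  table <- feature_table(features, samples, X, polarity = polarity)
  truth <- structure(
    list(
      compounds = compounds,
      feature_to_compound = feat[!is.na(feat$compound),
                                 c("feature_id", "compound", "role")],
      blank_feature_ids = feat$feature_id[feat$role == "blank"],
      void_feature_ids = feat$feature_id[feat$role == "void"]
    ),
    class = "synthetic_truth"
  )
  list(table = table, truth = truth)
}

#' Generate a synthetic GC-MS dataset with known ground truth
#'
#' GC-MS features are one-to-one with compounds (a single quantifier feature
#' each), carry a retention index and a reference electron-ionisation
#' spectrum, and include an internal standard whose true abundance is
#' constant in every sample (perturbed only by technical noise). The return
#' value includes the reference spectral library for identification.
#'
#' @inheritParams generate_lcms_dataset
#' @param compounds list of [compound_truth()] with `ri` and `spectrum` set;
#'   exactly one flagged `is_internal_standard`.
#' @return list with `table` (polarity `"GC-EI"`; features carry an `ri`
#'   column), `truth` (with `is_feature_id` and per-feature `spectra`), and
#'   `library` (list of spectral library entries: `name`, `ri`, `spectrum`).
#' @export
generate_gcms_dataset <- function(design, compounds, seed) {
  stopifnot(inherits(design, "study_design"), length(compounds) >= 1)
  nms <- vapply(compounds, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate compound names")
  is_std <- vapply(compounds, `[[`, TRUE, "is_internal_standard")
  if (sum(is_std) != 1) stop("exactly one compound must be flagged as the internal standard")
  set.seed(seed)
  samples <- build_sample_sheet(design)
  n_samp <- nrow(samples)
  n_feat <- length(compounds)
  X <- matrix(0, n_feat, n_samp)
  exp_like <- samples$role != "blank"
  exp_cols <- which(samples$role == "experimental")
  for (i in seq_len(n_feat)) {
    cmp <- compounds[[i]]
    sdlog <- sdlog_from_cv(cmp$technical_cv)
    bio <- rep(1, n_samp)
    if (!is.null(cmp$biological_cv) && cmp$biological_cv > 0) {
      bio[exp_cols] <- exp(stats::rnorm(length(exp_cols), 0,
                                        sdlog_from_cv(cmp$biological_cv)))
    }
    for (j in seq_len(n_samp)) {
      base_val <- if (cmp$is_internal_standard) {
        cmp$base_intensity  # constant spike, every sample incl. blanks
      } else if (samples$role[j] == "experimental") {
        compound_true_level(cmp, samples$variety[j], samples$n_level[j]) * bio[j]
      } else if (samples$role[j] == "qa") {
        mean(vapply(which(samples$role == "experimental"), function(k) {
          compound_true_level(cmp, samples$variety[k], samples$n_level[k])
        }, 0))
      } else {
        0
      }
      if (base_val > 0) {
        noise <- if (sdlog > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
        X[i, j] <- base_val * noise
      }
    }
  }
  base_peak <- vapply(compounds, function(cmp) {
    sp <- as.data.frame(cmp$spectrum)
    sp$mz[which.max(sp$intensity)]
  }, 0)
  features <- data.frame(
    feature_id = sprintf("G%04d", seq_len(n_feat)),
    mz = base_peak,
    rt = vapply(compounds, `[[`, 0, "rt"),
    ri = vapply(compounds, `[[`, 0, "ri")
  )
  table <- feature_table(features, samples, X, polarity = "GC-EI")
  spectra <- lapply(compounds, function(cmp) as.data.frame(cmp$spectrum))
  names(spectra) <- features$feature_id
  library_entries <- lapply(compounds, function(cmp) {
    list(name = cmp$name, ri = cmp$ri, spectrum = as.data.frame(cmp$spectrum))
  })
  truth <- structure(
    list(
      compounds = compounds,
      feature_to_compound = data.frame(
        feature_id = features$feature_id, compound = nms, role = "parent"
      ),
      blank_feature_ids = character(),
      void_feature_ids = character(),
      is_feature_id = features$feature_id[is_std],
      spectra = spectra
    ),
    class = "synthetic_truth"
  )
  list(table = table, truth = truth, library = library_entries)
}

#' Write a ground-truth object as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    compounds = lapply(truth$compounds, function(cmp) {
      cmp[c("name", "neutral_mass", "rt", "parent_adduct", "base_intensity",
            "n_effect", "technical_cv")]
    }),
    feature_to_compound = truth$feature_to_compound,
    blank_feature_ids = truth$blank_feature_ids,
    void_feature_ids = truth$void_feature_ids
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
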