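#' Exclude features eluting in a retention-time window
#'
#' Removes features whose retention time falls inside the closed interval
#' `[window[1], window[2]]` — typically the column wash/re-equilibration
#' window at the end of the gradient, whose peaks are not chromatographic.
#'
#' @param table a [feature_table()].
#' @param window numeric length-2, minutes, start < end. Closed on both ends.
#' @return filtered `feature_table`; removals are logged (see
#'   [removed_features()]).
#' @export
exclude_rt_window <- function(table, window = c(36, 40)) {
  stopifnot(length(window) == 2)
  if (window[1] >= window[2]) stop("inverted retention-time window")
  keep <- !(table$features$rt >= window[1] & table$features$rt <= window[2])
  subset_features(table, keep, "rt_window")
}

#' Remove features dominant in blank extracts
#'
#' A feature is considered blank-derived when its mean intensity across blank
#' samples exceeds `fold` times its mean across experimental samples.
#'
#' @param table a [feature_table()] containing at least one blank sample.
#' @param fold blank/experimental mean-intensity ratio threshold (>= 1).
#' @return filtered `feature_table` with removals logged.
#' @export
remove_blank_features <- function(table, fold = 3) {
  if (fold < 1) stop("fold must be >= 1")
  if (!any(table$samples$role == "blank")) {
    stop("no blank samples present; skip blank filtering explicitly if intended")
  }
  blank_mean <- rowMeans(role_matrix(table, "blank"))
  exp_mean <- rowMeans(role_matrix(table, "experimental"))
  keep <- !(blank_mean > fold * exp_mean)
  subset_features(table, keep, "blank_dominant")
}

#' Total-ion-current normalisation
#'
#' Divides every sample column by its total intensity, so each normalised
#' column sums to 1. Any constant rescaling of a sample leaves its
#' normalised column unchanged, and all downstream rank/correlation
#' statistics are invariant to the choice of constant.
#'
#' @param table a [feature_table()]; every sample must have positive total
#'   intensity.
#' @return normalised `feature_table`.
#' @export
tic_normalise <- function(table) {
  tot <- colSums(table$intensities)
  if (any(tot <= 0)) stop("zero-total-intensity sample column")
  out <- table
  out$intensities <- sweep(table$intensities, 2, tot, `/`)
  out
}

#' Internal-standard normalisation
#'
#' Divides every sample column by that sample's internal-standard intensity
#' (GC-MS convention: a ribitol/sorbitol spike). The internal-standard row
#' becomes all 1.
#'
#' @param table a [feature_table()].
#' @param is_feature_id feature id of the internal standard; must have
#'   positive intensity in every sample.
#' @return normalised `feature_table`.
#' @export
is_normalise <- function(table, is_feature_id) {
  i <- match(is_feature_id, table$features$feature_id)
  if (is.na(i)) stop("internal-standard feature not found: ", is_feature_id)
  is_row <- table$intensities[i, ]
  if (any(is_row <= 0)) stop("internal-standard intensity is 0 in some sample")
  out <- table
  out$intensities <- sweep(table$intensities, 2, is_row, `/`)
  out
}

#' Pooled-QA relative-standard-deviation filter
#'
#' Computes each feature's RSD (100 * sd / mean, sample sd with n-1
#' denominator) across the pooled-QA injections and removes features above
#' the threshold. A feature absent from every QA (mean 0) has undefined RSD
#' and is removed, flagged in the report.
#'
#' @param table a [feature_table()] with at least 3 QA samples.
#' @param threshold RSD threshold in percent (default 25).
#' @param exclude_conditioning drop column-conditioning QA injections (when a
#'   `qa_kind` metadata column is present) before computing RSDs.
#' @return list with `table` (filtered) and `report` (data.frame:
#'   `feature_id`, `rsd_pct`, `removed`).
#' @export
qa_rsd_filter <- function(table, threshold = 25, exclude_conditioning = FALSE) {
  if (threshold <= 0) stop("threshold must be > 0")
  qa_cols <- table$samples$role == "qa"
  if (exclude_conditioning && "qa_kind" %in% names(table$samples)) {
    qa_cols <- qa_cols & !(table$samples$qa_kind %in% "conditioning")
  }
  if (sum(qa_cols) < 3) stop("need at least 3 QA samples")
  qa <- table$intensities[, qa_cols, drop = FALSE]
  m <- rowMeans(qa)
  s <- apply(qa, 1, stats::sd)
  rsd <- ifelse(m > 0, 100 * s / m, Inf)
  keep <- rsd <= threshold
  report <- data.frame(
    feature_id = table$features$feature_id,
    rsd_pct = rsd, removed = !keep,
    row.names = NULL
  )
  list(table = subset_features(table, keep, "qa_rsd"), report = report)
}
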