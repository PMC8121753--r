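#' Feature table container
#'
#' The central data structure of the package: a features x samples intensity
#' matrix with per-feature retention/mass metadata and per-sample design
#' metadata, as produced by peak deconvolution of an LC-MS or GC-MS run.
#'
#' @param features data.frame with columns `feature_id`, `mz` (Da) and `rt`
#'   (minutes). GC-EI tables may additionally carry an `ri` (retention index)
#'   column.
#' @param samples data.frame with columns `sample_id` and `role` (one of
#'   `"experimental"`, `"qa"`, `"blank"`); design columns (`trial`, `variety`,
#'   `n_level`, `replicate`, `run_order`) are carried through when present.
#' @param intensities numeric matrix, `nrow(features)` x `nrow(samples)`,
#'   non-negative. Row/column names are set to feature and sample ids.
#' @param polarity one of `"ESI+"`, `"ESI-"`, `"GC-EI"`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `features`, `samples`, `intensities`, `polarity`.
#' @export
#' @examples
#' ft <- feature_table(
#'   features = data.frame(feature_id = c("F1", "F2"), mz = c(299.1, 300.1),
#'                         rt = c(5.2, 5.2)),
#'   samples = data.frame(sample_id = c("s1", "s2"),
#'                        role = c("experimental", "qa")),
#'   intensities = matrix(c(10, 11, 20, 19), nrow = 2, byrow = TRUE)
#' )
#' dim(ft)
feature_table <- function(features, samples, intensities, polarity = "ESI+") {
  stopifnot(is.data.frame(features), is.data.frame(samples))
  required_f <- c("feature_id", "mz", "rt")
  if (!all(required_f %in% names(features))) {
    stop("`features` needs columns: ", paste(required_f, collapse = ", "))
  }
  if (!all(c("sample_id", "role") %in% names(samples))) {
    stop("`samples` needs columns: sample_id, role")
  }
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) || ncol(intensities) != nrow(samples)) {
    stop("intensity matrix dimensions do not match feature/sample lists")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!all(samples$role %in% c("experimental", "qa", "blank"))) {
    stop("sample role must be experimental, qa or blank")
  }
  polarity <- match.arg(polarity, c("ESI+", "ESI-", "GC-EI"))
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(features = features, samples = samples,
         intensities = intensities, polarity = polarity),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s)\n",
    nrow(x$intensities), ncol(x$intensities), x$polarity
  ))
  roles <- table(x$samples$role)
  cat("  samples:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  invisible(x)
}

## Row-subset helper used by every filter: keeps surviving rows bitwise
## unchanged and records what was removed and why.
subset_features <- function(table, keep, reason) {
  removed <- table$features$feature_id[!keep]
  out <- table
  out$features <- table$features[keep, , drop = FALSE]
  rownames(out$features) <- NULL
  out$intensities <- table$intensities[keep, , drop = FALSE]
  prev <- attr(table, "removed_features")
  rec <- if (length(removed)) {
    data.frame(feature_id = removed, reason = reason, stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(), reason = character(), stringsAsFactors = FALSE)
  }
  attr(out, "removed_features") <- rbind(prev, rec)
  out
}

#' Removal log of a filtered feature table
#'
#' Filters record removed feature ids and the reason for removal; this
#' accessor returns the accumulated log.
#'
#' @param table a `feature_table` that has passed through one or more filters.
#' @return data.frame with columns `feature_id`, `reason` (possibly 0 rows).
#' @export
removed_features <- function(table) {
  out <- attr(table, "removed_features")
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Intensity sub-matrix for a sample role
#'
#' @param table a `feature_table`.
#' @param role sample role to select (`"experimental"`, `"qa"` or `"blank"`).
#' @return numeric matrix (features x selected samples).
#' @export
role_matrix <- function(table, role) {
  table$intensities[, table$samples$role == role, drop = FALSE]
}

#' Drop all samples of a given role
#'
#' Typically used to drop blank-extract columns once blank-derived features
#' have been removed (their columns are all zero afterwards and would break
#' total-ion-current normalisation).
#'
#' @param table a `feature_table`.
#' @param role sample role to drop.
#' @return `feature_table` without those sample columns.
#' @export
drop_sample_role <- function(table, role) {
  keep <- table$samples$role != role
  out <- table
  out$samples <- table$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$intensities <- table$intensities[, keep, drop = FALSE]
  out
}

#' Write / read a feature table as plain CSV
#'
#' The on-disk layout mirrors XCMS-style exports: one row per feature with
#' `feature_id`, `mz`, `rt` (and `ri` if present) followed by one intensity
#' column per sample; sample metadata goes to a companion CSV. An optional
#' `# key=value` comment header records provenance (e.g. the seed).
#'
#' @param table a `feature_table`.
#' @param features_path,metadata_path output CSV paths.
#' @param header named character vector written as `# name=value` lines.
#' @return `write_feature_csv` invisibly returns the paths;
#'   `read_feature_csv` returns a `feature_table`.
#' @export
write_feature_csv <- function(table, features_path, metadata_path, header = NULL) {
  hdr <- if (length(header)) paste0("# ", names(header), "=", header) else character()
  fdf <- cbind(table$features,
               as.data.frame(table$intensities, check.names = FALSE))
  con <- file(features_path, "w")
  writeLines(c(hdr, paste(colnames(fdf), collapse = ",")), con)
  utils::write.table(fdf, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  con <- file(metadata_path, "w")
  writeLines(hdr, con)
  utils::write.table(table$samples, con, sep = ",", row.names = FALSE)
  close(con)
  invisible(c(features_path, metadata_path))
}

#' @rdname write_feature_csv
#' @param polarity polarity tag for the reconstructed table.
#' @export
read_feature_csv <- function(features_path, metadata_path, polarity = "ESI+") {
  fdf <- utils::read.csv(features_path, comment.char = "#", check.names = FALSE)
  samples <- utils::read.csv(metadata_path, comment.char = "#")
  meta_cols <- intersect(c("feature_id", "mz", "rt", "ri"), names(fdf))
  features <- fdf[, meta_cols, drop = FALSE]
  intens <- as.matrix(fdf[, setdiff(names(fdf), meta_cols), drop = FALSE])
  feature_table(features, samples, intens, polarity = polarity)
}
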