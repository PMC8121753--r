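#' Group co-eluting, correlated features
#'
#' Builds a graph with an edge between two features when their retention
#' times differ by at most `rt_tol` minutes AND their Pearson correlation
#' across experimental samples is at least `r_min`, then returns the
#' connected components (single-linkage): each component is an RT-m/z group
#' of features likely derived from one compound. Singletons are allowed, and
#' the result is a partition of all features.
#'
#' @param table a [feature_table()] with >= 4 experimental samples.
#' @param rt_tol retention-time tolerance, minutes.
#' @param r_min minimum Pearson correlation, in (0, 1).
#' @param use_roles sample roles used for the correlation (default
#'   experimental only).
#' @return list of `feature_group` lists: `group_id`, `feature_ids`,
#'   `rt_centroid`.
#' @export
group_by_correlation <- function(table, rt_tol = 0.05, r_min = 0.8,
                                 use_roles = "experimental") {
  stopifnot(r_min > 0, r_min < 1)
  X <- table$intensities[, table$samples$role %in% use_roles, drop = FALSE]
  if (ncol(X) < 4) stop("need at least 4 samples to define correlations")
  n <- nrow(X)
  rt <- table$features$rt
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(rt)
  suppressWarnings(cmat <- stats::cor(t(X)))
  cmat[is.na(cmat)] <- 0
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (rt[j] - rt[i] > rt_tol) break
      if (cmat[i, j] >= r_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- split(table$features$feature_id, comp)
  rts <- split(rt, comp)
  groups <- Map(function(fid, r) list(feature_ids = fid, rt_centroid = mean(r)),
                ids, rts)
  ## stable ordering by centroid retention time
  groups <- groups[order(vapply(groups, `[[`, 0, "rt_centroid"))]
  for (k in seq_along(groups)) groups[[k]]$group_id <- sprintf("G%04d", k)
  unname(groups)
}

#' Annotate adduct and isotope roles within an RT-m/z group
#'
#' Searches pairwise m/z relations for matches to adduct mass-shift
#' differences and to the 13C isotope spacing (1.00336 Da, chained +1/+2/+3
#' from the parent), all at ppm tolerance. The parent is the most intense
#' member that, read as the primary ion form (`[M+H]` in positive mode,
#' `[M-H]` in negative), explains at least one other member; ties are broken
#' by lowest m/z. If no member explains any other, the most intense member
#' is labelled parent by default. Every assignment carries its ppm error as
#' evidence.
#'
#' @param group one group from [group_by_correlation()].
#' @param table the [feature_table()] the group refers to.
#' @param adducts adduct table restricted to the table's polarity.
#' @param mz_tol_ppm tolerance on m/z differences, ppm.
#' @param max_isotope highest isotopologue searched.
#' @return data.frame of annotations: `feature_id`, `group_id`, `role`,
#'   `neutral_mass`, `ppm_error`.
#' @export
annotate_adducts_isotopes <- function(group, table,
                                      adducts = default_adducts(table$polarity),
                                      mz_tol_ppm = 5, max_isotope = 3) {
  if (nrow(adducts) == 0) stop("empty adduct table")
  idx <- match(group$feature_ids, table$features$feature_id)
  mz <- table$features$mz[idx]
  inten <- rowMeans(role_matrix(table, "experimental")[idx, , drop = FALSE])
  n <- length(idx)
  primary <- primary_ion_name(table$polarity)
  empty <- data.frame(
    feature_id = group$feature_ids, group_id = group$group_id,
    role = "unassigned", neutral_mass = NA_real_, ppm_error = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n == 1) {
    empty$role <- "parent"
    empty$neutral_mass <- neutral_mass(mz, primary, adducts)
    return(empty)
  }

  tol_da <- function(m) mz_tol_ppm * 1e-6 * m
  ## role of feature j relative to a hypothetical parent p: list(role, ppm)
  explain <- function(M_p, mz_p, mz_j) {
    for (k in seq_len(max_isotope)) {
      expect <- mz_p + k * ISOTOPE_SPACING
      if (abs(mz_j - expect) <= tol_da(mz_j)) {
        return(list(role = sprintf("isotope+%d", k),
                    ppm = 1e6 * (mz_j - expect) / mz_j))
      }
    }
    best <- NULL
    for (a in setdiff(adducts$name, primary)) {
      expect <- mz_for_adduct(M_p, a, adducts)
      err <- mz_j - expect
      if (abs(err) <= tol_da(mz_j)) {
        ppm <- 1e6 * err / mz_j
        if (is.null(best) || abs(ppm) < abs(best$ppm)) {
          best <- list(role = paste0("adduct:", a), ppm = ppm)
        }
      }
    }
    best
  }

  explained_count <- integer(n)
  for (p in seq_len(n)) {
    M_p <- neutral_mass(mz[p], primary, adducts)
    for (j in seq_len(n)[-p]) {
      if (!is.null(explain(M_p, mz[p], mz[j]))) {
        explained_count[p] <- explained_count[p] + 1L
      }
    }
  }
  cand <- which(explained_count >= 1L)
  parent_i <- if (length(cand)) {
    cand[order(-inten[cand], mz[cand])][1]
  } else {
    which(inten == max(inten))[which.min(mz[inten == max(inten)])]
  }

  out <- empty
  M <- neutral_mass(mz[parent_i], primary, adducts)
  out$role[parent_i] <- "parent"
  out$neutral_mass[parent_i] <- M
  out$ppm_error[parent_i] <- 0
  if (length(cand)) {
    for (j in seq_len(n)[-parent_i]) {
      hit <- explain(M, mz[parent_i], mz[j])
      if (!is.null(hit)) {
        out$role[j] <- hit$role
        out$neutral_mass[j] <- M
        out$ppm_error[j] <- hit$ppm
      }
    }
  }
  out
}

#' Annotate every group of a table
#'
#' @param groups list from [group_by_correlation()].
#' @inheritParams annotate_adducts_isotopes
#' @return single data.frame of annotations for all groups (exactly one
#'   parent per group).
#' @export
annotate_groups <- function(groups, table,
                            adducts = default_adducts(table$polarity),
                            mz_tol_ppm = 5) {
  do.call(rbind, lapply(groups, annotate_adducts_isotopes, table = table,
                        adducts = adducts, mz_tol_ppm = mz_tol_ppm))
}

#' Collapse each group to its most intense representative feature
#'
#' Keeps, per RT-m/z group, the member with the highest mean experimental
#' intensity, and attaches group metadata (group id, the kept member's role
#' and the group's neutral mass) to the feature table. The output has
#' exactly one row per group.
#'
#' @param groups list from [group_by_correlation()].
#' @param annotations data.frame from [annotate_groups()].
#' @param table the [feature_table()] the groups refer to.
#' @return collapsed `feature_table`; `features` gains `group_id`, `role`,
#'   `neutral_mass` and `n_members` columns.
#' @export
collapse_to_representative <- function(groups, annotations, table) {
  exp_mean <- rowMeans(role_matrix(table, "experimental"))
  names(exp_mean) <- table$features$feature_id
  keep_ids <- character(length(groups))
  meta <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    ints <- exp_mean[g$feature_ids]
    rep_id <- g$feature_ids[which.max(ints)]
    keep_ids[k] <- rep_id
    ann <- annotations[annotations$feature_id == rep_id, , drop = FALSE]
    grp_ann <- annotations[annotations$group_id == g$group_id, , drop = FALSE]
    meta[[k]] <- data.frame(
      feature_id = rep_id, group_id = g$group_id,
      role = ann$role[1],
      neutral_mass = grp_ann$neutral_mass[grp_ann$role == "parent"][1],
      n_members = length(g$feature_ids), stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta)
  keep <- table$features$feature_id %in% keep_ids
  out <- subset_features(table, keep, "redundant_in_group")
  out$features <- merge(out$features, meta, by = "feature_id", sort = FALSE)
  ## preserve matrix row order
  out$features <- out$features[match(rownames(out$intensities),
                                     out$features$feature_id), ]
  rownames(out$features) <- NULL
  out
}
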