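## Spectra are data.frames/matrices with columns mz, intensity.

bin_spectrum <- function(spectrum) {
  sp <- as.data.frame(spectrum)
  if (nrow(sp) == 0) stop("empty spectrum")
  names(sp)[1:2] <- c("mz", "intensity")
  bins <- round(sp$mz)
  tapply(sp$intensity, bins, sum)
}

#' Spectral similarity score (0-1000)
#'
#' Cosine (normalised dot-product) similarity between two spectra aligned
#' on unit (integer) m/z bins, scaled to the conventional 0-1000 "MS match"
#' range. The score is symmetric and invariant to rescaling either
#' spectrum's intensities.
#'
#' @param query,reference spectra: two-column matrix/data.frame of
#'   (m/z, intensity); both non-empty.
#' @return numeric score in \[0, 1000\].
#' @export
spectral_match_score <- function(query, reference) {
  q <- bin_spectrum(query)
  r <- bin_spectrum(reference)
  bins <- union(names(q), names(r))
  qv <- ifelse(bins %in% names(q), q[bins], 0)
  rv <- ifelse(bins %in% names(r), r[bins], 0)
  qv[is.na(qv)] <- 0
  rv[is.na(rv)] <- 0
  denom <- sqrt(sum(qv^2)) * sqrt(sum(rv^2))
  if (denom == 0) return(0)
  1000 * sum(qv * rv) / denom
}

#' GC-MS identification by retention index and spectral match
#'
#' Library candidates are first filtered to a retention-index window
#' (`|RI_query - RI_library| <= ri_window`), then scored with
#' [spectral_match_score()]; the highest-scoring candidate is returned as an
#' unambiguous identification (MSI level 1) only if its score strictly
#' exceeds `min_score`; otherwise the feature remains unknown (MSI level 4).
#'
#' @param ri query retention index.
#' @param spectrum query spectrum (m/z, intensity).
#' @param library list of entries, each a list with `name`, `ri` and
#'   `spectrum`; see [read_msp()].
#' @param ri_window retention-index window (default +/- 10).
#' @param min_score minimum spectral score, exclusive (default 800).
#' @return list `(name, ri, score, msi_level)` for a match, or `NULL` when
#'   no candidate qualifies.
#' @export
gcms_identify <- function(ri, spectrum, library, ri_window = 10,
                          min_score = 800) {
  stopifnot(length(library) >= 1)
  best <- NULL
  for (entry in library) {
    if (abs(ri - entry$ri) > ri_window) next
    s <- spectral_match_score(spectrum, entry$spectrum)
    if (is.null(best) || s > best$score) {
      best <- list(name = entry$name, ri = entry$ri, score = s, msi_level = 1L)
    }
  }
  if (is.null(best) || best$score <= min_score) return(NULL)
  best
}

#' Read / write MSP spectral libraries
#'
#' Minimal reader/writer for the NIST MSP text format used for GC-MS
#' spectral libraries: records with `NAME:`, `RI:` and `Num Peaks:` headers
#' followed by whitespace-separated m/z-intensity pairs, blank-line
#' separated.
#'
#' @param path file path.
#' @return `read_msp()`: list of entries (`name`, `ri`, `spectrum`);
#'   `write_msp()` invisibly returns `path`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  entries <- list()
  cur <- NULL
  peaks <- NULL
  flush <- function() {
    if (!is.null(cur) && length(peaks)) {
      vals <- as.numeric(unlist(strsplit(paste(peaks, collapse = " "),
                                         "[;,[:space:]]+")))
      vals <- vals[!is.na(vals)]
      cur$spectrum <<- data.frame(mz = vals[c(TRUE, FALSE)],
                                  intensity = vals[c(FALSE, TRUE)])
      entries[[length(entries) + 1L]] <<- cur
    }
    cur <<- NULL
    peaks <<- NULL
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) {
      flush()
    } else if (grepl("^(NAME|Name):", ln)) {
      flush()
      cur <- list(name = trimws(sub("^(NAME|Name):", "", ln)), ri = NA_real_)
    } else if (grepl("^(RI|Ri|Retention_index):", ln)) {
      cur$ri <- as.numeric(trimws(sub("^[A-Za-z_]+:", "", ln)))
    } else if (grepl("^(Num Peaks|NUM PEAKS):", ln, ignore.case = TRUE)) {
      peaks <- character()
    } else if (!is.null(peaks)) {
      peaks <- c(peaks, ln)
    }
  }
  flush()
  entries
}

#' @rdname read_msp
#' @param entries list of entries as returned by [read_msp()].
#' @export
write_msp <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in entries) {
    sp <- as.data.frame(entry$spectrum)
    writeLines(c(
      paste0("NAME: ", entry$name),
      paste0("RI: ", format(entry$ri, scientific = FALSE)),
      paste0("Num Peaks: ", nrow(sp)),
      paste(sp$mz, round(sp$intensity, 2), collapse = "; "),
      ""
    ), con)
  }
  invisible(path)
}
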