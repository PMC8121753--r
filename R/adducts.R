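## Mass constants (monoisotopic; CODATA/IUPAC values, Da).
PROTON_MASS <- 1.00727646688
## 13C - 12C isotopologue spacing used for +1/+2 annotation.
ISOTOPE_SPACING <- 1.00336

#' Electrospray adduct definitions
#'
#' Returns the adduct table shipped with the package (editable CSV at
#' `system.file("extdata", "adducts.csv", package = "groatlab")`): adduct
#' name, polarity, mass shift in Da relative to the neutral molecule M, and
#' charge. Shifts are computed from monoisotopic atomic masses including the
#' electron mass, so that for a singly charged ion `mz = M + shift`.
#'
#' @param polarity optional filter: `"ESI+"`/`"positive"` or
#'   `"ESI-"`/`"negative"`; `NULL` returns the full table.
#' @return data.frame with columns `name`, `polarity`, `shift_da`, `charge`.
#' @export
default_adducts <- function(polarity = NULL) {
  path <- system.file("extdata", "adducts.csv", package = "groatlab")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(polarity)) {
    pol <- switch(polarity,
                  "ESI+" = "positive", "positive" = "positive",
                  "ESI-" = "negative", "negative" = "negative",
                  stop("unknown polarity: ", polarity))
    tab <- tab[tab$polarity == pol, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

primary_ion_name <- function(polarity) {
  if (polarity %in% c("ESI+", "positive")) "[M+H]" else "[M-H]"
}

lookup_adduct <- function(adduct, adducts) {
  i <- match(adduct, adducts$name)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  adducts[i, ]
}

#' Neutral mass from an observed m/z and adduct assignment
#'
#' For a singly charged adduct, `M = mz * |charge| - shift`; the inverse
#' `mz_for_adduct()` returns the m/z at which the adduct of a neutral mass
#' is observed, so the two are exact round-trip inverses.
#'
#' @param mz observed m/z, Da.
#' @param adduct adduct name (must appear in `adducts`).
#' @param adducts adduct definition table, see [default_adducts()].
#' @return neutral monoisotopic mass, Da.
#' @export
neutral_mass <- function(mz, adduct, adducts = default_adducts()) {
  a <- lookup_adduct(adduct, adducts)
  if (abs(a$charge) != 1) stop("only singly charged adducts are supported")
  mz * abs(a$charge) - a$shift_da
}

#' @rdname neutral_mass
#' @param neutral neutral monoisotopic mass, Da.
#' @export
mz_for_adduct <- function(neutral, adduct, adducts = default_adducts()) {
  a <- lookup_adduct(adduct, adducts)
  if (abs(a$charge) != 1) stop("only singly charged adducts are supported")
  (neutral + a$shift_da) / abs(a$charge)
}

#' Match a neutral mass against a compound library at ppm tolerance
#'
#' Returns every library entry whose monoisotopic mass lies within `tol_ppm`
#' parts per million of the query (inclusive boundary:
#' `1e6 * |neutral - mass| / mass <= tol_ppm`), ordered by absolute ppm
#' error, ties broken by name.
#'
#' @param neutral query neutral mass, Da.
#' @param library data.frame with at least columns `name` and
#'   `monoisotopic_mass` (Da).
#' @param tol_ppm tolerance in ppm (> 0), default 5.
#' @return data.frame: library columns plus `ppm_error` (signed), possibly
#'   0 rows.
#' @export
ppm_match_library <- function(neutral, library, tol_ppm = 5) {
  stopifnot(tol_ppm > 0, is.data.frame(library))
  if (!all(c("name", "monoisotopic_mass") %in% names(library))) {
    stop("library needs columns name, monoisotopic_mass")
  }
  ppm <- 1e6 * (neutral - library$monoisotopic_mass) / library$monoisotopic_mass
  hit <- abs(ppm) <= tol_ppm
  out <- library[hit, , drop = FALSE]
  out$ppm_error <- ppm[hit]
  out <- out[order(abs(out$ppm_error), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
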