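#' Field-trial study design
#'
#' Describes the split-plot nitrogen-response design the generators emulate:
#' a set of trials, each with applied-N doses on main plots, varieties on
#' sub-plots and a fixed number of replicate blocks, together with the
#' LC-MS injection scheme (pooled-QA conditioning/lead-in/periodic/terminal
#' injections and blank extracts).
#'
#' Defaults reproduce the three-trial layout of the study the package
#' models: one 2014 trial with five applied-N levels (0-200 kg N/ha) and two
#' trials with six levels (up to 250 and 280 kg N/ha), four winter oat
#' varieties (one dwarf), three replicates.
#'
#' @param trials character vector of trial labels.
#' @param varieties character vector of variety names.
#' @param n_levels named list, one numeric vector of applied-N doses
#'   (kg N/ha) per trial; every trial needs >= 2 levels including a 0-dose
#'   control.
#' @param replicates replicate blocks per variety x N cell (>= 2).
#' @param qa_schedule list with counts `conditioning`, `lead_in`, `every`
#'   (one periodic QA after this many experimental injections) and
#'   `terminal`.
#' @param blank_count blank extract injections per trial (split between the
#'   start and end of the run).
#' @return A `study_design` list.
#' @export
study_design <- function(trials = c("IB14", "AD14", "AD15"),
                         varieties = c("Balado", "Gerald", "Mascani", "Tardis"),
                         n_levels = list(
                           IB14 = c(0, 50, 100, 150, 200),
                           AD14 = c(0, 50, 100, 150, 200, 250),
                           AD15 = c(0, 60, 120, 180, 230, 280)
                         ),
                         replicates = 3,
                         qa_schedule = list(conditioning = 8, lead_in = 3,
                                            every = 8, terminal = 3),
                         blank_count = 2) {
  stopifnot(length(trials) >= 1, length(varieties) >= 1)
  if (!all(trials %in% names(n_levels))) {
    stop("`n_levels` must carry one dose vector per trial")
  }
  n_levels <- n_levels[trials]
  for (tr in trials) {
    doses <- n_levels[[tr]]
    if (length(doses) < 2 || !any(doses == 0)) {
      stop("every trial needs >= 2 N levels including a 0-dose control")
    }
    if (any(doses < 0)) stop("doses must be >= 0")
  }
  if (replicates < 2) stop("replicates must be >= 2")
  if (blank_count < 0) stop("blank_count must be >= 0")
  structure(
    list(trials = trials, varieties = varieties, n_levels = n_levels,
         replicates = replicates, qa_schedule = qa_schedule,
         blank_count = blank_count),
    class = "study_design"
  )
}

#' Ground-truth compound for the synthetic LC-MS/GC-MS generators
#'
#' @param name compound name (unique within a generator call).
#' @param neutral_mass monoisotopic neutral mass, Da (> 0).
#' @param rt retention time, minutes.
#' @param adduct_family data.frame with columns `adduct` (name matching the
#'   adduct table) and `rel_ab` (relative abundance in (0, 1]).
#' @param parent_adduct which family member is the parent ion form (exactly
#'   one; typically the protonated/deprotonated molecule).
#' @param isotope_abundances relative abundances of the +1/+2 (etc.)
#'   isotopologues of the parent ion, each in (0, 1].
#' @param base_intensity mean intensity at 0 kg N/ha for a variety with
#'   effect factor 1 (arbitrary units).
#' @param n_effect signed slope of log intensity per kg applied N/ha
#'   (monotone dose response on the log scale).
#' @param variety_effects named numeric vector of multiplicative variety
#'   factors.
#' @param technical_cv coefficient of variation of the multiplicative
#'   log-normal technical noise (fraction, e.g. 0.1).
#' @param biological_cv coefficient of variation of the between-plot
#'   biological variation, shared by every ion form of the compound within
#'   a sample (fraction; default 0.3, typical of replicate field plots).
#'   QA injections, being a physical pool, carry technical noise only.
#' @param ri optional GC retention index (GC-MS generator).
#' @param spectrum optional reference spectrum: matrix/data.frame with
#'   columns `mz`, `intensity` (GC-MS generator).
#' @param is_internal_standard logical; GC-MS internal standard flag.
#' @return A `compound_truth` list.
#' @export
compound_truth <- function(name, neutral_mass, rt,
                           adduct_family, parent_adduct,
                           isotope_abundances = c(0.25, 0.05),
                           base_intensity = 1e5,
                           n_effect = 0,
                           variety_effects = c(Balado = 1, Gerald = 1,
                                               Mascani = 1, Tardis = 1),
                           technical_cv = 0.1,
                           biological_cv = 0.3,
                           ri = NULL, spectrum = NULL,
                           is_internal_standard = FALSE) {
  stopifnot(neutral_mass > 0, rt >= 0, technical_cv >= 0,
            biological_cv >= 0, base_intensity > 0)
  adduct_family <- as.data.frame(adduct_family)
  stopifnot(all(c("adduct", "rel_ab") %in% names(adduct_family)))
  if (any(adduct_family$rel_ab <= 0 | adduct_family$rel_ab > 1)) {
    stop("relative abundances must lie in (0, 1]")
  }
  if (sum(adduct_family$adduct == parent_adduct) != 1) {
    stop("exactly one adduct family member must be the parent ion form")
  }
  if (length(isotope_abundances) &&
      any(isotope_abundances <= 0 | isotope_abundances > 1)) {
    stop("isotope abundances must lie in (0, 1]")
  }
  structure(
    list(name = name, neutral_mass = neutral_mass, rt = rt,
         adduct_family = adduct_family, parent_adduct = parent_adduct,
         isotope_abundances = isotope_abundances,
         base_intensity = base_intensity, n_effect = n_effect,
         variety_effects = variety_effects, technical_cv = technical_cv,
         biological_cv = biological_cv,
         ri = ri, spectrum = spectrum,
         is_internal_standard = is_internal_standard),
    class = "compound_truth"
  )
}

#' Randomised but reproducible compound panels
#'
#' `example_compounds()` draws a panel of LC-MS compound truths with full
#' adduct families; retention times sit on a jittered grid with at least
#' ~0.3 min separation, reflecting that deconvolved features of different
#' compounds are chromatographically resolved. `example_gcms_compounds()`
#' draws a GC-MS panel (one quantifier feature per compound) with retention
#' indices and reference spectra, including a ribitol-like internal
#' standard.
#'
#' @param n number of compounds.
#' @param polarity `"ESI+"` or `"ESI-"`; determines the adduct pool.
#' @param varieties variety names for the per-variety effect factors.
#' @param technical_cv technical noise CV applied to every compound.
#' @param biological_cv between-plot biological CV applied to every
#'   compound.
#' @param prop_null fraction of compounds with no nitrogen effect.
#' @param seed RNG seed.
#' @return list of `compound_truth`.
#' @export
example_compounds <- function(n = 50, polarity = c("ESI-", "ESI+"),
                              varieties = c("Balado", "Gerald", "Mascani", "Tardis"),
                              technical_cv = 0.1, biological_cv = 0.3,
                              prop_null = 0.2, seed = 1) {
  polarity <- match.arg(polarity)
  adducts <- default_adducts(polarity)
  primary <- if (polarity == "ESI+") "[M+H]" else "[M-H]"
  secondary <- setdiff(adducts$name, primary)
  set.seed(seed)
  rts <- seq(2, 34, length.out = n) + stats::runif(n, -0.05, 0.05)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    n_extra <- sample(1:min(3, length(secondary)), 1)
    fam <- data.frame(
      adduct = c(primary, sample(secondary, n_extra)),
      rel_ab = c(1, stats::runif(n_extra, 0.1, 0.6))
    )
    eff <- if (stats::runif(1) < prop_null) 0 else {
      sample(c(-1, 1), 1) * stats::runif(1, 0.002, 0.008)
    }
    vf <- exp(stats::rnorm(length(varieties), 0, 0.25))
    names(vf) <- varieties
    out[[i]] <- compound_truth(
      name = sprintf("Cmpd%03d", i),
      neutral_mass = round(stats::runif(1, 150, 800), 4),
      rt = rts[i],
      adduct_family = fam, parent_adduct = primary,
      isotope_abundances = c(0.25, 0.05),
      base_intensity = 10^stats::runif(1, 4.5, 6.5),
      n_effect = eff, variety_effects = vf,
      technical_cv = technical_cv, biological_cv = biological_cv
    )
  }
  out
}

#' @rdname example_compounds
#' @export
example_gcms_compounds <- function(n = 62,
                                   varieties = c("Balado", "Gerald", "Mascani", "Tardis"),
                                   technical_cv = 0.1, biological_cv = 0.3,
                                   prop_null = 0.2, seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  ris <- seq(1100, 3500, length.out = n) + stats::runif(n, -5, 5)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    npk <- sample(8:15, 1)
    spec <- data.frame(
      mz = sort(sample(70:600, npk)),
      intensity = round(stats::runif(npk, 50, 1000))
    )
    spec$intensity <- spec$intensity / max(spec$intensity) * 1000
    eff <- if (stats::runif(1) < prop_null) 0 else {
      sample(c(-1, 1), 1) * stats::runif(1, 0.002, 0.008)
    }
    vf <- exp(stats::rnorm(length(varieties), 0, 0.25))
    names(vf) <- varieties
    is_std <- i == 1
    out[[i]] <- compound_truth(
      name = if (is_std) "ribitol (IS)" else sprintf("GC%03d", i),
      neutral_mass = round(stats::runif(1, 100, 600), 4),
      rt = ris[i] / 100,
      adduct_family = data.frame(adduct = "[M]", rel_ab = 1),
      parent_adduct = "[M]",
      isotope_abundances = numeric(),
      base_intensity = if (is_std) 1e5 else 10^stats::runif(1, 4, 6),
      n_effect = if (is_std) 0 else eff,
      variety_effects = if (is_std) stats::setNames(rep(1, length(varieties)), varieties) else vf,
      technical_cv = technical_cv,
      biological_cv = if (is_std) 0 else biological_cv,
      ri = ris[i], spectrum = spec,
      is_internal_standard = is_std
    )
  }
  out
}
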