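#' Default per-variety nitrogen-response parameters
#'
#' Linear-plus-exponential yield curves y(N) = a + b r^N + c N (t/ha) with
#' economic optima in the 150-210 kg N/ha range typical of UK winter oats,
#' together with thousand-grain-weight means (g), grains-per-panicle scale
#' and a lodging propensity (0 = lodging resistant, as for a dwarf variety).
#'
#' @return named list, one parameter list per variety.
#' @export
default_agronomy_params <- function() {
  list(
    Balado  = list(a = 10.8, b = -6.2, r = 0.988, c = -0.0038,
                   tgw_mean = 43, gpp_base = 50, lodging_propensity = 0),
    Gerald  = list(a = 10.5, b = -6.0, r = 0.9875, c = -0.0040,
                   tgw_mean = 36, gpp_base = 44, lodging_propensity = 1.5),
    Mascani = list(a = 11.0, b = -6.5, r = 0.990, c = -0.0030,
                   tgw_mean = 45, gpp_base = 35, lodging_propensity = 0.4),
    Tardis  = list(a = 10.9, b = -6.2, r = 0.988, c = -0.0038,
                   tgw_mean = 42, gpp_base = 44, lodging_propensity = 1.8)
  )
}

#' Generate synthetic field-trial plot records
#'
#' Per-plot grain yield follows the linear-plus-exponential dose-response
#' y(N) = a + b r^N + c N scaled by a per-trial productivity factor, with
#' additive Gaussian noise. Thousand grain weight, panicle counts and
#' lodging/leaning percentages are generated with the study's qualitative
#' structure: lodging increases with applied N according to each variety's
#' lodging propensity (a propensity of 0 gives no lodging at any dose).
#'
#' @param design a [study_design()].
#' @param params named list of per-variety parameters, see
#'   [default_agronomy_params()]. Each `r` must lie in (0, 1).
#' @param noise_sd yield noise standard deviation, t/ha (>= 0).
#' @param trial_factors named multiplicative productivity factor per trial
#'   (season/site effect).
#' @param seed RNG seed.
#' @return data.frame of plot records: `trial`, `block`, `variety`,
#'   `applied_n` (kg N/ha), `yield_t_ha`, `tgw_g`, `panicles_m2`,
#'   `pct_lodged`, `pct_leaning`.
#' @export
generate_agronomy_trials <- function(design, params = default_agronomy_params(),
                                     noise_sd = 0.25,
                                     trial_factors = c(IB14 = 1, AD14 = 0.75,
                                                       AD15 = 0.45),
                                     seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (v in design$varieties) {
    p <- params[[v]]
    if (is.null(p)) stop("missing parameters for variety ", v)
    if (p$r <= 0 || p$r >= 1) stop("r must lie in (0, 1) for variety ", v)
  }
  set.seed(seed)
  rows <- list()
  for (tr in design$trials) {
    tf <- unname(trial_factors[tr])
    if (length(tf) != 1 || is.na(tf)) tf <- 1
    for (blk in seq_len(design$replicates)) {
      for (N in design$n_levels[[tr]]) {
        for (v in design$varieties) {
          p <- params[[v]]
          mu <- tf * (p$a + p$b * p$r^N + p$c * N)
          yield <- max(0, mu + stats::rnorm(1, 0, noise_sd))
          tgw <- max(10, p$tgw_mean + stats::rnorm(1, 0, noise_sd * 6))
          grains_m2 <- yield * 100 * 0.85 / tgw * 1000
          gpp <- p$gpp_base * (1 + 0.001 * N)
          panicles <- grains_m2 / gpp
          lodged <- if (p$lodging_propensity > 0) {
            min(100, p$lodging_propensity * max(0, N - 100) / 10 *
                  exp(stats::rnorm(1, 0, 0.2)))
          } else 0
          leaning <- min(100 - lodged, lodged / 2)
          rows[[length(rows) + 1L]] <- data.frame(
            trial = tr, block = blk, variety = v, applied_n = N,
            yield_t_ha = yield, tgw_g = tgw, panicles_m2 = panicles,
            pct_lodged = lodged, pct_leaning = leaning,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
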