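#' Simulate a time-to-event cohort under the validation model
#'
#' Generates individual data under the generative model in [sim_config()]:
#' the latent hazard-rate derivative is
#' \deqn{\upsilon_i(t) = \gamma_0(t) + \gamma(t) x_i(t) + q_u(t)(u_i - \bar u)
#'       + q_z(t) z_i + \epsilon_{i\upsilon}(t),}
#' the exposure trajectory is
#' \deqn{x_i(t) = \beta_0(t) + \beta_G(t) G_i + c_u(t)(u_i - \bar u)
#'       + c_z(t) z_i + \epsilon_{ix}(t),}
#' and the hazard rate \eqn{\lambda_i(t) = \int_0^t \upsilon_i} is
#' discretized on yearly bins (mid-bin evaluation, floored at zero).  Onset
#' follows a negative-binomial mechanism: an individual gamma frailty
#' multiplies the yearly Poisson intensity and the first bin with a count of
#' at least one is the event.  Recorded event ages emulate registry ages
#' (year of event minus year of birth), an unbiased half-year rounding of the
#' continuous onset age.  The observed exposure is the latent trajectory at a
#' random assessment age plus measurement noise.
#'
#' @param config A [sim_config()].
#' @return A \code{data.frame} of class \code{"chronomr_cohort"} with columns
#'   \code{id}, \code{sex}, \code{instrument}, \code{exposure_raw},
#'   \code{age_at_assessment}, \code{event_age} (NA when censored),
#'   \code{censor_age}, \code{event_free_at_assessment} and the observed
#'   covariate \code{z}.  The fraction of yearly hazard cells clipped at zero
#'   is attached as attribute \code{"clip_fraction"}.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  sim_cohort_impl(config)
}

# core generator; assumes RNG state already set (so that calibration and the
# multi-SNP variant can reuse it under their own seeding discipline)
sim_cohort_impl <- function(config, snp_profiles = NULL, snp_freqs = NULL) {
  n <- config$n_individuals
  K <- as.integer(config$max_age)
  betaf <- sim_beta_fun(config)
  gammaf <- sim_gamma_fun(config)

  multisnp <- !is.null(snp_profiles)
  if (multisnp) {
    nsnp <- length(snp_profiles)
    if (length(snp_freqs) != nsnp) {
      stop("snp_profiles and snp_freqs must have the same length")
    }
    G <- vapply(snp_freqs, function(f) stats::rbinom(n, 2L, f), numeric(n))
    colnames(G) <- paste0("snp", seq_len(nsnp))
    pgs <- rowSums(G)
  } else {
    g <- stats::rbinom(n, 1L, config$instrument_freq)
  }

  sex <- stats::rbinom(n, 1L, 0.5)
  u <- stats::rgamma(n, shape = config$confounder_shape,
                     scale = config$confounder_scale)
  uc <- u - config$confounder_shape * config$confounder_scale
  z <- stats::rnorm(n)
  frail <- stats::rgamma(n, shape = config$frailty_dispersion,
                         rate = config$frailty_dispersion)

  # genetic contribution to the exposure at age t, centered so E[x(t)] = 0
  gen_part <- function(t) {
    if (multisnp) {
      contrib <- numeric(n)
      for (j in seq_along(snp_profiles)) {
        bj <- snp_profiles[[j]](t)
        contrib <- contrib + bj * (G[, j] - 2 * snp_freqs[j])
      }
      contrib
    } else {
      betaf(t) * (g - config$instrument_freq)
    }
  }

  # latent exposure at age t with fresh trajectory noise
  latent_x <- function(t) {
    gen_part(t) +
      config$confounder_exposure_profile(t) * uc +
      config$covariate_exposure_profile(t) * z +
      stats::rnorm(n, sd = config$noise_sd_trajectory)
  }

  # walk the yearly bins (j-1, j], hazard rate evaluated at mid-bin; one
  # extra bin past max_age so that the registry rounding of the last year
  # is two sided (recorded ages > max_age are treated as censored below)
  cum_ups <- numeric(n)           # integral of upsilon up to previous midpoint
  onset_bin <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  clipped <- 0
  cells <- 0
  for (j in seq_len(K + 1L)) {
    tm <- j - 0.5
    ups <- config$baseline_hazard * (tm / config$max_age)^4 +
      gammaf(tm) * latent_x(tm) +
      config$confounder_outcome_profile(tm) * uc +
      config$covariate_outcome_profile(tm) * z
    if (config$noise_sd_outcome > 0) {
      ups <- ups + stats::rnorm(n, sd = config$noise_sd_outcome)
    }
    lam <- config$hazard_offset + cum_ups + 0.5 * ups  # hazard rate at mid-bin
    cum_ups <- cum_ups + ups
    if (!any(alive)) next
    cells <- cells + sum(alive)
    clipped <- clipped + sum(lam[alive] < 0)
    h <- pmax(lam[alive], 0)
    if (any(!is.finite(h))) {
      stop("non-finite hazard encountered; check the configured profiles")
    }
    fired <- stats::runif(sum(alive)) < -expm1(-frail[alive] * h)
    idx <- which(alive)[fired]
    onset_bin[idx] <- j
    alive[idx] <- FALSE
  }
  clip_frac <- if (cells > 0) clipped / cells else 0
  if (clip_frac > 0.10) {
    warning(sprintf(
      "%.1f%% of yearly hazard cells were clipped at zero; the configuration is implausible",
      100 * clip_frac))
  }

  # registry-age convention: year(event) - year(birth)
  has_event <- !is.na(onset_bin)
  event_age <- rep(NA_real_, n)
  event_age[has_event] <- onset_bin[has_event] - 1L +
    stats::rbinom(sum(has_event), 1L, 0.5)
  event_age[!is.na(event_age) & event_age > K] <- NA_real_

  assess_age <- sample(seq(config$assess_age_range[1],
                           config$assess_age_range[2]), n, replace = TRUE)
  # observed exposure, vectorized over the few distinct assessment ages
  exposure <- numeric(n)
  for (ta in unique(assess_age)) {
    sel <- assess_age == ta
    xg <- if (multisnp) {
      contrib <- numeric(sum(sel))
      for (jj in seq_along(snp_profiles)) {
        contrib <- contrib +
          snp_profiles[[jj]](ta) * (G[sel, jj] - 2 * snp_freqs[jj])
      }
      contrib
    } else {
      betaf(ta) * (g[sel] - config$instrument_freq)
    }
    exposure[sel] <- xg +
      config$confounder_exposure_profile(ta) * uc[sel] +
      config$covariate_exposure_profile(ta) * z[sel] +
      stats::rnorm(sum(sel), sd = config$noise_sd_trajectory) +
      stats::rnorm(sum(sel), sd = config$noise_sd_exposure)
  }

  out <- data.frame(
    id = seq_len(n),
    sex = sex,
    instrument = if (multisnp) pgs else g,
    exposure_raw = exposure,
    age_at_assessment = assess_age,
    event_age = event_age,
    censor_age = rep(as.numeric(K), n),
    event_free_at_assessment =
      is.na(event_age) | event_age > assess_age,
    z = z
  )
  if (multisnp) out <- cbind(out, as.data.frame(G), pgs = pgs)
  attr(out, "clip_fraction") <- clip_frac
  class(out) <- c("chronomr_cohort", "data.frame")
  out
}

#' Calibrate the baseline hazard to a target prevalence
#'
#' Adjusts \code{baseline_hazard} by bisection so that the realized disease
#' prevalence by \code{max_age} in a calibration cohort of \code{n_calib}
#' individuals matches \code{target_prevalence}.  Common random numbers (the
#' configured seed) are used at every bisection step, making the realized
#' prevalence monotone in the baseline and the search deterministic.
#'
#' @param config A [sim_config()].
#' @param target_prevalence Target proportion with an event by
#'   \code{max_age}, in (0, 1).
#' @param n_calib Calibration cohort size.
#' @param tol Tolerance on the realized prevalence (absolute proportion).
#' @param upper Upper bracket for the baseline hazard scale.
#' @param max_iter Bisection iteration cap.
#' @return The configuration with \code{baseline_hazard} replaced.
#' @export
calibrate_baseline <- function(config, target_prevalence, n_calib = 100000L,
                               tol = 0.005, upper = 0.02, max_iter = 40L) {
  validate_sim_config(config)
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    stop("target_prevalence must lie in (0, 1)")
  }
  calib_cfg <- config
  calib_cfg$n_individuals <- as.integer(n_calib)
  prev_at <- function(g0) {
    cc <- calib_cfg
    cc$baseline_hazard <- g0
    coh <- suppressWarnings(simulate_cohort(cc))
    mean(!is.na(coh$event_age))
  }
  lo <- 0
  hi <- upper
  p_lo <- prev_at(lo)
  p_hi <- prev_at(hi)
  if (p_lo > target_prevalence + tol) {
    stop(sprintf(
      "target prevalence %.3g unreachable: prevalence is %.3g at zero baseline",
      target_prevalence, p_lo))
  }
  if (p_hi < target_prevalence - tol) {
    stop("bisection bracket failure: raise `upper`")
  }
  mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p_mid <- prev_at(mid)
    if (abs(p_mid - target_prevalence) <= tol) break
    if (p_mid < target_prevalence) lo <- mid else hi <- mid
  }
  config$baseline_hazard <- mid
  config
}

#' Simulate a cohort driven by several SNPs with distinct time profiles
#'
#' Each SNP is an independent Binomial(2, freq) dosage with its own
#' time-dependent effect on the exposure; the exposure receives the sum of
#' the per-SNP contributions (each centered at its dosage mean).  An
#' unweighted polygenic score column \code{pgs} (the plain genotype sum) is
#' appended and also used as the \code{instrument} column, so the standard
#' pipeline treats the score as a single composite instrument.
#'
#' @param config A [sim_config()].
#' @param snp_profiles List of at least two functions of age, the per-SNP
#'   time-varying effects on the exposure (exposure SD per allele).
#' @param snp_freqs Allele frequencies, one per profile.
#' @return A cohort as in [simulate_cohort()], with additional per-SNP dosage
#'   columns \code{snp1, snp2, ...} and the \code{pgs} column.
#' @export
simulate_multisnp_cohort <- function(config, snp_profiles, snp_freqs) {
  validate_sim_config(config)
  if (length(snp_profiles) < 2L) stop("need at least two SNP profiles")
  if (length(snp_freqs) != length(snp_profiles)) {
    stop("snp_freqs must match snp_profiles in length")
  }
  set.seed(config$seed)
  sim_cohort_impl(config, snp_profiles = snp_profiles, snp_freqs = snp_freqs)
}
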