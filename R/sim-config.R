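#' Simulation configuration for synthetic validation cohorts
#'
#' Bundles the generative model used to validate time-resolved MR: a
#' dichotomous genetic instrument whose effect on the exposure follows the
#' quartic \eqn{\beta_G(t) = a + b t + c t^4}, a momentaneous exposure effect
#' on the latent hazard derivative \eqn{\gamma(t) = c_\gamma t^4}, a
#' gamma-distributed confounder and a normal covariate with time-dependent
#' coefficients on both exposure and outcome, and a negative-binomial onset
#' mechanism (gamma frailty mixed over yearly Poisson counts).
#'
#' The exposure is generated on the standardized (SD) scale: the intercept
#' profile is set to \eqn{-\mathrm{freq}\cdot\beta_G(t)} so that the exposure
#' has mean zero at every age, and the default noise levels give total
#' variance close to one.  Latent trajectory noise (drawn independently every
#' year, feeding the hazard) is separated from assessment-time measurement
#' noise (added once, when the exposure is observed).
#'
#' @param n_individuals Number of individuals to simulate.
#' @param max_age Final age of follow-up in years; individuals without an
#'   event are censored here.
#' @param instrument_freq Carrier frequency of the dichotomous instrument,
#'   in (0, 1).
#' @param beta_g_coeffs Numeric triple \code{(a, b, c)} of the quartic
#'   instrument-effect model \eqn{\beta_G(t) = a + b t + c t^4}
#'   (exposure SD per instrument unit).
#' @param gamma_scale Coefficient \eqn{c_\gamma} of the power-law momentaneous
#'   effect \eqn{\gamma(t) = c_\gamma t^4} (hazard-rate change per year, per
#'   exposure SD).  Ignored when \code{gamma_profile} is supplied.
#' @param gamma_profile Optional function of age returning \eqn{\gamma(t)};
#'   overrides the power law.
#' @param baseline_hazard Scale \eqn{g_0} of the baseline hazard derivative
#'   \eqn{\gamma_0(t) = g_0 (t/\mathrm{max\_age})^4} (per year^2); calibrated
#'   to a target prevalence by [calibrate_baseline()].
#' @param hazard_offset Constant background hazard rate \eqn{C_0} (per
#'   year), the additive floor that keeps the young-age hazard positive
#'   before the age-rising component dominates.
#' @param confounder_shape,confounder_scale Gamma-distribution parameters of
#'   the unobserved confounder \eqn{u}.
#' @param confounder_exposure_profile,confounder_outcome_profile Functions of
#'   age giving the time-dependent coefficient of the centered confounder
#'   \eqn{(u - \mathrm{mean})} on the exposure and on the hazard derivative.
#' @param covariate_exposure_profile,covariate_outcome_profile Functions of
#'   age giving the coefficient of the observed standard-normal covariate
#'   \code{z} on exposure and hazard derivative.
#' @param noise_sd_trajectory SD of the iid yearly latent exposure-trajectory
#'   noise (enters the hazard).
#' @param noise_sd_exposure SD of the assessment-time measurement noise
#'   (enters the observed exposure only).
#' @param noise_sd_outcome SD of an optional iid yearly noise on the hazard
#'   derivative.
#' @param frailty_dispersion Shape \eqn{\theta} of the mean-one gamma frailty;
#'   the yearly event counts are then negative binomial.  Larger values
#'   approach a pure Poisson mechanism.
#' @param assess_age_range Integer range of assessment ages (uniform draw).
#' @param seed Integer seed; fixing it reproduces the cohort bit for bit.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @seealso [simulate_cohort()], [calibrate_baseline()],
#'   [true_cumulative_effect()]
#' @export
sim_config <- function(n_individuals = 100000L,
                       max_age = 80,
                       instrument_freq = 0.5,
                       beta_g_coeffs = c(a = 0.3, b = -9e-4, c = -4e-9),
                       gamma_scale = 4.5e-11,
                       gamma_profile = NULL,
                       baseline_hazard = 7.6e-4,
                       hazard_offset = 2e-4,
                       confounder_shape = 2,
                       confounder_scale = 1,
                       confounder_exposure_profile = function(t) 0.1 - 5e-4 * t,
                       confounder_outcome_profile = function(t) 2e-4 * (t / 80)^4,
                       covariate_exposure_profile = function(t) 0.1 + 5e-4 * t,
                       covariate_outcome_profile = function(t) 1e-4 * (t / 80)^4,
                       noise_sd_trajectory = 0.3,
                       noise_sd_exposure = 0.9,
                       noise_sd_outcome = 0,
                       frailty_dispersion = 20,
                       assess_age_range = c(20L, 80L),
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    max_age = max_age,
    instrument_freq = instrument_freq,
    beta_g_coeffs = unname(as.numeric(beta_g_coeffs)),
    gamma_scale = gamma_scale,
    gamma_profile = gamma_profile,
    baseline_hazard = baseline_hazard,
    hazard_offset = hazard_offset,
    confounder_shape = confounder_shape,
    confounder_scale = confounder_scale,
    confounder_exposure_profile = confounder_exposure_profile,
    confounder_outcome_profile = confounder_outcome_profile,
    covariate_exposure_profile = covariate_exposure_profile,
    covariate_outcome_profile = covariate_outcome_profile,
    noise_sd_trajectory = noise_sd_trajectory,
    noise_sd_exposure = noise_sd_exposure,
    noise_sd_outcome = noise_sd_outcome,
    frailty_dispersion = frailty_dispersion,
    assess_age_range = as.integer(assess_age_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_individuals < 1L) stop("n_individuals must be positive")
  if (!(cfg$instrument_freq > 0 && cfg$instrument_freq < 1)) {
    stop("instrument_freq must lie in (0, 1)")
  }
  if (cfg$max_age <= 0) stop("max_age must be positive")
  if (length(cfg$beta_g_coeffs) != 3L) {
    stop("beta_g_coeffs must be a triple (a, b, c)")
  }
  if (cfg$baseline_hazard < 0) stop("baseline_hazard must be non-negative")
  if (cfg$hazard_offset < 0) stop("hazard_offset must be non-negative")
  if (cfg$frailty_dispersion <= 0) stop("frailty_dispersion must be positive")
  for (p in c("confounder_exposure_profile", "confounder_outcome_profile",
              "covariate_exposure_profile", "covariate_outcome_profile")) {
    if (!is.function(cfg[[p]])) stop(sprintf("%s must be a function of age", p))
  }
  if (!is.null(cfg$gamma_profile) && !is.function(cfg$gamma_profile)) {
    stop("gamma_profile must be NULL or a function of age")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d individuals, follow-up to age %g\n",
              x$n_individuals, x$max_age))
  cat(sprintf("  instrument: Bernoulli(%.3g); betaG(t) = %.3g + %.3g t + %.3g t^4\n",
              x$instrument_freq, x$beta_g_coeffs[1], x$beta_g_coeffs[2],
              x$beta_g_coeffs[3]))
  if (is.null(x$gamma_profile)) {
    cat(sprintf("  gamma(t) = %.3g * t^4\n", x$gamma_scale))
  } else {
    cat("  gamma(t): user profile\n")
  }
  cat(sprintf("  baseline_hazard g0 = %.4g, frailty dispersion = %g, seed = %d\n",
              x$baseline_hazard, x$frailty_dispersion, x$seed))
  invisible(x)
}

# gamma(t) used by the generator and by the closed-form truth
sim_gamma_fun <- function(cfg) {
  if (!is.null(cfg$gamma_profile)) cfg$gamma_profile
  else function(t) cfg$gamma_scale * t^4
}

# beta_G(t) of the generative quartic
sim_beta_fun <- function(cfg) {
  cf <- cfg$beta_g_coeffs
  function(t) cf[1] + cf[2] * t + cf[3] * t^4
}

#' True cumulative (life-course) effect of the generative model
#'
#' Returns \eqn{\Gamma(T) = \int_0^T \gamma(t)\,dt}, the hazard-rate
#' difference at age \code{T} from sustaining a one-SD-higher exposure since
#' conception.  For the default power law \eqn{\gamma(t) = c_\gamma t^4} this
#' is the closed form \eqn{c_\gamma T^5 / 5}; for a user-supplied
#' \code{gamma_profile} the integral is evaluated by adaptive quadrature.
#'
#' @param config A [sim_config()].
#' @param T Evaluation age(s) in years, within \code{[0, max_age]}.
#' @return Hazard-rate difference per year (vectorized over \code{T}).
#' @export
true_cumulative_effect <- function(config, T) {
  validate_sim_config(config)
  if (any(T < 0 | T > config$max_age)) {
    stop("T must lie in [0, max_age]")
  }
  if (is.null(config$gamma_profile)) {
    return(config$gamma_scale * T^5 / 5)
  }
  g <- config$gamma_profile
  vapply(T, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(g, 0, ti, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Preset simulation scenarios
#'
#' Named configurations for the validation studies: \code{"main"} is the
#' primary scenario (15\% prevalence by age 80, quartic instrument effect,
#' \eqn{\gamma \propto t^4}); \code{"low-prevalence"} and
#' \code{"high-prevalence"} are the 3\% and 30\% robustness variants;
#' \code{"multisnp"} returns the main configuration together with three
#' diverse per-SNP time-effect profiles for [simulate_multisnp_cohort()].
#'
#' The prevalence variants rescale the whole latent hazard process (baseline
#' scale, constant offset, exposure effect and the confounder/covariate
#' outcome profiles) by \code{target/0.15}, keeping the relative effect
#' structure of the main scenario, and still expect a final
#' [calibrate_baseline()] to the target.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return For \code{"multisnp"} a list with elements \code{config},
#'   \code{target_prevalence}, \code{snp_profiles} and \code{snp_freqs};
#'   otherwise a list with elements \code{config} and
#'   \code{target_prevalence}.
#' @export
preset_config <- function(name = c("main", "low-prevalence", "high-prevalence",
                                   "multisnp"), ...) {
  name <- match.arg(name)
  cfg <- sim_config(...)
  target <- switch(name,
    "main" = 0.15, "multisnp" = 0.15,
    "low-prevalence" = 0.03, "high-prevalence" = 0.30)
  rho <- target / 0.15
  if (rho != 1) cfg <- scale_hazard_process(cfg, rho)
  if (name == "multisnp") {
    list(
      config = cfg,
      target_prevalence = target,
      snp_profiles = list(
        function(t) rep(0.15, length(t)),
        function(t) 0.25 - 2e-3 * t,
        function(t) 0.04 + 1.5e-3 * t
      ),
      snp_freqs = c(0.3, 0.5, 0.2)
    )
  } else {
    list(config = cfg, target_prevalence = target)
  }
}

# multiply every component of the latent hazard derivative by rho
scale_hazard_process <- function(cfg, rho) {
  cfg$gamma_scale <- cfg$gamma_scale * rho
  cfg$baseline_hazard <- cfg$baseline_hazard * rho
  cfg$hazard_offset <- cfg$hazard_offset * rho
  if (!is.null(cfg$gamma_profile)) {
    g_old <- cfg$gamma_profile
    cfg$gamma_profile <- function(t) rho * g_old(t)
  }
  cu <- cfg$confounder_outcome_profile
  cz <- cfg$covariate_outcome_profile
  cfg$confounder_outcome_profile <- function(t) rho * cu(t)
  cfg$covariate_outcome_profile <- function(t) rho * cz(t)
  cfg
}
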