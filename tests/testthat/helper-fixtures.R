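# shared fixtures, built in code at test time

zero_profile <- function(t) 0 * t

# small cohort with no confounding/noise pathways beyond what is requested
quiet_config <- function(n = 5000L, seed = 42L, beta = c(0.3, 0, 0), ...) {
  args <- list(
    n_individuals = n, seed = seed, beta_g_coeffs = beta,
    confounder_exposure_profile = zero_profile,
    confounder_outcome_profile = zero_profile,
    covariate_exposure_profile = zero_profile,
    covariate_outcome_profile = zero_profile,
    noise_sd_trajectory = 0, noise_sd_exposure = 0
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# hand-held cohort table for Aalen fixtures
tiny_cohort <- function(event_age, censor_age, ...) {
  n <- length(censor_age)
  cols <- list(...)
  df <- data.frame(id = seq_len(n), event_age = event_age,
                   censor_age = censor_age)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  df
}

# yearly-increments table from raw vectors
make_increments <- function(H, sigma2 = rep(0, length(H)),
                            n_events = rep(1L, length(H))) {
  structure(
    data.frame(year = seq_along(H), H_hat = H, sigma2 = sigma2,
               n_events = n_events),
    class = c("yearly_increments", "data.frame"))
}

# the generative quartic of the main validation scenario, as a known truth
true_beta_fit <- function() {
  beta_fit("quartic", coef = c(0.3, -9e-4, -4e-9), age_domain = c(0, 80))
}
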