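test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_individuals = 2000L, seed = 42L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_individuals = 2000L, seed = 43L)
  expect_false(identical(simulate_cohort(cfg2)$exposure_raw, a$exposure_raw))
})

test_that("cohort invariants hold: ages in range, events imply censor bound", {
  cfg <- sim_config(n_individuals = 5000L, seed = 42L)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 5000L)
  ev <- !is.na(coh$event_age)
  expect_true(all(coh$event_age[ev] >= 0 & coh$event_age[ev] <= cfg$max_age))
  expect_true(all(coh$event_age[ev] <= coh$censor_age[ev]))
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(attr(coh, "clip_fraction") >= 0 &&
                attr(coh, "clip_fraction") < 0.10)
})

test_that("null instrument leaves exposure uncorrelated with genotype", {
  cfg <- quiet_config(n = 20000L, seed = 42L, beta = c(0, 0, 0),
                      noise_sd_exposure = 0.9)
  coh <- simulate_cohort(cfg)
  r <- cor(coh$instrument, coh$exposure_raw)
  expect_lt(abs(r), 3 / sqrt(nrow(coh)))
})

test_that("constant noiseless instrument effect is recovered exactly per age", {
  cfg <- quiet_config(n = 5000L, seed = 42L, beta = c(0.3, 0, 0))
  coh <- simulate_cohort(cfg)
  # direct per-stratum least squares oracle
  for (a in c(25, 45, 65)) {
    sub <- coh[coh$age_at_assessment == a, ]
    slope <- coef(lm(exposure_raw ~ instrument, data = sub))[2]
    expect_equal(unname(slope), 0.3, tolerance = 1e-10)
  }
})

test_that("age-stratified instrument effect tracks the generative quartic", {
  cfg <- sim_config(n_individuals = 150000L, seed = 42L)
  coh <- simulate_cohort(cfg)
  st <- stratified_beta(coh, age_breaks = seq(20, 80, by = 10),
                        covariates = "z")
  truth <- 0.3 - 9e-4 * st$age_mid - 4e-9 * st$age_mid^4
  zscore <- (st$estimate - truth) / st$se
  expect_lt(max(abs(zscore)), 3)
  expect_lt(mean(abs(zscore) > 2), 0.5)
})

test_that("true cumulative effect matches the closed form and quadrature", {
  cfg <- sim_config(seed = 1L)
  expect_equal(true_cumulative_effect(cfg, 0), 0)
  expect_equal(true_cumulative_effect(cfg, c(40, 80)),
               cfg$gamma_scale * c(40, 80)^5 / 5)
  gp <- function(t) 1e-6 * (1 + sin(t / 10)^2)
  cfgp <- sim_config(gamma_profile = gp, seed = 1L)
  num <- integrate(gp, 0, 63, rel.tol = 1e-10)$value
  expect_equal(true_cumulative_effect(cfgp, 63), num, tolerance = 1e-6)
  expect_error(true_cumulative_effect(cfg, 81), "max_age")
})

test_that("prevalence is monotone in the baseline hazard", {
  prevs <- sapply(c(2e-4, 6e-4, 1.5e-3), function(g0) {
    cfg <- sim_config(n_individuals = 20000L, seed = 42L,
                      baseline_hazard = g0)
    mean(!is.na(suppressWarnings(simulate_cohort(cfg))$event_age))
  })
  expect_true(all(diff(prevs) > 0))
})

test_that("baseline calibration reaches the target and is a fixed point", {
  cfg <- sim_config(n_individuals = 20000L, seed = 42L)
  realized <- mean(!is.na(simulate_cohort(cfg)$event_age))
  cal <- calibrate_baseline(cfg, realized, n_calib = 20000L, tol = 0.005)
  re2 <- mean(!is.na(simulate_cohort(cal)$event_age))
  expect_lt(abs(re2 - realized), 0.005 + 0.01)
  expect_error(calibrate_baseline(cfg, 1e-6, n_calib = 5000L),
               "unreachable")
})

test_that("implausible configurations warn about hazard clipping", {
  cfg <- sim_config(n_individuals = 3000L, seed = 42L,
                    gamma_scale = 1e-9, hazard_offset = 0)
  expect_warning(simulate_cohort(cfg), "clipped")
})

test_that("multi-SNP cohorts carry dosages and the unweighted score", {
  pr <- preset_config("multisnp", n_individuals = 20000L, seed = 42L)
  coh <- simulate_multisnp_cohort(pr$config, pr$snp_profiles, pr$snp_freqs)
  expect_true(all(c("snp1", "snp2", "snp3", "pgs") %in% names(coh)))
  expect_identical(coh$pgs, coh$snp1 + coh$snp2 + coh$snp3)
  expect_identical(coh$instrument, coh$pgs)
  expect_true(all(coh$snp1 %in% 0:2))
  expect_error(simulate_multisnp_cohort(pr$config, pr$snp_profiles,
                                        c(0.5, 0.5)),
               "length")
  expect_error(simulate_multisnp_cohort(pr$config, pr$snp_profiles[1],
                                        0.5),
               "at least two")
})

test_that("equal constant SNP effects give a score effect equal to each SNP's", {
  prof <- list(function(t) rep(0.2, length(t)),
               function(t) rep(0.2, length(t)))
  cfg <- quiet_config(n = 30000L, seed = 42L)
  coh <- simulate_multisnp_cohort(cfg, prof, c(0.4, 0.4))
  # closed form: cov(x, pgs)/var(pgs) = 0.2 when effects are equal
  slope <- coef(lm(exposure_raw ~ pgs, data = coh))[2]
  expect_equal(unname(slope), 0.2, tolerance = 1e-10)
})
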