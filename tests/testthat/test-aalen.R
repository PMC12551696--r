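test_that("jitter breaks ties within the event year and is reproducible", {
  ages <- rep(55L, 1000)
  t1 <- jitter_event_ages(ages, seed = 42)
  expect_true(all(t1 > 55 & t1 < 56))
  expect_false(anyDuplicated(t1) > 0)
  expect_identical(t1, jitter_event_ages(ages, seed = 42))
  expect_length(jitter_event_ages(integer(0)), 0)
  single <- jitter_event_ages(7L, seed = 1)
  expect_true(single > 7 && single < 8)
})

test_that("intercept-only fit equals the Nelson-Aalen estimator exactly", {
  coh <- tiny_cohort(event_age = c(1, 3, NA, NA, NA),
                     censor_age = c(10, 10, 2, 5, 5))
  fit <- fit_aalen(coh, covariates = character(0), max_follow_age = 10,
                   seed = 42)
  # exits: events jittered in (1,2) and (3,4); censored exit at c+1,
  # so risk sets are 5 then 3 (the age-2 censoring leaves at time 3)
  expect_equal(fit$B[, 1], cumsum(c(1 / 5, 1 / 3)), tolerance = 1e-14)
  expect_equal(fit$V[, 1], cumsum(c(1 / 25, 1 / 9)), tolerance = 1e-14)
})

test_that("two-event binary-covariate fit solves the per-event normal equations", {
  coh <- tiny_cohort(event_age = c(2, 4, NA, NA, NA),
                     censor_age = c(9, 9, 9, 9, 9),
                     x = c(1, 0, 1, 0, 0))
  fit <- fit_aalen(coh, covariates = "x", max_follow_age = 9, seed = 7)
  # hand-solved oracle: at each event, b = (X'X)^{-1} x_event over the
  # at-risk design (first event: all 5 at risk; second: 3 remain)
  X1 <- cbind(1, c(1, 0, 1, 0, 0))
  b1 <- solve(crossprod(X1), X1[1, ])
  X2 <- cbind(1, c(0, 1, 0, 0))
  b2 <- solve(crossprod(X2), X2[1, ])
  expect_equal(fit$increments[1, ], b1, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fit$increments[2, ], b2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fit$B[2, ], b1 + b2, ignore_attr = TRUE, tolerance = 1e-12)
  # single-event variance contribution is the squared increment
  expect_equal(fit$V[2, ], b1^2 + b2^2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the fit agrees with survival::aareg on a simulated cohort", {
  skip_if_not_installed("survival")
  cfg <- quiet_config(n = 3000L, seed = 42L, beta = c(0.3, 0, 0),
                      noise_sd_exposure = 0.5)
  coh <- simulate_cohort(cfg)
  fit <- fit_aalen(coh, covariates = "instrument", max_follow_age = 80,
                   seed = 9)
  # feed aareg the same jittered exit times so both solve identical
  # least-squares problems
  status <- !is.na(coh$event_age) & coh$event_age <= 80
  exit <- numeric(nrow(coh))
  exit[status] <- jitter_event_ages(coh$event_age[status], seed = 9)
  exit[!status] <- pmin(coh$censor_age[!status], 80) + 1
  ar <- survival::aareg(survival::Surv(exit, status) ~ instrument,
                        data = coh, nmin = 1)
  keep <- seq_len(fit$n_events)
  expect_equal(colSums(ar$coefficient[keep, , drop = FALSE]),
               fit$B[fit$n_events, ], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("yearly increments telescope and have non-negative variances", {
  cfg <- sim_config(n_individuals = 20000L, seed = 42L)
  coh <- simulate_cohort(cfg)
  fit <- fit_aalen(coh, covariates = c("instrument", "z"),
                   max_follow_age = 76, seed = 3)
  inc <- yearly_increments(fit, "instrument")
  expect_equal(nrow(inc), 76L)
  expect_true(all(inc$sigma2 >= 0))
  expect_true(all(diff(fit$V[, "instrument"]) >= 0))
  expect_equal(sum(inc$H_hat), unname(fit$B[nrow(fit$B), "instrument"]),
               tolerance = 1e-12)
  expect_equal(sum(inc$sigma2), unname(fit$V[nrow(fit$V), "instrument"]),
               tolerance = 1e-12)
  expect_equal(sum(inc$n_events), fit$n_events)
  # years without events contribute exactly zero
  empty <- inc$n_events == 0
  expect_true(all(inc$H_hat[empty] == 0) && all(inc$sigma2[empty] == 0))
  expect_error(yearly_increments(fit, "nope"), "not present")
})

test_that("a randomly permuted covariate has a null cumulative coefficient", {
  cfg <- sim_config(n_individuals = 30000L, seed = 42L)
  coh <- simulate_cohort(cfg)
  set.seed(4242)
  coh$perm <- sample(coh$instrument)
  fit <- fit_aalen(coh, covariates = c("instrument", "perm"),
                   max_follow_age = 76, seed = 3)
  last <- nrow(fit$B)
  zstat <- fit$B[last, "perm"] / sqrt(fit$V[last, "perm"])
  expect_lt(abs(zstat), 3)
})

test_that("disjoint-bin increments are uncorrelated across replicates", {
  R <- 400
  H <- matrix(NA, R, 2)
  for (r in seq_len(R)) {
    cfg <- quiet_config(n = 400L, seed = 9000L + r, beta = c(0.3, 0, 0),
                        noise_sd_exposure = 0.5,
                        baseline_hazard = 5e-3, hazard_offset = 2e-3)
    coh <- simulate_cohort(cfg)
    fit <- fit_aalen(coh, covariates = "instrument", max_follow_age = 80,
                     seed = r)
    inc <- yearly_increments(fit, "instrument")
    H[r, ] <- inc$H_hat[c(60, 75)]
  }
  cc <- cor(H[, 1], H[, 2])
  expect_lt(abs(cc), 3 / sqrt(R))
})

test_that("degenerate inputs are refused", {
  coh <- tiny_cohort(event_age = c(NA, NA), censor_age = c(80, 80))
  expect_error(fit_aalen(coh, character(0)), "no events")
  coh2 <- tiny_cohort(event_age = c(5, NA), censor_age = c(80, 80),
                      x = c(1, 1))
  expect_error(fit_aalen(coh2, "x"), "rank deficient")
  expect_error(fit_aalen(coh2, "missing_col"), "absent")
})
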