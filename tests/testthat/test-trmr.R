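# closed-form H(t) = int_0^t gamma(s) betaG(s) ds for the power-law gamma
# and the quartic betaG of the main validation scenario
H_closed <- function(t, cg = 4.5e-11, a = 0.3, b = -9e-4, cc = -4e-9) {
  cg * (a * t^5 / 5 + b * t^6 / 6 + cc * t^9 / 9)
}

test_that("zero increments give a zero momentaneous series", {
  inc <- make_increments(rep(0, 20))
  out <- momentaneous_effects(inc, true_beta_fit())
  expect_true(all(out$gamma == 0))
  expect_equal(out$t_mid, (1:20) - 0.5)
})

test_that("analytic increments recover the power-law momentaneous effect", {
  K <- 80
  cg <- 4.5e-11
  H <- H_closed(1:K, cg)             # exact yearly H(t_k) series
  inc <- make_increments(H)
  out <- momentaneous_effects(inc, true_beta_fit())
  truth <- cg * out$t_mid^4
  rel <- abs(out$gamma - truth) / pmax(truth, cg)
  # midpoint quadrature error is O(dt^2); relative error ~ 0.5/t^2
  expect_lt(max(rel[out$year >= 10]), 0.01)
  Gm <- cumulative_midpoint(out)
  expect_lt(abs(Gm[80] - cg * 80^5 / 5) / (cg * 80^5 / 5), 0.005)
})

test_that("constant instrument effect reduces to elementwise division", {
  set.seed(42)
  H <- cumsum(abs(rnorm(15, 1e-4, 5e-5)))
  inc <- make_increments(H, sigma2 = rep(1e-8, 15))
  bconst <- beta_fit("constant", coef = 0.25)
  out <- momentaneous_effects(inc, bconst)
  expect_equal(out$gamma, diff(c(0, H)) / 0.25, tolerance = 1e-14)
  # exact telescoping: Gamma_mid(t_k) = H(t_k) / beta for every k
  expect_equal(cumulative_midpoint(out), H / 0.25, tolerance = 1e-12)
  # and both naive estimators coincide with the time-resolved one
  expect_equal(naive_wald_constant(inc, 0.25),
               cumulative_midpoint(out), tolerance = 1e-12)
  expect_equal(naive_wald_timevarying(inc, bconst),
               cumulative_midpoint(out), tolerance = 1e-12)
})

test_that("weak instruments are refused with the offending ages named", {
  inc <- make_increments(rep(1e-4, 80))
  weak <- beta_fit("quartic", coef = c(0.3, -9e-4, -5.6e-9)) # crosses floor
  expect_error(momentaneous_effects(inc, weak), "weak instrument")
  expect_error(variance_midpoint(inc, weak), "weak instrument")
  expect_error(naive_wald_timevarying(inc, weak), "weak instrument")
  expect_error(naive_wald_constant(inc, 0), "zero")
})

test_that("the trapezoid rule matches a literal transcription of its weights", {
  set.seed(42)
  g <- rnorm(12)
  got <- cumulative_trapezoid(g)
  oracle <- sapply(seq_along(g), function(k) {
    if (k == 1) return(g[1] / 4)
    interior <- if (k >= 3) sum(g[2:(k - 1)]) else 0
    g[1] / 4 + g[1] / 2 + interior + g[k] / 2
  })
  expect_equal(got, oracle, tolerance = 1e-14)
  # constant series: printed weights give g * (k - 1/2) - g/4
  gc <- cumulative_trapezoid(rep(2, 10))
  expect_equal(gc[10], 2 * (10 - 0.5) - 2 / 4)
  expect_true(all(cumulative_trapezoid(rep(0, 6)) == 0))
})

test_that("trapezoid quadrature error is second order on smooth profiles", {
  K <- 60
  g <- 3 * ((1:K) - 0.5)^2 * 1e-6      # gamma(t) = 3e-6 t^2
  Gt <- cumulative_trapezoid(g)
  truth <- 1e-6 * ((1:K) - 0.5)^3      # int gamma = 1e-6 t^3
  expect_lt(max((abs(Gt - truth) / truth)[10:K]), 0.01)
  Gm <- cumulative_midpoint(g)
  truth_m <- 1e-6 * (1:K)^3
  expect_lt(max((abs(Gm - truth_m) / truth_m)[10:K]), 0.01)
})

test_that("variance formulas honor the printed special cases and limits", {
  bconst <- beta_fit("constant", coef = 0.2)
  s2 <- c(4e-8, 9e-8, 1e-8, 2.5e-8)
  inc <- make_increments(rep(1e-4, 4), sigma2 = s2)
  v <- variance_trapezoid(inc, bconst)
  b2 <- 0.2^2
  expect_equal(v[1], s2[1] / (16 * b2), tolerance = 1e-14)
  expect_equal(v[2], s2[1] / (16 * b2) + s2[2] / (4 * b2), tolerance = 1e-14)
  expect_equal(v[4], s2[1] / (16 * b2) + s2[3] / (4 * b2) + s2[4] / (4 * b2),
               tolerance = 1e-14)
  # sigma_1 -> 0 with equal adjacent variances: half the midpoint variance
  s2b <- c(0, 1e-8, 1e-8, 1e-8)
  incb <- make_increments(rep(1e-4, 4), sigma2 = s2b)
  expect_equal(variance_trapezoid(incb, bconst)[4],
               variance_midpoint(incb, bconst)[4] / 2, tolerance = 1e-12)
  # equal variances: full and simplified forms differ by 12.5%
  s2c <- rep(1e-8, 10)
  incc <- make_increments(rep(1e-4, 10), sigma2 = s2c)
  full <- variance_trapezoid(incc, bconst)
  simp <- variance_trapezoid(incc, bconst, simplified = TRUE)
  expect_equal(full[10] / simp[10], 1.125, tolerance = 1e-10)
  expect_true(all(variance_midpoint(incc, bconst) >= 0))
  # zero variance propagates to zero
  inc0 <- make_increments(rep(1e-4, 5))
  expect_true(all(variance_midpoint(inc0, bconst) == 0))
})

test_that("pointwise bands use the exact normal quantile", {
  ci <- pointwise_ci(c(1, 2), c(0.04, 0.09), alpha = 0.05)
  expect_equal(ci$upper - ci$estimate, qnorm(0.975) * c(0.2, 0.3),
               tolerance = 1e-12)
  expect_equal(unname(qnorm(0.975)), 1.959964, tolerance = 1e-6)
  ci32 <- pointwise_ci(0, 1, alpha = 0.32)
  expect_equal(ci32$upper, qnorm(1 - 0.16), tolerance = 1e-12)
  expect_equal(ci32$upper, 0.9944579, tolerance = 1e-6)
  ci0 <- pointwise_ci(c(5, 5), c(0, 0))
  expect_equal(ci0$lower, ci0$upper)
  expect_error(pointwise_ci(1, -1), "non-negative")
})

test_that("the naive comparators behave on degenerate series", {
  expect_equal(naive_wald_constant(rep(0, 5), 0.3), rep(0, 5))
  one <- make_increments(3e-4)
  bconst <- beta_fit("constant", coef = 0.3)
  expect_equal(naive_wald_timevarying(one, bconst),
               cumulative_midpoint(momentaneous_effects(one, bconst)),
               tolerance = 1e-14)
})

test_that("effect_series bundles all estimators consistently", {
  set.seed(42)
  H <- H_closed(1:76)
  inc <- make_increments(H, sigma2 = abs(rnorm(76, 1e-7, 2e-8)))
  eff <- effect_series(inc, true_beta_fit())
  expect_s3_class(eff, "effect_series")
  expect_equal(eff$Gamma_mid, cumsum(eff$gamma), tolerance = 1e-14)
  expect_true(all(eff$var_Gamma_mid >= 0))
  expect_true(all(eff$Gamma_mid_upper >= eff$Gamma_mid))
  expect_true(all(eff$Gamma_trap_lower <= eff$Gamma_trap))
})
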