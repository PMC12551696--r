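#' Momentaneous exposure effects from yearly increments
#'
#' The age-resolved Wald ratio: the central finite difference of the yearly
#' instrument-on-outcome effects, divided by the instrument-on-exposure
#' effect at the bin midpoint,
#' \deqn{\hat\gamma(t_{k-1/2}) = \frac{\hat H(t_k) - \hat H(t_{k-1})}
#'       {\beta_G(t_{k-1/2})}, \qquad \hat H(t_0) = 0,}
#' with variance \eqn{(\sigma_k^2 + \sigma_{k-1}^2) / \beta_G^2(t_{k-1/2})}.
#'
#' Division refuses when \eqn{|\beta_G|} falls below \code{floor} anywhere on
#' the analysis grid (weak instrument / zero crossing); switch to the linear
#' instrument model in that case.
#'
#' @param incr A [yearly_increments()] table.
#' @param beta A [beta_fit()].
#' @param floor Smallest admissible \eqn{|\beta_G|} (exposure SD per
#'   instrument unit).
#' @return \code{data.frame} with \code{year} k, midpoint age \code{t_mid}
#'   = k - 1/2, \code{gamma} and \code{var_gamma}.
#' @export
momentaneous_effects <- function(incr, beta, floor = 0.01) {
  k <- incr$year
  t_mid <- k - 0.5
  b_mid <- beta_eval(beta, t_mid)
  b_int <- beta_eval(beta, k)
  bad <- abs(b_mid) < floor | abs(b_int) < floor
  if (any(bad)) {
    stop(sprintf(
      "weak instrument: |betaG| < %g at age(s) %s; refusing the Wald ratio (consider the linear model)",
      floor, paste(utils::head(t_mid[bad], 5), collapse = ", ")))
  }
  dH <- diff(c(0, incr$H_hat))
  s2 <- incr$sigma2
  s2_prev <- c(0, s2[-length(s2)])
  data.frame(year = k, t_mid = t_mid,
             gamma = dH / b_mid,
             var_gamma = (s2 + s2_prev) / b_mid^2)
}

#' Cumulative life-course effect by the midpoint rule
#'
#' \eqn{\hat\Gamma(t_k) = \sum_{i \le k} \hat\gamma(t_{i-1/2})}, with
#' \eqn{\hat\Gamma(t_0) = 0}.  This is the series consumed by the trend and
#' bootstrap stages (midpoint increments are uncorrelated across bins).
#'
#' @param gamma Momentaneous effect series from [momentaneous_effects()]
#'   (or a bare numeric vector of midpoint effects).
#' @return Numeric vector \eqn{\hat\Gamma(t_k)}, k = 1..K.
#' @export
cumulative_midpoint <- function(gamma) {
  g <- if (is.data.frame(gamma)) gamma$gamma else gamma
  cumsum(g)
}

#' Cumulative life-course effect by the trapezoidal rule
#'
#' Evaluated at half-integer ages \eqn{t_{k-1/2}}:
#' \deqn{\hat\Gamma(t_{k-1/2}) = \tfrac14\hat\gamma(t_{1/2})
#'  + \tfrac12\hat\gamma(t_{1/2}) + \sum_{i=2}^{k-1}\hat\gamma(t_{i-1/2})
#'  + \tfrac12\hat\gamma(t_{k-1/2}),}
#' where the leading quarter term integrates over \eqn{[0, t_{1/2}]} with
#' \eqn{\hat\gamma(t_0) = 0}.  For \code{k = 1} only that leading term
#' remains.  Smoother than the midpoint series but with correlated adjacent
#' points; used for presentation.
#'
#' @inheritParams cumulative_midpoint
#' @return Numeric vector \eqn{\hat\Gamma(t_{k-1/2})}, k = 1..K.
#' @export
cumulative_trapezoid <- function(gamma) {
  g <- if (is.data.frame(gamma)) gamma$gamma else gamma
  K <- length(g)
  out <- numeric(K)
  out[1] <- g[1] / 4
  if (K >= 2) {
    csum <- cumsum(g)
    for (k in 2:K) {
      interior <- if (k >= 3) csum[k - 1] - csum[1] else 0
      out[k] <- g[1] / 4 + g[1] / 2 + interior + g[k] / 2
    }
  }
  out
}

#' Variance of the midpoint-rule cumulative effect
#'
#' \eqn{\mathrm{Var}[\hat\Gamma(t_k)] \approx \sigma_k^2 / \beta_G^2(t_k)}:
#' because the cumulative effect telescopes, only the variance of the final
#' yearly increment survives to first order.
#'
#' @inheritParams momentaneous_effects
#' @return Numeric vector of variances at \eqn{t_k}.
#' @export
variance_midpoint <- function(incr, beta, floor = 0.01) {
  b <- beta_eval(beta, incr$year)
  if (any(abs(b) < floor)) {
    stop(sprintf("weak instrument: |betaG| < %g on the grid", floor))
  }
  incr$sigma2 / b^2
}

#' Variance of the trapezoid-rule cumulative effect
#'
#' Full form, for interior points \eqn{k \ge 3}:
#' \deqn{\mathrm{Var}[\hat\Gamma(t_{k-1/2})] \approx
#'  \frac{\sigma_1^2}{16\beta_G^2(t_1)} +
#'  \frac{\sigma_{k-1}^2}{4\beta_G^2(t_{k-1})} +
#'  \frac{\sigma_k^2}{4\beta_G^2(t_k)},}
#' with \eqn{\sigma_1^2/16\beta_G^2(t_1)} at \eqn{k=1} and
#' \eqn{\sigma_1^2/16\beta_G^2(t_1) + \sigma_2^2/4\beta_G^2(t_2)} at
#' \eqn{k=2}.  The \code{simplified} form \eqn{\sigma_k^2/2\beta_G^2(t_k)}
#' (half the midpoint-rule variance) is adequate for large \code{k}.
#'
#' @inheritParams momentaneous_effects
#' @param simplified Use the simpler large-k approximation.
#' @return Numeric vector of variances at \eqn{t_{k-1/2}}.
#' @export
variance_trapezoid <- function(incr, beta, floor = 0.01, simplified = FALSE) {
  b <- beta_eval(beta, incr$year)
  if (any(abs(b) < floor)) {
    stop(sprintf("weak instrument: |betaG| < %g on the grid", floor))
  }
  s2 <- incr$sigma2
  r <- s2 / b^2                        # sigma_k^2 / betaG^2(t_k)
  K <- length(r)
  if (simplified) return(r / 2)
  out <- numeric(K)
  out[1] <- r[1] / 16
  if (K >= 2) out[2] <- r[1] / 16 + r[2] / 4
  if (K >= 3) {
    ks <- 3:K
    out[ks] <- r[1] / 16 + r[ks - 1] / 4 + r[ks] / 4
  }
  out
}

#' Pointwise normal confidence bands
#'
#' \eqn{\hat\Gamma \pm z_{1-\alpha/2}\sqrt{\mathrm{Var}}}, with
#' \eqn{z_{0.975} = 1.96} at the default level.
#'
#' @param estimate Point estimates.
#' @param var Variances (non-negative).
#' @param alpha Significance level.
#' @return \code{data.frame} with \code{estimate}, \code{lower},
#'   \code{upper}.
#' @export
pointwise_ci <- function(estimate, var, alpha = 0.05) {
  if (any(var < 0)) stop("variances must be non-negative")
  zq <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(var)
  data.frame(estimate = estimate, lower = estimate - zq * se,
             upper = estimate + zq * se)
}

#' Naive Wald comparator with a time-averaged instrument effect
#'
#' Divides the yearly instrument-on-outcome effect \eqn{\hat H(T)} by a
#' constant, time-averaged \eqn{\bar\beta_G} from the misspecified
#' (time-fixed) instrument regression.  Biased whenever \eqn{\beta_G}
#' actually varies with age; provided as the first comparator.
#'
#' @param incr A [yearly_increments()] table (or numeric \eqn{\hat H}
#'   series).
#' @param beta_const Scalar \eqn{\bar\beta_G}, or a \code{"constant"}
#'   [beta_fit()].
#' @return Numeric vector \eqn{\hat H(t_k)/\bar\beta_G}.
#' @export
naive_wald_constant <- function(incr, beta_const) {
  H <- if (is.data.frame(incr)) incr$H_hat else incr
  b <- if (inherits(beta_const, "beta_fit")) beta_const$coef[1] else beta_const
  if (b == 0) stop("constant instrument effect is zero")
  H / b
}

#' Naive Wald comparator with the instantaneous instrument effect
#'
#' Divides \eqn{\hat H(T)} by \eqn{\beta_G(T)} at the same age, ignoring
#' that the accumulated outcome effect depends on \eqn{\beta_G(t)} at all
#' earlier ages \eqn{t \le T}.  Coincides with the time-resolved estimate
#' only when \eqn{\beta_G} is constant.
#'
#' @param incr A [yearly_increments()] table (or numeric \eqn{\hat H}
#'   series; ages then assumed 1..K).
#' @param beta A [beta_fit()].
#' @param floor Weak-instrument floor.
#' @return Numeric vector \eqn{\hat H(t_k)/\beta_G(t_k)}.
#' @export
naive_wald_timevarying <- function(incr, beta, floor = 0.01) {
  H <- if (is.data.frame(incr)) incr$H_hat else incr
  yrs <- if (is.data.frame(incr)) incr$year else seq_along(H)
  b <- beta_eval(beta, yrs)
  if (any(abs(b) < floor)) {
    stop(sprintf("weak instrument: |betaG| < %g on the grid", floor))
  }
  H / b
}

#' Assemble the full effect series
#'
#' Runs [momentaneous_effects()], both quadrature rules and their variances,
#' and attaches pointwise confidence bands.
#'
#' @inheritParams momentaneous_effects
#' @param alpha Significance level for the pointwise bands.
#' @return \code{data.frame} of class \code{"effect_series"} with one row per
#'   yearly bin: \code{year}, \code{t_mid}, \code{gamma}, \code{var_gamma},
#'   \code{Gamma_mid}, \code{var_Gamma_mid}, \code{Gamma_mid_lower/upper},
#'   \code{Gamma_trap}, \code{var_Gamma_trap},
#'   \code{Gamma_trap_lower/upper}.
#' @export
effect_series <- function(incr, beta, floor = 0.01, alpha = 0.05) {
  gam <- momentaneous_effects(incr, beta, floor = floor)
  Gm <- cumulative_midpoint(gam)
  vGm <- variance_midpoint(incr, beta, floor = floor)
  Gt <- cumulative_trapezoid(gam)
  vGt <- variance_trapezoid(incr, beta, floor = floor)
  ci_m <- pointwise_ci(Gm, vGm, alpha)
  ci_t <- pointwise_ci(Gt, vGt, alpha)
  out <- data.frame(
    year = gam$year, t_mid = gam$t_mid,
    gamma = gam$gamma, var_gamma = gam$var_gamma,
    Gamma_mid = Gm, var_Gamma_mid = vGm,
    Gamma_mid_lower = ci_m$lower, Gamma_mid_upper = ci_m$upper,
    Gamma_trap = Gt, var_Gamma_trap = vGt,
    Gamma_trap_lower = ci_t$lower, Gamma_trap_upper = ci_t$upper
  )
  class(out) <- c("effect_series", "data.frame")
  out
}
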