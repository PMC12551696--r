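#' Raised-cosine smoothing kernel
#'
#' \eqn{K(u) = \tfrac12\cos(\pi u / b) + \tfrac12} for \eqn{|u| \le b} and 0
#' otherwise.  \code{b} is the full duration at half maximum (FDHM):
#' \eqn{K(\pm b/2) = 1/2}, so adjacent temporal structures closer than
#' \code{b} years are not resolved.
#'
#' @param u Offset(s) in years.
#' @param b FDHM in years (> 0).
#' @return Weights in \eqn{[0, 1]}.
#' @export
cosine_kernel <- function(u, b = 10) {
  if (b <= 0) stop("b must be positive")
  ifelse(abs(u) <= b, 0.5 * cos(pi * u / b) + 0.5, 0)
}

# rows of the linear smoother mapping a series y (at `times`) to the
# local-linear slope at each T in `T_eval`
local_slope_weights <- function(times, T_eval, b) {
  W <- matrix(0, length(T_eval), length(times))
  for (i in seq_along(T_eval)) {
    T0 <- T_eval[i]
    w <- cosine_kernel(times - T0, b)
    pos <- w > 0
    if (sum(pos) < 2L || length(unique(times[pos])) < 2L) {
      stop(sprintf("degenerate kernel support at T = %g (need >= 2 points)", T0))
    }
    X <- cbind(1, times - T0)
    A <- crossprod(X, w * X)
    # slope row of (X'WX)^{-1} X'W
    W[i, ] <- solve(A, t(X * w))[2, ]
  }
  W
}

#' Kernel local-linear trend of the momentaneous effect
#'
#' Smoothed momentaneous effect \eqn{\bar\gamma(T)}: the slope of a weighted
#' linear regression of the cumulative-effect series on age, with
#' raised-cosine weights centred at \code{T} ([cosine_kernel()]).  On an
#' equidistant grid with the (interior-)symmetric kernel the slope is
#' accurate to second order, i.e. it matches the derivative of a local
#' quadratic fit.  Near the boundary ages the kernel support is truncated.
#'
#' @param Gamma Cumulative effect series \eqn{\hat\Gamma(t_i)} (numeric), or
#'   an [effect_series()] (its \code{Gamma_mid} column is used).
#' @param times Grid ages \eqn{t_i}; defaults to \code{seq_along(Gamma)}
#'   or the \code{year} column.
#' @param T_eval Ages at which to evaluate the trend (default: the grid).
#' @param b Kernel FDHM in years.
#' @return \code{data.frame} with \code{T} and \code{gamma_bar}
#'   (hazard-rate change per year per exposure SD, averaged over ~\code{b}
#'   years).
#' @export
local_slope <- function(Gamma, times = NULL, T_eval = NULL, b = 10) {
  if (inherits(Gamma, "effect_series")) {
    times <- Gamma$year
    Gamma <- Gamma$Gamma_mid
  }
  if (is.null(times)) times <- seq_along(Gamma)
  if (is.null(T_eval)) T_eval <- times
  W <- local_slope_weights(times, T_eval, b)
  data.frame(T = T_eval, gamma_bar = drop(W %*% Gamma))
}

#' Hodrick-Prescott trend filter
#'
#' Returns the minimizer of
#' \eqn{\sum_t (y_t - \tau_t)^2 + \lambda \sum_t (\Delta^2 \tau_t)^2},
#' i.e. \eqn{\tau = (I + \lambda D^\top D)^{-1} y} with \code{D} the
#' second-difference operator.  \code{lambda = 0} reproduces the input;
#' \eqn{\lambda \to \infty} approaches the least-squares straight line.
#'
#' @param y Numeric series (length >= 4), or a matrix whose columns are
#'   filtered independently.
#' @param lambda Smoothness penalty (>= 0).
#' @return Trend of the same shape as \code{y}.
#' @export
hp_filter <- function(y, lambda = 50) {
  if (lambda < 0) stop("lambda must be non-negative")
  ym <- as.matrix(y)
  n <- nrow(ym)
  if (n < 4L) stop("series too short for the HP filter (need length >= 4)")
  D <- diff(diag(n), differences = 2)
  A <- diag(n) + lambda * crossprod(D)
  out <- solve(A, ym)
  if (is.matrix(y)) out else drop(out)
}

#' Parametric bootstrap bands for effect trends
#'
#' Resamples the cumulative-effect series as
#' \eqn{\hat\Gamma_{boot}(t_k) = \hat\Gamma(t_k) + \varepsilon_k},
#' \eqn{\varepsilon_k \sim N(0, \sigma_k^2/\beta_G^2(t_k))} independently
#' across time points, refits the trend for each bootstrap series, and
#' returns percentile bands (the \eqn{\alpha/2} and \eqn{1-\alpha/2}
#' quantiles per age).  Only the series noise is resampled; the instrument
#' fit and the Aalen fit are held fixed.
#'
#' @param effects An [effect_series()] (uses \code{Gamma_mid} and
#'   \code{var_Gamma_mid}), or a list with elements \code{Gamma},
#'   \code{var} and \code{times}.
#' @param trend \code{"hp"} for the Hodrick-Prescott trend of the
#'   cumulative effect, or \code{"gamma_bar"} for the kernel local-linear
#'   trend of the momentaneous effect.
#' @param lambda HP penalty (trend = "hp").
#' @param b Kernel FDHM in years (trend = "gamma_bar").
#' @param n_boot Number of bootstrap samples.
#' @param alpha Band level.
#' @param seed Integer seed.
#' @return \code{data.frame} with \code{T}, \code{trend}, \code{lower},
#'   \code{upper}; class \code{"trend_series"}.
#' @export
bootstrap_trend_bands <- function(effects, trend = c("hp", "gamma_bar"),
                                  lambda = 50, b = 10, n_boot = 10000,
                                  alpha = 0.05, seed = 1L) {
  trend <- match.arg(trend)
  if (inherits(effects, "effect_series") || is.data.frame(effects)) {
    Gamma <- effects$Gamma_mid
    v <- effects$var_Gamma_mid
    times <- effects$year
  } else {
    Gamma <- effects$Gamma
    v <- effects$var
    times <- if (is.null(effects$times)) seq_along(Gamma) else effects$times
  }
  if (any(v < 0)) stop("variances must be non-negative")
  if (n_boot < 100) warning("n_boot < 100 gives unstable percentile bands")
  set.seed(seed)
  K <- length(Gamma)
  eps <- matrix(stats::rnorm(K * n_boot, sd = sqrt(v)), K, n_boot)
  Y <- Gamma + eps
  if (trend == "hp") {
    point <- hp_filter(Gamma, lambda)
    boots <- hp_filter(Y, lambda)
  } else {
    W <- local_slope_weights(times, times, b)
    point <- drop(W %*% Gamma)
    boots <- W %*% Y
  }
  qs <- apply(boots, 1, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- data.frame(T = times, trend = point,
                    lower = pmin(qs[1, ], point),
                    upper = pmax(qs[2, ], point))
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Basic bootstrap confidence interval for a stratum statistic
#'
#' Utility for descriptive per-stratum statistics (e.g. mean or SD of the
#' raw exposure by sex and age): resamples individuals with replacement and
#' returns percentile intervals.
#'
#' @param x Numeric vector.
#' @param stat Function computing the statistic.
#' @param n_boot Number of resamples.
#' @param alpha Interval level.
#' @param seed Integer seed.
#' @return Named vector \code{estimate}, \code{lower}, \code{upper}.
#' @export
basic_bootstrap_ci <- function(x, stat = mean, n_boot = 1000, alpha = 0.05,
                               seed = 1L) {
  set.seed(seed)
  est <- stat(x)
  reps <- vapply(seq_len(n_boot),
                 function(i) stat(sample(x, replace = TRUE)), numeric(1))
  q <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(estimate = est, lower = q[1], upper = q[2])
}
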