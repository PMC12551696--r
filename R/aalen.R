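#' Jitter integer event ages to distinct continuous times
#'
#' Aalen's estimator needs a strict ordering of event times; register data
#' record whole years.  Each event recorded at year \code{k} is mapped to
#' \code{k + u} with \code{u ~ Uniform(0, 1)} (re-drawn on the rare exact
#' collision), so ties within a year are broken while the year membership is
#' preserved.
#'
#' @param event_ages Integer event ages (years, >= 0).
#' @param seed Optional integer seed; when supplied the jitter is reproducible.
#' @return Numeric vector of distinct jittered times, same length and order.
#' @export
jitter_event_ages <- function(event_ages, seed = NULL) {
  if (length(event_ages) == 0) return(numeric(0))
  if (any(event_ages < 0)) stop("event ages must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  times <- event_ages + stats::runif(length(event_ages))
  while (anyDuplicated(times)) {
    dup <- duplicated(times)
    times[dup] <- event_ages[dup] + stats::runif(sum(dup))
  }
  times
}

#' Fit Aalen's additive hazards model
#'
#' Nonparametric least-squares estimation of the cumulative regression
#' coefficients \eqn{\hat B_m(t)} of the additive model
#' \eqn{\lambda(t \mid x) = b_0(t) + \sum_m b_m(t) x_m}.  At each (jittered)
#' event time the coefficient increment solves the normal equations of the
#' at-risk design matrix regressed on the event indicator; the per-event
#' variance contribution is the squared increment (the single-event form of
#' the usual sandwich estimator).  The risk-set normal equations are
#' maintained by downdating as individuals exit, so the cost is
#' O((n + events) p^2 + events p^3).
#'
#' Follow-up is from birth (age scale, no delayed entry) and administratively
#' censored at \code{max_follow_age}: events recorded later are treated as
#' censored there.  All covariate effects are time varying (none is held
#' constant).
#'
#' @param cohort A cohort table with \code{event_age} (integer years, NA when
#'   censored) and \code{censor_age} columns.
#' @param covariates Character vector of covariate columns (the instrument
#'   first, by convention); an intercept is always included.
#' @param max_follow_age Administrative censoring age in years.
#' @param seed Seed for the within-year jitter.
#' @return An object of class \code{"aalen_fit"}: jittered \code{times},
#'   recorded \code{event_year} per event, matrices \code{B} (cumulative
#'   coefficients) and \code{V} (cumulative variances), one column per term.
#' @export
fit_aalen <- function(cohort, covariates = "instrument",
                      max_follow_age = 76, seed = 1L) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("covariate(s) absent from cohort: ", paste(miss, collapse = ", "))
  }
  K <- max_follow_age
  status <- !is.na(cohort$event_age) & cohort$event_age <= K
  if (!any(status)) stop("no events before max_follow_age; empty fit")

  # exits: events at their jittered time within (age, age + 1); censored
  # individuals (incl. events past the cutoff) at the end of the last
  # fully-observed year
  event_year <- cohort$event_age[status]
  jit <- jitter_event_ages(event_year, seed = seed)
  exit <- numeric(nrow(cohort))
  exit[status] <- jit
  exit[!status] <- pmin(cohort$censor_age[!status], K) + 1

  X <- cbind(`(Intercept)` = 1,
             as.matrix(cohort[, covariates, drop = FALSE]))
  p <- ncol(X)
  storage.mode(X) <- "double"

  ord <- order(exit)
  X <- X[ord, , drop = FALSE]
  exit_o <- exit[ord]
  is_event <- status[ord]
  year_o <- rep(NA_real_, length(exit_o))
  year_o[is_event] <- floor(exit_o[is_event])   # recorded age of the event

  M <- crossprod(X)
  n_events <- sum(is_event)
  inc <- matrix(0, n_events, p)
  vinc <- matrix(0, n_events, p)
  times <- numeric(n_events)
  years <- numeric(n_events)

  ev_idx <- which(is_event)
  ptr <- 1L        # next individual (in exit order) still in the risk set
  e <- 0L
  for (i in ev_idx) {
    if (ptr < i) {
      drop <- ptr:(i - 1L)
      M <- M - crossprod(X[drop, , drop = FALSE])
      ptr <- i
    }
    e <- e + 1L
    xi <- X[i, ]
    b <- tryCatch(solve(M, xi), error = function(err) {
      stop(sprintf(
        "risk-set design is rank deficient at event time %.3f (risk set too small or separated)",
        exit_o[i]))
    })
    inc[e, ] <- b
    vinc[e, ] <- b^2
    times[e] <- exit_o[i]
    years[e] <- year_o[i]
    M <- M - tcrossprod(xi)
    ptr <- i + 1L
  }

  B <- apply(inc, 2, cumsum)
  V <- apply(vinc, 2, cumsum)
  if (n_events == 1L) {
    B <- matrix(B, 1L)
    V <- matrix(V, 1L)
  }
  colnames(B) <- colnames(V) <- colnames(inc) <- colnames(X)
  structure(list(times = times, event_year = years, increments = inc,
                 B = B, V = V, covariates = colnames(X),
                 n_events = n_events, n = nrow(cohort),
                 max_follow_age = K),
            class = "aalen_fit")
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat(sprintf(
    "Aalen additive hazards fit: %d events among %d individuals (follow-up to age %g)\n",
    x$n_events, x$n, x$max_follow_age))
  cat("  terms:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Yearly increments of a cumulative Aalen coefficient
#'
#' Converts the cumulative coefficient \eqn{\hat B_m(t)} of one covariate into
#' the yearly instrument-on-outcome effects
#' \eqn{\hat H(t_k) = \hat B_m(t_\psi) - \hat B_m(t_\chi)}, where
#' \eqn{t_\psi} is the last jittered event of year \code{k} and
#' \eqn{t_\chi} the last jittered event of the preceding year; years with no
#' events contribute a zero increment.  The corresponding variance
#' \eqn{\sigma_k^2} is the same difference of the cumulative variances.
#'
#' @param fit An [fit_aalen()] result.
#' @param covariate Name of the covariate (e.g. \code{"instrument"}).
#' @return A \code{data.frame} with columns \code{year} (k = 1..K),
#'   \code{H_hat}, \code{sigma2} and \code{n_events}; class
#'   \code{"yearly_increments"}.
#' @export
yearly_increments <- function(fit, covariate = "instrument") {
  if (!covariate %in% fit$covariates) {
    stop("covariate not present in the Aalen fit: ", covariate)
  }
  K <- as.integer(fit$max_follow_age)
  Bm <- fit$B[, covariate]
  Vm <- fit$V[, covariate]
  # value of the step functions at the end of each yearly bin (k, k+1]
  #   year k collects events with floor(jittered time) == k
  idx_last <- findInterval(seq_len(K) + 1 - 1e-9, fit$times)
  B_at <- c(0, Bm)[idx_last + 1L]
  V_at <- c(0, Vm)[idx_last + 1L]
  H <- diff(c(0, B_at))
  s2 <- diff(c(0, V_at))
  # events in year 0 (jittered time < 1) fold into the first bin
  nev <- tabulate(pmax(floor(fit$times), 1), nbins = K)
  out <- data.frame(year = seq_len(K), H_hat = H, sigma2 = s2,
                    n_events = nev)
  class(out) <- c("yearly_increments", "data.frame")
  out
}
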