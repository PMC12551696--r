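#' Construct an instrument-effect function object
#'
#' Container for a fitted age-varying instrument effect
#' \eqn{\beta_G(t) = a + b t + c t^4} (quartic), \eqn{a + b t} (linear) or a
#' constant \eqn{a}, with the coefficient covariance needed for delta-method
#' confidence bands.  Normally produced by [fit_beta_quartic()],
#' [fit_beta_linear()] or [fit_beta_constant()]; the constructor is exported
#' so that synthetic fits (e.g. a known generative truth with zero
#' covariance) can be fed to the downstream estimator.
#'
#' @param kind One of \code{"quartic"}, \code{"linear"}, \code{"constant"}.
#' @param coef Named or unnamed coefficients: \code{(a, b, c)},
#'   \code{(a, b)} or \code{a}.
#' @param vcov Coefficient covariance matrix (symmetric PSD), matching
#'   \code{coef} in dimension; defaults to zero.
#' @param n Fit sample size (informational).
#' @param age_domain Ages over which evaluation is defined.
#' @return An object of class \code{"beta_fit"}.
#' @export
beta_fit <- function(kind = c("quartic", "linear", "constant"), coef,
                     vcov = NULL, n = NA_integer_, age_domain = c(0, 80)) {
  kind <- match.arg(kind)
  want <- switch(kind, quartic = 3L, linear = 2L, constant = 1L)
  coef <- as.numeric(coef)
  if (length(coef) != want) {
    stop(sprintf("%s model needs %d coefficients", kind, want))
  }
  if (is.null(vcov)) vcov <- matrix(0, want, want)
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == want)) stop("vcov dimension does not match coef")
  if (max(abs(vcov - t(vcov))) > 1e-8 * (1 + max(abs(vcov)))) {
    stop("vcov must be symmetric")
  }
  structure(list(kind = kind, coef = coef, vcov = vcov, n = n,
                 age_domain = as.numeric(age_domain)),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  lab <- switch(x$kind,
    quartic = sprintf("betaG(t) = %.4g + %.4g t + %.4g t^4",
                      x$coef[1], x$coef[2], x$coef[3]),
    linear = sprintf("betaG(t) = %.4g + %.4g t", x$coef[1], x$coef[2]),
    constant = sprintf("betaG = %.4g", x$coef[1]))
  cat(sprintf("Instrument-effect fit (%s): %s  [n = %s]\n",
              x$kind, lab, format(x$n)), sep = "")
  invisible(x)
}

# design row(s) g(t) such that betaG(t) = g(t) . coef
beta_basis <- function(fit, t) {
  switch(fit$kind,
    quartic = cbind(1, t, t^4),
    linear = cbind(1, t),
    constant = cbind(rep(1, length(t))))
}

#' Evaluate a fitted instrument-effect function
#'
#' @param fit A [beta_fit()].
#' @param t Ages (years) within the fit's domain.
#' @return \eqn{\beta_G(t)} (exposure SD per instrument unit).
#' @export
beta_eval <- function(fit, t) {
  drop(beta_basis(fit, t) %*% fit$coef)
}

#' Point estimate and normal confidence interval for beta_G(t)
#'
#' The variance is the delta-method quadratic form
#' \eqn{g(t)^\top \Sigma g(t)} with \eqn{g(t) = (1, t, t^4)} for the quartic
#' model, which expands to
#' \eqn{\mathrm{Var}\,\hat a + t^2 \mathrm{Var}\,\hat b + t^8 \mathrm{Var}\,\hat c
#' + 2t\,\mathrm{Cov}(\hat a,\hat b) + 2t^4 \mathrm{Cov}(\hat a,\hat c)
#' + 2t^5 \mathrm{Cov}(\hat b,\hat c)}.
#'
#' @param fit A [beta_fit()].
#' @param t Ages in years.
#' @param alpha Significance level (default 0.05, i.e. multiplier 1.96).
#' @return \code{data.frame} with \code{t}, \code{estimate}, \code{lower},
#'   \code{upper}, \code{se}.
#' @export
beta_ci <- function(fit, t, alpha = 0.05) {
  G <- beta_basis(fit, t)
  est <- drop(G %*% fit$coef)
  v <- rowSums((G %*% fit$vcov) * G)
  se <- sqrt(pmax(v, 0))
  zq <- stats::qnorm(1 - alpha / 2)
  data.frame(t = t, estimate = est, lower = est - zq * se,
             upper = est + zq * se, se = se)
}

# shared worker: least squares of exposure on instrument x time-basis
fit_beta_model <- function(cohort, kind, instrument, exposure, covariates,
                           event_free_only, age_domain) {
  for (col in c(instrument, exposure, "age_at_assessment", covariates)) {
    if (!col %in% names(cohort)) stop("column absent from cohort: ", col)
  }
  dat <- cohort
  if (event_free_only && "event_free_at_assessment" %in% names(dat)) {
    dat <- dat[dat$event_free_at_assessment, , drop = FALSE]
  } else if (event_free_only && "event_age" %in% names(dat)) {
    keep <- is.na(dat$event_age) | dat$event_age > dat$age_at_assessment
    dat <- dat[keep, , drop = FALSE]
  }
  if (nrow(dat) == 0L) stop("no event-free individuals at assessment")
  tt <- dat$age_at_assessment
  if (kind != "constant" && length(unique(tt)) < 3L) {
    stop("need at least 3 distinct assessment ages to fit a time-varying model")
  }
  g <- dat[[instrument]]
  y <- dat[[exposure]]
  # main age terms absorb any residual age trend of the exposure so the
  # instrument x time block is estimated from the between-genotype contrast
  terms <- switch(kind,
    quartic = data.frame(g = g, g_t = g * tt, g_t4 = g * tt^4),
    linear = data.frame(g = g, g_t = g * tt),
    constant = data.frame(g = g))
  main <- switch(kind,
    quartic = data.frame(t_main = tt, t4_main = tt^4),
    linear = data.frame(t_main = tt),
    constant = if (length(unique(tt)) > 1L) data.frame(t_main = tt)
               else NULL)
  df <- cbind(data.frame(.y = y), terms)
  if (!is.null(main)) df <- cbind(df, main)
  if (length(covariates)) df <- cbind(df, dat[, covariates, drop = FALSE])
  fml <- stats::as.formula(paste(".y ~", paste(names(df)[-1], collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) stop("collinear design in instrument-effect fit")
  vc <- stats::vcov(fit)
  sel <- names(terms)                  # the instrument x time block
  beta_fit(kind, coef = stats::coef(fit)[sel],
           vcov = vc[sel, sel, drop = FALSE],
           n = nrow(dat), age_domain = age_domain)
}

#' Fit the quartic age-varying instrument effect on exposure
#'
#' Least-squares fit of the standardized exposure on the instrument and its
#' interactions with assessment age, \code{t} and \code{t^4} (plus additive
#' covariates), restricted by default to individuals who were event free at
#' assessment.  Assessment ages enter in raw years; evaluation below the
#' youngest observed age follows the fitted polynomial.
#'
#' @param cohort Cohort table with \code{age_at_assessment} and the exposure.
#' @param instrument Instrument column name (dosage or score).
#' @param exposure Exposure column name (SD scale).
#' @param covariates Additional additive covariate columns.
#' @param event_free_only Restrict to event-free-at-assessment individuals.
#' @param age_domain Ages over which downstream evaluation is intended.
#' @return A [beta_fit()] of kind \code{"quartic"}.
#' @export
fit_beta_quartic <- function(cohort, instrument = "instrument",
                             exposure = "exposure_raw",
                             covariates = character(),
                             event_free_only = TRUE,
                             age_domain = c(0, 80)) {
  fit_beta_model(cohort, "quartic", instrument, exposure, covariates,
                 event_free_only, age_domain)
}

#' Fit the linear age-interaction instrument-effect model
#'
#' Companion to [fit_beta_quartic()] with terms \code{(1, t)}; used to
#' classify time dependence and as a fallback when the quartic extrapolation
#' crosses zero at young ages (weak-instrument refusal downstream).
#'
#' @inheritParams fit_beta_quartic
#' @return A [beta_fit()] of kind \code{"linear"}.
#' @export
fit_beta_linear <- function(cohort, instrument = "instrument",
                            exposure = "exposure_raw",
                            covariates = character(),
                            event_free_only = TRUE,
                            age_domain = c(0, 80)) {
  fit_beta_model(cohort, "linear", instrument, exposure, covariates,
                 event_free_only, age_domain)
}

#' Fit the time-constant (misspecified) instrument effect
#'
#' The time-averaged effect used by the first naive Wald comparator.
#'
#' @inheritParams fit_beta_quartic
#' @return A [beta_fit()] of kind \code{"constant"}.
#' @export
fit_beta_constant <- function(cohort, instrument = "instrument",
                              exposure = "exposure_raw",
                              covariates = character(),
                              event_free_only = TRUE,
                              age_domain = c(0, 80)) {
  fit_beta_model(cohort, "constant", instrument, exposure, covariates,
                 event_free_only, age_domain)
}

#' Age-stratified time-fixed instrument effects
#'
#' Per-stratum regression of the exposure on the instrument (plus
#' covariates), for overlay plots and smoke checks of the quartic fit.
#'
#' @param cohort Cohort table.
#' @param age_breaks Cut points defining assessment-age strata.
#' @param instrument,exposure,covariates As in [fit_beta_quartic()].
#' @param event_free_only Restrict to event-free-at-assessment individuals.
#' @return \code{data.frame} with stratum bounds, midpoint age, estimate,
#'   standard error and n.
#' @export
stratified_beta <- function(cohort, age_breaks = seq(40, 70, by = 5),
                            instrument = "instrument",
                            exposure = "exposure_raw",
                            covariates = character(),
                            event_free_only = TRUE) {
  if (length(age_breaks) < 2L) stop("need at least one age stratum")
  dat <- cohort
  if (event_free_only && "event_free_at_assessment" %in% names(dat)) {
    dat <- dat[dat$event_free_at_assessment, , drop = FALSE]
  }
  bin <- cut(dat$age_at_assessment, breaks = age_breaks,
             include.lowest = TRUE, right = FALSE)
  out <- lapply(levels(bin), function(lv) {
    sub <- dat[!is.na(bin) & bin == lv, , drop = FALSE]
    if (nrow(sub) < 3L || length(unique(sub[[instrument]])) < 2L) {
      stop("degenerate age stratum: ", lv)
    }
    f <- fit_beta_model(sub, "constant", instrument, exposure, covariates,
                        event_free_only = FALSE, age_domain = range(sub$age_at_assessment))
    data.frame(stratum = lv,
               age_mid = mean(sub$age_at_assessment),
               estimate = f$coef[1], se = sqrt(f$vcov[1, 1]), n = f$n)
  })
  do.call(rbind, out)
}
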