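#' Expected mean-score offsets per age stratum
#'
#' Fits a linear trend of the stratum mean score on assessment age over
#' \code{[age_lo, age_hi]} and returns, per stratum,
#' \eqn{m_k = } expected mean score at \code{age_lo} minus the expected mean
#' at stratum age \eqn{k} — the amount by which each stratum's mean must be
#' raised for the age trend in the score to vanish.
#'
#' @param cohort Cohort table with \code{age_at_assessment} and the score.
#' @param score_column Score column name (e.g. \code{"pgs"}).
#' @param age_lo,age_hi Age range of the fit (anchor at \code{age_lo}).
#' @param min_per_stratum Minimum individuals per stratum.
#' @return \code{data.frame} with \code{age}, \code{mean_score}, \code{n},
#'   \code{m_k}.
#' @export
expected_offsets <- function(cohort, score_column = "pgs",
                             age_lo = 40, age_hi = 70,
                             min_per_stratum = 30L) {
  age <- cohort$age_at_assessment
  keep <- age >= age_lo & age <= age_hi
  dat <- cohort[keep, , drop = FALSE]
  ages <- sort(unique(dat$age_at_assessment))
  if (length(ages) < 2L) stop("need at least two age strata in the fit range")
  ms <- vapply(ages, function(a) {
    s <- dat[[score_column]][dat$age_at_assessment == a]
    if (length(s) < min_per_stratum) {
      stop(sprintf("age stratum %d has fewer than %d individuals",
                   a, min_per_stratum))
    }
    mean(s)
  }, numeric(1))
  ns <- vapply(ages, function(a) sum(dat$age_at_assessment == a), numeric(1))
  fit <- stats::lm(ms ~ ages, weights = ns)
  fitted_at <- function(a) unname(stats::coef(fit)[1] + stats::coef(fit)[2] * a)
  data.frame(age = ages, mean_score = ms, n = ns,
             m_k = fitted_at(age_lo) - fitted_at(ages))
}

#' Probit resampling correction for age-dependent selection
#'
#' Relative correction for non-representative participation: individuals in
#' a reference set \eqn{D} (assessed below \code{reference_age_cutoff},
#' assumed least affected by selection) stand in for those who opted out.
#' For each age stratum \eqn{k}, reference individuals are appended with
#' probability \eqn{p_i = \Phi(d_i - \mu_k)}, where \eqn{d_i} is the
#' globally standardized exposure, and \eqn{\mu_k} is found by a grid search
#' so that the corrected stratum mean score satisfies
#' \eqn{|\langle s\rangle_{k,corr} - (\langle s\rangle_{k,orig} + m_k)| <
#' \varepsilon}.  Appended rows are exact copies apart from the assigned
#' assessment age and a duplicate flag; only the slope of the mean score
#' over age is rectified, not its absolute level.
#'
#' @param cohort Cohort table with the score and exposure columns.
#' @param score_column Score column (e.g. \code{"pgs"}).
#' @param exposure Exposure column entering the probit.
#' @param reference_age_cutoff Reference set: assessed strictly below this
#'   age.
#' @param age_lo,age_hi Strata to correct (inclusive).
#' @param tolerance Acceptance tolerance \eqn{\varepsilon} in score SD.
#' @param offsets Optional precomputed offset table as returned by
#'   [expected_offsets()] (columns \code{age}, \code{mean_score}, \code{n},
#'   \code{m_k}); computed from the cohort when NULL.
#' @param mu_grid Grid searched for \eqn{\mu_k}.
#' @param max_tries Random draws attempted per grid value.
#' @param seed Integer seed.
#' @return List with \code{cohort} (expanded table, appended rows flagged by
#'   \code{selection_duplicate}) and \code{plan} (per-stratum \eqn{\mu_k},
#'   offsets, appended counts, achieved residuals); class
#'   \code{"selection_plan"} on the plan.
#' @export
rectify_sample <- function(cohort, score_column = "pgs",
                           exposure = "exposure_raw",
                           reference_age_cutoff = 45,
                           age_lo = 40, age_hi = 70,
                           tolerance = 0.005,
                           offsets = NULL,
                           mu_grid = seq(-4, 4, by = 0.01),
                           max_tries = 5L, seed = 1L) {
  off <- if (is.null(offsets)) {
    expected_offsets(cohort, score_column, age_lo, age_hi)
  } else {
    offsets
  }
  ref <- cohort[cohort$age_at_assessment < reference_age_cutoff, , drop = FALSE]
  if (nrow(ref) == 0L) stop("empty reference set below the age cutoff")
  d <- (ref[[exposure]] - mean(cohort[[exposure]])) /
    stats::sd(cohort[[exposure]])
  s_ref <- ref[[score_column]]
  set.seed(seed)

  appended <- list()
  plan <- off
  plan$mu_k <- NA_real_
  plan$appended <- 0L
  plan$residual <- NA_real_
  for (r in seq_len(nrow(off))) {
    k <- off$age[r]
    target <- off$mean_score[r] + off$m_k[r]
    n_k <- off$n[r]
    sum_k <- off$mean_score[r] * n_k
    # expected corrected mean as a function of mu, for ordering the search;
    # among admissible values prefer the largest mu (fewest appended rows)
    grid <- c(mu_grid, Inf)            # Inf = append nobody
    exp_resid <- vapply(grid, function(mu) {
      p <- stats::pnorm(d - mu)
      abs((sum_k + sum(p * s_ref)) / (n_k + sum(p)) - target)
    }, numeric(1))
    admissible <- which(exp_resid < tolerance)
    cand <- if (length(admissible)) {
      grid[admissible[order(grid[admissible], decreasing = TRUE)]]
    } else {
      grid[order(exp_resid)]
    }
    best <- list(resid = Inf, sel = integer(0), mu = NA_real_)
    for (mu in cand[seq_len(min(50L, length(cand)))]) {
      p <- stats::pnorm(d - mu)
      for (try in seq_len(max_tries)) {
        sel <- which(stats::runif(length(p)) < p)
        m_corr <- (sum_k + sum(s_ref[sel])) / (n_k + length(sel))
        resid <- abs(m_corr - target)
        if (resid < best$resid) best <- list(resid = resid, sel = sel, mu = mu)
        if (best$resid < tolerance) break
      }
      if (best$resid < tolerance) break
    }
    if (best$resid >= tolerance) {
      warning(sprintf(
        "stratum %d: tolerance %.4g unattainable on the mu grid (best residual %.4g)",
        k, tolerance, best$resid))
    }
    plan$mu_k[r] <- best$mu
    plan$appended[r] <- length(best$sel)
    plan$residual[r] <- best$resid
    if (length(best$sel)) {
      add <- ref[best$sel, , drop = FALSE]
      add$age_at_assessment <- k
      appended[[length(appended) + 1L]] <- add
    }
  }
  cohort$selection_duplicate <- FALSE
  if (length(appended)) {
    add <- do.call(rbind, appended)
    add$selection_duplicate <- TRUE
    expanded <- rbind(cohort, add)
  } else {
    expanded <- cohort
  }
  class(plan) <- c("selection_plan", "data.frame")
  list(cohort = expanded, plan = plan)
}
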