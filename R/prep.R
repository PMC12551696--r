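#' Z-transform the exposure within sex and age strata
#'
#' Standardizes the raw exposure to mean 0 and SD 1 (denominator n-1) within
#' each sex-by-integer-assessment-age stratum.  To avoid small outermost
#' strata, ages at or below \code{low_pool} are pooled into one stratum and
#' ages at or above \code{high_pool} into another.  Removes age trends in
#' both location and scale so the age-varying instrument effect is expressed
#' on a common SD scale.
#'
#' @param cohort Cohort table with \code{exposure_raw},
#'   \code{age_at_assessment} and (optionally) \code{sex}.
#' @param low_pool,high_pool Pooling cut points in years.
#' @return The cohort with an \code{exposure_z} column added (replaced if
#'   present).
#' @export
ztransform_by_stratum <- function(cohort, low_pool = 40, high_pool = 70) {
  if (!"exposure_raw" %in% names(cohort)) stop("exposure_raw column required")
  if (!"age_at_assessment" %in% names(cohort)) {
    stop("age_at_assessment column required")
  }
  age <- pmin(pmax(cohort$age_at_assessment, low_pool), high_pool)
  strata <- if ("sex" %in% names(cohort)) {
    interaction(cohort$sex, age, drop = TRUE)
  } else {
    factor(age)
  }
  sizes <- table(strata)
  if (any(sizes < 2L)) {
    stop("stratum with fewer than 2 individuals cannot be standardized: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  x <- cohort$exposure_raw
  m <- stats::ave(x, strata, FUN = mean)
  s <- stats::ave(x, strata, FUN = stats::sd)
  if (any(s == 0)) stop("zero within-stratum variance; cannot standardize")
  cohort$exposure_z <- (x - m) / s
  cohort
}

#' Polygenic score from dosages and a weight table
#'
#' \eqn{\mathrm{PGS}_i = \sum_j w_j g_{ij}} over the SNPs in \code{weights}.
#' Missing dosages are mean-imputed to twice the allele frequency observed in
#' the scored sample.
#'
#' @param genotypes \code{data.frame} with one dosage column per SNP
#'   (values in \eqn{[0, 2]}).
#' @param weights \code{data.frame} with columns \code{snp_id} and
#'   \code{weight} (effect-allele aligned upstream); optional columns
#'   \code{effect_allele}, \code{source_split}.
#' @return Numeric score per individual.
#' @export
compute_pgs <- function(genotypes, weights) {
  if (anyDuplicated(weights$snp_id)) stop("duplicate snp_id in weights")
  if (any(!is.finite(weights$weight))) stop("weights must be finite")
  miss <- setdiff(weights$snp_id, names(genotypes))
  if (length(miss)) {
    stop("SNP(s) absent from genotype table: ", paste(miss, collapse = ", "))
  }
  G <- as.matrix(genotypes[, weights$snp_id, drop = FALSE])
  if (any(G < 0 | G > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  unname(drop(G %*% weights$weight))
}

#' Cross-fitted polygenic score over two cohort splits
#'
#' Scores the individuals of split A with the weights derived in split B and
#' vice versa, standardizes the score to zero mean and unit variance within
#' each split, and re-merges the splits.  No individual is ever scored with
#' weights estimated from its own split; the scoring split is recorded in
#' \code{pgs_weights_from}.
#'
#' @param cohort_a,cohort_b Disjoint cohort tables (by \code{id}) carrying
#'   the dosage columns.
#' @param weights_a,weights_b Weight tables derived in split A and B
#'   respectively.
#' @return Merged cohort with columns \code{pgs} (standardized within
#'   split), \code{pgs_split} (A or B) and \code{pgs_weights_from}.
#' @export
crossfit_pgs <- function(cohort_a, cohort_b, weights_a, weights_b) {
  if (length(intersect(cohort_a$id, cohort_b$id))) {
    stop("cohort splits overlap by id; cross-fitting requires disjoint splits")
  }
  zstd <- function(x) (x - mean(x)) / stats::sd(x)
  a <- cohort_a
  a$pgs <- zstd(compute_pgs(cohort_a, weights_b))
  a$pgs_split <- "A"
  a$pgs_weights_from <- "B"
  b <- cohort_b
  b$pgs <- zstd(compute_pgs(cohort_b, weights_a))
  b$pgs_split <- "B"
  b$pgs_weights_from <- "A"
  rbind(a, b)
}

#' Steiger test for two dependent, overlapping correlations
#'
#' Tests whether the instrument explains more variance in the exposure than
#' in the outcome.  Both correlations are Fisher-z transformed,
#' \eqn{Z_* = \mathrm{atanh}(\rho_*)}, and the statistic is
#' \deqn{z = (Z_{g,x} - Z_{g,y})\sqrt{\frac{N-3}{2h(1-\rho_{x,y})}},\quad
#'  h = \frac{1 - f\bar\rho^2}{1-\bar\rho^2},\quad
#'  f = \frac12\,\frac{1-\rho_{x,y}}{1-\bar\rho^2},}
#' with \eqn{\bar\rho^2 = (\rho_{g,x}^2 + \rho_{g,y}^2)/2}.  The p-value is
#' one-sided against \eqn{H_1: \rho_{g,x} > \rho_{g,y}} (upper normal tail);
#' a two-sided variant is available but off by default.
#'
#' @param rho_gx,rho_gy Instrument-exposure and instrument-outcome
#'   correlations (|rho| < 1); vectorized.
#' @param n Sample size (> 3).
#' @param rho_xy Exposure-outcome correlation (see [estimate_rho_xy()]).
#' @param two_sided Return the two-sided p-value instead.
#' @return \code{data.frame} with \code{z} and \code{p}.
#' @export
steiger_test <- function(rho_gx, rho_gy, n, rho_xy, two_sided = FALSE) {
  if (any(abs(c(rho_gx, rho_gy, rho_xy)) >= 1)) {
    stop("correlations must satisfy |rho| < 1 (Fisher transform undefined)")
  }
  if (any(n <= 3)) stop("need n > 3")
  zx <- atanh(rho_gx)
  zy <- atanh(rho_gy)
  rb2 <- (rho_gx^2 + rho_gy^2) / 2
  f <- 0.5 * (1 - rho_xy) / (1 - rb2)
  h <- (1 - f * rb2) / (1 - rb2)
  z <- (zx - zy) * sqrt((n - 3) / (2 * h * (1 - rho_xy)))
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  data.frame(z = z, p = p)
}

#' Ratio-median estimate of the exposure-outcome correlation
#'
#' Under the forward model the per-SNP correlations satisfy
#' \eqn{\rho_{g,y} = \rho_{x,y}\,\rho_{g,x}}; the exposure-outcome
#' correlation is estimated as the median of \eqn{\rho_{g,y}/\rho_{g,x}}
#' over SNPs.
#'
#' @param rho_gx,rho_gy Per-SNP correlation vectors.
#' @return Scalar estimate of \eqn{\rho_{x,y}}.
#' @export
estimate_rho_xy <- function(rho_gx, rho_gy) {
  if (length(rho_gx) != length(rho_gy)) stop("length mismatch")
  stats::median(rho_gy / rho_gx)
}

#' Steiger filtering with Benjamini-Hochberg correction
#'
#' Applies [steiger_test()] per SNP, adjusts the one-sided p-values with the
#' Benjamini-Hochberg step-up procedure, and keeps SNPs with
#' \eqn{q \le} \code{fdr}; the removed SNPs fail to explain significantly
#' more variance in the exposure than in the outcome (possible reverse
#' causation).
#'
#' @param snps \code{data.frame} with columns \code{snp_id}, \code{rho_gx},
#'   \code{rho_gy}.
#' @param n Sample size used for the correlations.
#' @param rho_xy Exposure-outcome correlation; estimated from the SNP set
#'   via [estimate_rho_xy()] when NULL.
#' @param fdr FDR threshold.
#' @return The input with \code{z}, \code{p}, \code{q} and logical
#'   \code{keep} appended; class \code{"steiger_result"}.
#' @export
steiger_filter <- function(snps, n, rho_xy = NULL, fdr = 0.05) {
  if (nrow(snps) < 1L) stop("need at least one SNP")
  if (is.null(rho_xy)) rho_xy <- estimate_rho_xy(snps$rho_gx, snps$rho_gy)
  ts <- steiger_test(snps$rho_gx, snps$rho_gy, n, rho_xy)
  snps$z <- ts$z
  snps$p <- ts$p
  snps$q <- stats::p.adjust(ts$p, method = "BH")
  snps$keep <- snps$q <= fdr
  attr(snps, "rho_xy") <- rho_xy
  class(snps) <- c("steiger_result", "data.frame")
  snps
}

#' Per-SNP correlations with exposure and a binary outcome
#'
#' Convenience for [steiger_filter()] on a cohort: \eqn{\rho_{g,x}} is the
#' Pearson correlation of each dosage column with the exposure, and
#' \eqn{\rho_{g,y}} the point-biserial correlation with the indicator of an
#' event by \code{max_follow_age}.
#'
#' @param cohort Cohort table with dosage columns, the exposure and
#'   \code{event_age}.
#' @param snp_cols Dosage column names.
#' @param exposure Exposure column.
#' @param max_follow_age Event indicator cutoff in years.
#' @return \code{data.frame} with \code{snp_id}, \code{rho_gx},
#'   \code{rho_gy}.
#' @export
snp_cohort_correlations <- function(cohort, snp_cols,
                                    exposure = "exposure_raw",
                                    max_follow_age = 76) {
  y <- as.numeric(!is.na(cohort$event_age) &
                    cohort$event_age <= max_follow_age)
  x <- cohort[[exposure]]
  data.frame(
    snp_id = snp_cols,
    rho_gx = vapply(snp_cols, function(s) stats::cor(cohort[[s]], x),
                    numeric(1)),
    rho_gy = vapply(snp_cols, function(s) stats::cor(cohort[[s]], y),
                    numeric(1))
  )
}
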