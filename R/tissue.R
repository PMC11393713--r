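#' Harmonize effect alleles between two datasets
#'
#' If the effect alleles differ but match after swapping effect/other
#' alleles, the second dataset's beta sign is flipped. Strand-ambiguous
#' (A/T, C/G) variants and irreconcilable allele sets are excluded with a
#' labeled reason.
#'
#' @param record1,record2 Lists/rows with \code{effect_allele},
#'   \code{other_allele}, \code{beta} and \code{se}.
#' @return List: \code{status} ("ok", "strand-ambiguous", "mismatch"),
#'   \code{b1}, \code{se1}, \code{b2}, \code{se2}, \code{flipped}.
#' @export
harmonize_alleles <- function(record1, record2) {
  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (pal(record1$effect_allele, record1$other_allele) ||
      pal(record2$effect_allele, record2$other_allele))
    return(list(status = "strand-ambiguous"))
  same <- record1$effect_allele == record2$effect_allele &&
    record1$other_allele == record2$other_allele
  swapped <- record1$effect_allele == record2$other_allele &&
    record1$other_allele == record2$effect_allele
  if (!same && !swapped) return(list(status = "mismatch"))
  list(status = "ok", b1 = record1$beta, se1 = record1$se,
       b2 = if (swapped) -record2$beta else record2$beta,
       se2 = record2$se, flipped = swapped)
}

#' Storey's pi1 statistic
#'
#' pi0 = #\{p > lambda\} / (m (1 - lambda)) clamped to [0, 1];
#' pi1 = 1 - pi0, the estimated fraction of true associations among lookup
#' p values (the replication rate).
#'
#' @param p_values P values in (0, 1].
#' @param lambda Tuning parameter (default 0.5).
#' @return pi1 in [0, 1].
#' @export
estimate_pi1 <- function(p_values, lambda = 0.5) {
  if (!length(p_values)) stopf("empty p-value vector")
  if (lambda <= 0 || lambda >= 1) stopf("lambda must be in (0, 1)")
  pi0 <- sum(p_values > lambda) / (length(p_values) * (1 - lambda))
  1 - min(max(pi0, 0), 1)
}

#' Error-aware effect correlation between two datasets (r_b)
#'
#' Estimates the correlation of true effect sizes across two datasets,
#' correcting the naive Pearson correlation for estimation error in both:
#' r_b = [cov(b1, b2) - error_corr mean(se1 se2)] /
#' sqrt[(var(b1) - mean(se1^2)) (var(b2) - mean(se2^2))], clamped to
#' [-1, 1].
#'
#' @param b1,se1,b2,se2 Harmonized effect estimates and SEs (>= 10 pairs).
#' @param error_corr Correlation of estimation errors from sample overlap
#'   (default 0 for non-overlapping cohorts).
#' @return r_b in [-1, 1].
#' @export
estimate_rb <- function(b1, se1, b2, se2, error_corr = 0) {
  if (length(b1) < 10) stopf("need >= 10 effect pairs")
  if (any(se1 < 0) || any(se2 < 0)) stopf("SEs must be >= 0")
  num <- cov(b1, b2) - error_corr * mean(se1 * se2)
  d1 <- var(b1) - mean(se1^2)
  d2 <- var(b2) - mean(se2^2)
  if (d1 <= 0 || d2 <= 0) stopf("noise exceeds signal in one dataset")
  min(max(num / sqrt(d1 * d2), -1), 1)
}

#' Bonferroni validation count
#'
#' @param lookup_p P values looked up in the validation dataset.
#' @param n_tests Number of tests (>= 1).
#' @return List: \code{threshold} = 0.05 / n_tests, \code{validated} =
#'   count of p below it.
#' @export
bonferroni_validate <- function(lookup_p, n_tests) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  thr <- 0.05 / n_tests
  list(threshold = thr, validated = sum(lookup_p < thr))
}
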