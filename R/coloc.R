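#' Per-variant prior configuration for colocalization
#'
#' @param p1,p2,p12 Prior probabilities that a variant is associated with
#'   trait 1 only, trait 2 only, or both. All must be positive and
#'   p1 + p2 + p12 < 1.
#' @param provenance Optional record of the counts the priors came from.
#' @return List of class \code{prior_config}.
#' @export
prior_config <- function(p1, p2, p12, provenance = NULL) {
  if (any(c(p1, p2, p12) <= 0)) stopf("priors must be > 0")
  if (p1 + p2 + p12 >= 1) stopf("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12, provenance = provenance),
            class = "prior_config")
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a single-variant association summary (beta, se) and a normal effect
#' prior N(0, W): with V = se^2, z = beta/se and r = W/(V + W),
#' log ABF = 0.5 log(1 - r) + r z^2 / 2.
#'
#' @param beta,se Effect and standard error (vectorized); se > 0.
#' @param prior_sd Prior effect-size SD (sqrt(W)); default 0.15 on the
#'   standardized-trait scale.
#' @return Log approximate Bayes factors.
#' @export
wakefield_log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stopf("se must be > 0")
  W <- prior_sd^2
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log(1 - r) + r * z^2 / 2
}

#' Bayesian colocalization of two traits from summary statistics
#'
#' Enumerates the five hypotheses for a region: H0 no association, H1/H2
#' trait-1-only / trait-2-only, H3 two distinct causal variants, H4 one
#' shared causal variant. With per-variant log-ABFs l1, l2 the unnormalized
#' weights are 1, p1*sum(e^l1), p2*sum(e^l2),
#' p1*p2*sum_\{i != j\}(e^\{l1(i)+l2(j)\}) and p12*sum(e^\{l1+l2\}); posteriors
#' are computed in log-sum-exp arithmetic.
#'
#' @param region List with \code{lbf1} and \code{lbf2} (per-variant log
#'   ABFs, same variant order), or \code{beta1/se1/beta2/se2} from which
#'   ABFs are computed with \code{prior_sd}.
#' @param priors A \code{prior_config}.
#' @param prior_sd ABF prior SD used when betas/SEs are supplied.
#' @return List of class \code{coloc_result}: \code{pp} (PP0..PP4),
#'   \code{n_variants}, \code{priors}.
#' @export
coloc_abf <- function(region, priors, prior_sd = 0.15) {
  l1 <- region$lbf1 %||% wakefield_log_abf(region$beta1, region$se1, prior_sd)
  l2 <- region$lbf2 %||% wakefield_log_abf(region$beta2, region$se2, prior_sd)
  if (!length(l1) || length(l1) != length(l2)) stopf("empty or mismatched region")
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  ## sum over i != j = (sum_i)(sum_j) - sum_i(i==j), done stably in log space
  d <- ls12 - (ls1 + ls2)
  lcross <- if (d >= 0) -Inf else ls1 + ls2 + log1p(-exp(d))
  lw <- c(H0 = 0,
          H1 = log(priors$p1) + ls1,
          H2 = log(priors$p2) + ls2,
          H3 = log(priors$p1) + log(priors$p2) + lcross,
          H4 = log(priors$p12) + ls12)
  z <- logsumexp(lw)
  pp <- exp(lw - z)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = length(l1), priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d variants: %s\n", x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

#' Count-derived colocalization priors
#'
#' Sets p1 + p12 to the ratio of independent trait-1 signals to variants
#' tested for trait 1, p2 + p12 analogously for trait 2, and
#' p12 = shared_fraction * (p1 + p12); p1 and p2 follow by subtraction.
#'
#' @param n_indep_1,n_tested_1 Independent signal and tested-variant counts
#'   for trait 1 (e.g. the eQTL analysis).
#' @param n_indep_2,n_tested_2 The same for trait 2 (e.g. the meQTL
#'   analysis).
#' @param shared_fraction Probability that a trait-1 lead variant is also a
#'   trait-2 lead, in (0, 1).
#' @return A \code{prior_config} with provenance.
#' @export
priors_from_counts <- function(n_indep_1, n_tested_1, n_indep_2, n_tested_2,
                               shared_fraction) {
  if (any(c(n_indep_1, n_tested_1, n_indep_2, n_tested_2) <= 0))
    stopf("counts must be positive")
  if (shared_fraction <= 0 || shared_fraction >= 1)
    stopf("shared_fraction must be in (0, 1)")
  r1 <- n_indep_1 / n_tested_1
  r2 <- n_indep_2 / n_tested_2
  p12 <- shared_fraction * r1
  p1 <- r1 - p12
  p2 <- r2 - p12
  if (p1 <= 0 || p2 <= 0) stopf("resulting p1 or p2 <= 0")
  prior_config(p1, p2, p12, provenance = list(
    n_indep_1 = n_indep_1, n_tested_1 = n_tested_1,
    n_indep_2 = n_indep_2, n_tested_2 = n_tested_2,
    shared_fraction = shared_fraction))
}

## Prior probability of each hypothesis with flat evidence (all log-ABFs 0)
#' @keywords internal
#' @noRd
prior_hypothesis_probs <- function(priors, n) {
  w <- c(1, priors$p1 * n, priors$p2 * n,
         priors$p1 * priors$p2 * n * (n - 1), priors$p12 * n)
  w / sum(w)
}

#' Select the shared-signal fraction for the p12 prior
#'
#' For each candidate fraction, computes count-derived priors, runs
#' colocalization on every region pair and compares the posterior expectation
#' of colocalization (sum of PP4) to the prior expectation (sum of the
#' flat-evidence H4 probabilities). Returns the candidate minimizing the
#' absolute log ratio of the two (ties to the smallest candidate).
#'
#' @param pairs List of regions (see \code{\link{coloc_abf}}).
#' @param counts List with n_indep_1, n_tested_1, n_indep_2, n_tested_2.
#' @param candidates Candidate shared fractions
#'   (default c(0.10, 0.25, 0.50, 0.75)).
#' @param prior_sd ABF prior SD.
#' @return List: \code{shared_fraction}, \code{priors}, \code{table}
#'   (per-candidate prior/posterior expectations).
#' @export
select_shared_fraction <- function(pairs, counts,
                                   candidates = c(0.10, 0.25, 0.50, 0.75),
                                   prior_sd = 0.15) {
  if (!length(pairs)) stopf("empty pair list")
  if (!length(candidates)) stopf("empty candidate list")
  candidates <- sort(candidates)
  tab <- data.frame(shared_fraction = candidates, prior_exp = NA_real_,
                    posterior_exp = NA_real_)
  for (k in seq_along(candidates)) {
    pr <- priors_from_counts(counts$n_indep_1, counts$n_tested_1,
                             counts$n_indep_2, counts$n_tested_2,
                             candidates[k])
    prior_e <- 0; post_e <- 0
    for (rg in pairs) {
      nv <- length(rg$lbf1 %||% rg$beta1)
      prior_e <- prior_e + prior_hypothesis_probs(pr, nv)[5]
      post_e <- post_e + coloc_abf(rg, pr, prior_sd)$pp["PP4"]
    }
    tab$prior_exp[k] <- prior_e
    tab$posterior_exp[k] <- post_e
  }
  crit <- abs(log(tab$posterior_exp / tab$prior_exp))
  ## ties (within numerical noise) resolve to the smallest candidate
  best <- which(crit <= min(crit) + 1e-9)[1]
  pr <- priors_from_counts(counts$n_indep_1, counts$n_tested_1,
                           counts$n_indep_2, counts$n_tested_2,
                           candidates[best])
  list(shared_fraction = candidates[best], priors = pr, table = tab)
}

#' Multi-signal colocalization via exact conditional decomposition
#'
#' Relaxes the single-causal-variant assumption: for each pair of
#' independent signals (one per trait), per-variant summary statistics are
#' recomputed conditioning each trait on its \emph{other} selected signals
#' (exact regression, individual-level data), and single-signal
#' colocalization is run on the conditional summaries.
#'
#' @param y1,y2 Adjusted trait vectors (e.g. expression, methylation).
#' @param region_geno \code{genotype_matrix} of the region's shared variants.
#' @param signals1,signals2 \code{signal_set}s of the two traits (selected
#'   variant IDs must appear in \code{region_geno}).
#' @param priors A \code{prior_config}.
#' @param prior_sd ABF prior SD.
#' @return List of class \code{multi_coloc}: \code{results} (data.frame
#'   signal1, signal2, PP0..PP4), \code{max_pp4}.
#' @export
multi_signal_coloc <- function(y1, y2, region_geno, signals1, signals2,
                               priors, prior_sd = 0.15) {
  if (!length(signals1$variants) || !length(signals2$variants))
    stopf("need >= 1 independent signal per trait")
  G <- region_geno$dosage
  ids <- region_geno$variants$id
  cond_summaries <- function(y, keep_out) {
    ## per-variant beta/se conditioning on the other selected signals
    if (length(keep_out)) {
      Xc <- cbind(1, t(G[keep_out, , drop = FALSE]))
      y <- as.numeric(qr.resid(qr(Xc), y))
    }
    n <- length(y)
    t(vapply(seq_len(nrow(G)), function(j) {
      g <- G[j, ]
      s <- joint_stats(y, cbind(1, g))
      c(s$beta[2], s$se[2])
    }, numeric(2)))
  }
  res <- NULL
  for (s1 in signals1$variants) for (s2 in signals2$variants) {
    o1 <- setdiff(signals1$variants, s1)
    o2 <- setdiff(signals2$variants, s2)
    sm1 <- cond_summaries(y1, match(o1, ids))
    sm2 <- cond_summaries(y2, match(o2, ids))
    cr <- coloc_abf(list(beta1 = sm1[, 1], se1 = sm1[, 2],
                         beta2 = sm2[, 1], se2 = sm2[, 2]),
                    priors, prior_sd)
    res <- rbind(res, data.frame(signal1 = s1, signal2 = s2,
                                 t(cr$pp), stringsAsFactors = FALSE))
  }
  names(res)[3:7] <- paste0("PP", 0:4)
  structure(list(results = res, max_pp4 = max(res$PP4)),
            class = "multi_coloc")
}
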