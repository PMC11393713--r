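#' Scan configuration for QTL mapping
#'
#' @param cis_window Cis window in bp (default 1e6). A variant is cis to a
#'   feature iff on the same chromosome and strictly closer than the window
#'   (exactly 1 Mbp is assigned to trans).
#' @param cis_p,trans_p Nominal retention thresholds for emitted cis / trans
#'   associations (defaults 1e-3 and 1e-5).
#' @param n_perm Number of genome-wide permutations for the twin-aware FDR
#'   (default 20); gene-level mode uses 1000 per-feature permutations.
#' @param fdr_level Target FDR (default 0.05).
#' @param seed Seed for the permutation scheme.
#' @return A list of class \code{scan_config}.
#' @export
scan_config <- function(cis_window = 1e6, cis_p = 1e-3, trans_p = 1e-5,
                        n_perm = 20, fdr_level = 0.05, seed = 1L) {
  if (cis_window <= 0) stopf("cis_window must be > 0")
  if (any(c(cis_p, trans_p) <= 0) || any(c(cis_p, trans_p) >= 1))
    stopf("retention thresholds must be in (0,1)")
  structure(list(cis_window = cis_window, cis_p = cis_p, trans_p = trans_p,
                 n_perm = n_perm, fdr_level = fdr_level,
                 seed = as.integer(seed)), class = "scan_config")
}

#' Classify variant-feature pairs as cis or trans
#'
#' Cis iff same chromosome and |variant position - feature anchor| strictly
#' less than the window; otherwise trans (different chromosome included).
#'
#' @param var_chrom,var_pos Variant coordinates (1-based).
#' @param feat_chrom,feat_pos Feature anchor coordinates (CpG position or
#'   gene TSS).
#' @param window Cis window in bp.
#' @return Character vector "cis"/"trans".
#' @export
partition_cis_trans <- function(var_chrom, var_pos, feat_chrom, feat_pos,
                                window = 1e6) {
  if (any(is.na(var_chrom)) || any(is.na(feat_chrom)))
    stopf("unknown chromosome")
  ifelse(var_chrom == feat_chrom & abs(var_pos - feat_pos) < window,
         "cis", "trans")
}

#' Linear association scan between adjusted phenotypes and genotypes
#'
#' For every feature, fits the simple linear model value ~ dosage for all
#' variants (the phenotype is assumed fully adjusted upstream; family
#' structure is handled by residualization and by the permutation scheme).
#' Betas are oriented to the minor allele: variants whose coded allele has
#' frequency > 0.5 are recoded and the beta sign flipped. Emits every cis
#' pair with p below the cis retention threshold and every trans pair below
#' the trans threshold, plus each feature's best cis and trans p over all
#' tested pairs (needed for permutation FDR).
#'
#' @param resid A \code{residual_matrix} (or list with \code{values} and
#'   \code{features}).
#' @param geno A \code{genotype_matrix}.
#' @param cfg A \code{scan_config}.
#' @return List of class \code{qtl_scan}: \code{hits} (variant, feature,
#'   coordinates, beta, se, t, p, distance, class) and \code{best}
#'   (per-feature best cis/trans p).
#' @export
association_scan <- function(resid, geno, cfg = scan_config()) {
  Y <- resid$values
  G <- geno$dosage
  if (ncol(Y) != ncol(G) ||
      (!is.null(colnames(Y)) && !identical(colnames(Y), colnames(G))))
    stopf("sample mismatch between phenotype and genotype matrices")
  n <- ncol(Y)
  v <- geno$variants
  ## orient to minor allele
  f <- rowMeans(G) / 2
  flip <- f > 0.5
  if (any(flip)) G[flip, ] <- 2 - G[flip, ]

  gc <- G - rowMeans(G)
  sg2 <- rowSums(gc^2)
  sg2[sg2 == 0] <- NA  # monomorphic: undefined, drop
  hits <- vector("list", nrow(Y))
  best <- matrix(NA_real_, nrow(Y), 2,
                 dimnames = list(NULL, c("cis", "trans")))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    yc <- y - mean(y)
    sy2 <- sum(yc^2)
    b <- as.numeric(gc %*% yc) / sg2
    r2 <- b^2 * sg2 / sy2
    tt <- sign(b) * sqrt(pmax(r2, 0) * (n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    se <- b / tt
    cls <- partition_cis_trans(v$chrom, v$pos, resid$features$chrom[i],
                               resid$features$pos[i], cfg$cis_window)
    ok <- !is.na(p)
    best[i, "cis"] <- suppressWarnings(min(p[ok & cls == "cis"], Inf))
    best[i, "trans"] <- suppressWarnings(min(p[ok & cls == "trans"], Inf))
    keep <- ok & ((cls == "cis" & p < cfg$cis_p) |
                    (cls == "trans" & p < cfg$trans_p))
    if (any(keep)) {
      hits[[i]] <- data.frame(
        variant = v$id[keep], feature = resid$features$id[i],
        var_chrom = v$chrom[keep], var_pos = v$pos[keep],
        feat_chrom = resid$features$chrom[i],
        feat_pos = resid$features$pos[i],
        beta = b[keep], se = se[keep], t = tt[keep], p = p[keep],
        distance = ifelse(v$chrom[keep] == resid$features$chrom[i],
                          v$pos[keep] - resid$features$pos[i], NA),
        class = cls[keep], stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) hits <- data.frame(
    variant = character(0), feature = character(0), var_chrom = integer(0),
    var_pos = integer(0), feat_chrom = integer(0), feat_pos = integer(0),
    beta = numeric(0), se = numeric(0), t = numeric(0), p = numeric(0),
    distance = numeric(0), class = character(0))
  best <- data.frame(feature = resid$features$id,
                     best_cis_p = ifelse(is.finite(best[, "cis"]),
                                         best[, "cis"], NA),
                     best_trans_p = ifelse(is.finite(best[, "trans"]),
                                           best[, "trans"], NA),
                     stringsAsFactors = FALSE)
  structure(list(hits = hits, best = best), class = "qtl_scan")
}

#' Twin-aware permutation of genotype columns
#'
#' Permutes genotype columns so twin pairs move as units and only within
#' zygosity groups: each pair's column-pair is reassigned to another pair of
#' the same zygosity, and singletons are permuted among singletons. The
#' multiset of columns (and within-pair genotype sharing) is preserved, so
#' the null distribution respects the family structure.
#'
#' @param geno A \code{genotype_matrix}.
#' @param ped The matching \code{twin_pedigree}.
#' @param seed Optional seed.
#' @return A \code{genotype_matrix} with permuted columns.
#' @export
twin_aware_permutation <- function(geno, ped, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- pair_index(ped)
  ord <- seq_len(ncol(geno$dosage))
  for (z in c("MZ", "DZ")) {
    sel <- which(idx$zygosity == z)
    if (length(sel) > 1) {
      perm <- sample(sel)
      for (k in seq_along(sel)) {
        dest <- idx$pairs[[sel[k]]]
        src <- idx$pairs[[perm[k]]]
        ord[dest] <- src
      }
    }
  }
  if (length(idx$singletons) > 1)
    ord[idx$singletons] <- sample(idx$singletons)
  out <- geno
  out$dosage <- geno$dosage[, ord, drop = FALSE]
  colnames(out$dosage) <- colnames(geno$dosage)
  out
}

#' Permutation-based genome-wide FDR thresholds
#'
#' Candidate thresholds are the observed per-feature best p values. For each
#' candidate t, FDR(t) = [mean over permutations of the number of permuted
#' best p <= t] / [number of observed best p <= t]; the estimate is made
#' monotone by a running minimum from small t upward, and the largest t with
#' FDR(t) <= level is returned. If no candidate qualifies the threshold is
#' NA ("no threshold").
#'
#' @param observed_best Per-feature best (minimum) p values.
#' @param permuted_best Matrix (features x permutations) of per-feature best
#'   p values under permutation, or a vector for one permutation.
#' @param level FDR level (default 0.05).
#' @return List of class \code{fdr_thresholds}: \code{threshold},
#'   \code{achieved_fdr}, \code{n_discoveries}.
#' @export
permutation_fdr_thresholds <- function(observed_best, permuted_best,
                                       level = 0.05) {
  obs <- observed_best[!is.na(observed_best)]
  if (!length(obs)) stopf("no observed best p values")
  pm <- as.matrix(permuted_best)
  n_perm <- ncol(pm)
  if (n_perm < 1) stopf("need >= 1 permutation")
  perm_all <- as.numeric(pm)
  perm_all <- perm_all[!is.na(perm_all)]
  cand <- sort(obs)
  n_obs_le <- seq_along(cand)  # obs sorted: #obs <= cand[k] is k (ties ok below)
  n_obs_le <- vapply(cand, function(t) sum(obs <= t), numeric(1))
  n_perm_le <- vapply(cand, function(t) sum(perm_all <= t), numeric(1)) / n_perm
  fdr <- n_perm_le / n_obs_le
  fdr <- monotone_fdr(fdr)
  ok <- which(fdr <= level)
  if (!length(ok)) {
    return(structure(list(threshold = NA_real_, achieved_fdr = NA_real_,
                          n_discoveries = 0L), class = "fdr_thresholds"))
  }
  k <- max(ok)
  structure(list(threshold = cand[k], achieved_fdr = fdr[k],
                 n_discoveries = n_obs_le[k]), class = "fdr_thresholds")
}

## Monotone FDR estimate: FDR*(t) = min over t' >= t of FDR(t'), so the
## estimate is non-decreasing in t and "largest t with FDR <= level" is
## well defined.
#' @keywords internal
#' @noRd
monotone_fdr <- function(x) rev(cummin(rev(x)))

#' Gene-level FDR via beta-approximated permutation p values
#'
#' Per feature, fits a two-parameter beta distribution by maximum likelihood
#' to the feature's permutation minima and converts the observed minimum p to
#' an empirical p via the fitted beta CDF. Empirical p values are corrected
#' across features with the Storey-Tibshirani procedure; features with
#' q <= level are significant, and each significant feature's nominal
#' threshold is the beta quantile at the empirical-p value sitting at the
#' q = level boundary.
#'
#' @param observed Per-feature observed minimum p.
#' @param perm_minima Matrix (features x permutations) of permutation minima
#'   (>= 100 permutations).
#' @param level FDR level (default 0.05).
#' @param lambda Storey pi0 tuning parameter (default 0.5).
#' @return data.frame: feature index, beta shape1/shape2, empirical p, q,
#'   significant flag, nominal threshold (NA when not significant).
#' @export
gene_level_beta_fdr <- function(observed, perm_minima, level = 0.05,
                                lambda = 0.5) {
  pm <- as.matrix(perm_minima)
  if (ncol(pm) < 100) stopf("need >= 100 permutation minima per feature")
  m <- length(observed)
  shapes <- t(vapply(seq_len(m), function(i) fit_beta_ml(pm[i, ]), numeric(2)))
  emp <- pbeta(observed, shapes[, 1], shapes[, 2])
  q <- storey_qvalue(emp, lambda = lambda)
  sig <- q <= level
  thr <- rep(NA_real_, m)
  if (any(sig)) {
    p_star <- max(emp[sig])  # empirical-p cutoff at the q = level boundary
    thr[sig] <- qbeta(p_star, shapes[sig, 1], shapes[sig, 2])
  }
  data.frame(feature = seq_len(m), shape1 = shapes[, 1], shape2 = shapes[, 2],
             empirical_p = emp, q = q, significant = sig,
             nominal_threshold = thr)
}

## Two-parameter beta MLE (log-parameterized Nelder-Mead, moment start).
#' @keywords internal
#' @noRd
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  if (length(unique(x)) < 2) stopf("degenerate permutation minima (all equal)")
  mu <- mean(x); v <- var(x)
  k <- max(mu * (1 - mu) / v - 1, 0.1)
  start <- log(c(max(mu * k, 0.05), max((1 - mu) * k, 0.05)))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(dbeta(x, a, b, log = TRUE))
  }
  o <- optim(start, nll, method = "Nelder-Mead",
             control = list(reltol = 1e-10, maxit = 1000))
  exp(o$par)
}

#' Storey-Tibshirani q values
#'
#' pi0 is estimated at a single lambda: pi0 = #\{p > lambda\} /
#' (m (1 - lambda)), clamped to [0, 1] (and away from 0); q values are the
#' pi0-scaled BH step-up quantities.
#'
#' @param p P values in (0, 1].
#' @param lambda Tuning parameter in (0, 1), default 0.5.
#' @return Vector of q values in the input order.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  if (!length(p)) stopf("empty p-value vector")
  m <- length(p)
  pi0 <- min(max(sum(p > lambda) / (m * (1 - lambda)), 1 / m), 1)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  run <- 1
  for (i in ord) {
    rankp <- sum(p <= p[i])
    run <- min(run, pi0 * m * p[i] / rankp)
    q[i] <- run
  }
  q
}
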