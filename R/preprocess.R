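#' Methylation beta-value from probe intensities
#'
#' beta = M / (M + U + 100), the standard array definition with a 100-unit
#' stabilizing offset, so values lie in [0, 1).
#'
#' @param methylated,unmethylated Nonnegative intensity values (vectorized).
#' @return Beta-values in [0, 1).
#' @export
beta_from_intensities <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0))
    stopf("intensities must be nonnegative")
  methylated / (methylated + unmethylated + 100)
}

#' Adjustment recipe for phenotype preprocessing
#'
#' @param covariates Covariate names used in the kinship-aware residualization.
#' @param outlier_sd Outlier threshold in SD units (default 10).
#' @param outlier_iter Number of outlier-masking iterations (default 3).
#' @param n_factors Number of latent (PCA) factors to remove.
#' @param pca_top Number of most-variable features used for the PCA
#'   (default 20000, capped at the available feature count).
#' @param genetic_p Threshold below which a latent factor is considered under
#'   genetic control and excluded from adjustment (default 1e-7).
#' @return A list of class \code{adjustment_recipe}.
#' @export
adjustment_recipe <- function(covariates = character(0), outlier_sd = 10,
                              outlier_iter = 3, n_factors = 20,
                              pca_top = 20000, genetic_p = 1e-7) {
  if (outlier_sd <= 0) stopf("outlier_sd must be > 0")
  if (outlier_iter < 1) stopf("outlier_iter must be >= 1")
  structure(list(covariates = covariates, outlier_sd = outlier_sd,
                 outlier_iter = outlier_iter, n_factors = n_factors,
                 pca_top = pca_top, genetic_p = genetic_p),
            class = "adjustment_recipe")
}

#' Iterative SD-based outlier mask
#'
#' Masks values more than \code{outlier_sd} SDs from the mean, recomputing
#' mean and SD on unmasked values for exactly \code{outlier_iter} rounds.
#' Input values are untouched; only the mask is returned.
#'
#' @param values Numeric vector (may contain NA).
#' @param recipe An \code{adjustment_recipe}.
#' @return Logical vector: TRUE where masked.
#' @export
mask_outliers <- function(values, recipe = adjustment_recipe()) {
  if (sum(!is.na(values)) < 3) stopf("need >= 3 non-missing values")
  mask <- is.na(values)
  for (it in seq_len(recipe$outlier_iter)) {
    keep <- !mask
    mu <- mean(values[keep])
    sdv <- sd(values[keep])
    if (!is.finite(sdv) || sdv == 0) break
    new <- keep & abs(values - mu) > recipe$outlier_sd * sdv
    if (!any(new)) break
    mask <- mask | new
  }
  mask & !is.na(values)
}

#' Rank-based inverse normal transform
#'
#' Value with (average, for ties) rank r among n non-missing values maps to
#' \eqn{\Phi^{-1}((r - 0.5)/n)}. Missing entries stay missing.
#'
#' @param values Numeric vector.
#' @return Transformed vector of the same length.
#' @export
rint <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2) stopf("rint needs >= 2 distinct values")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - 0.5) / length(x))
  out
}

## Eigen-decomposition of a kinship matrix, cached for reuse across features.
#' @keywords internal
#' @noRd
kinship_eigen <- function(kin) {
  e <- eigen(kin, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors)
}

#' Kinship-aware residualization of one phenotype
#'
#' Fits \eqn{y = Xb + u + e} with \eqn{cov(u) = \sigma_g^2 K} by maximum
#' likelihood over the variance ratio \eqn{\lambda = \sigma_g^2 /
#' (\sigma_g^2 + \sigma_e^2)} on a grid [0, 0.99] (step 0.01), after rotating
#' by K's eigenvectors. Ties on the grid resolve to the smallest \eqn{\lambda},
#' so with K = identity the result is exactly the OLS residual. Returns
#' \eqn{y - X\hat b - \hat u} (the BLUP of u is removed as well).
#'
#' @param values Phenotype vector.
#' @param covariates Design matrix (an intercept is added if absent); NULL
#'   for intercept-only.
#' @param kin Kinship matrix, or a cached \code{kinship_eigen} result.
#' @return Residual vector.
#' @export
lmm_residualize <- function(values, covariates = NULL, kin) {
  n <- length(values)
  X <- if (is.null(covariates)) matrix(1, n, 1) else {
    X0 <- as.matrix(covariates)
    if (!any(apply(X0, 2, function(c) all(c == c[1])))) cbind(1, X0) else X0
  }
  if (qr(X)$rank < ncol(X)) stopf("singular design matrix")
  ke <- if (is.list(kin) && !is.null(kin$vectors)) kin else kinship_eigen(kin)
  U <- ke$vectors; d <- ke$values
  yr <- crossprod(U, values)
  Xr <- crossprod(U, X)
  grid <- seq(0, 0.99, by = 0.01)
  best <- NULL
  for (lam in grid) {
    w <- 1 / (lam * d + (1 - lam))
    XtWX <- crossprod(Xr, w * Xr)
    b <- solve(XtWX, crossprod(Xr, w * yr))
    r <- yr - Xr %*% b
    rss <- sum(w * r^2)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) - sum(log(w)) + n)
    if (is.null(best) || ll > best$ll + 1e-12) best <- list(ll = ll, lam = lam, b = b)
  }
  lam <- best$lam
  fit <- X %*% best$b
  r <- values - fit
  ## BLUP of u: lambda K (lambda K + (1-lambda) I)^-1 r, via the eigenbasis
  w <- lam * d / (lam * d + (1 - lam))
  u <- U %*% (w * crossprod(U, r))
  res <- as.numeric(r - u)
  attr(res, "lambda") <- lam
  attr(res, "loglik") <- best$ll
  res
}

## Residualize every row of a feature x sample matrix with a shared kinship.
#' @keywords internal
#' @noRd
lmm_residualize_matrix <- function(values, covariates, kin) {
  ke <- kinship_eigen(kin)
  t(apply(values, 1, function(y) as.numeric(lmm_residualize(y, covariates, ke))))
}

## RINT each row, then centre and rescale to unit sample variance so the
## residual-matrix contract (row mean 0, variance 1) holds exactly.
#' @keywords internal
#' @noRd
rint_rows <- function(m) {
  t(apply(m, 1, function(x) {
    z <- rint(x)
    z <- z - mean(z, na.rm = TRUE)
    z / sd(z, na.rm = TRUE)
  }))
}

#' Latent-factor adjustment of an adjusted phenotype matrix
#'
#' Computes principal components on the most-variable features (masked
#' outliers are set to the feature mean first), scans each of the first
#' \code{n_factors} components against all variants and drops any component
#' under strong genetic control (min p below \code{genetic_p}), regresses
#' each feature on the retained components, and re-applies the rank-based
#' inverse normal transform (standardized per row).
#'
#' @param residuals Feature x sample matrix (already covariate/kinship
#'   adjusted).
#' @param geno A \code{genotype_matrix} for the genetic check (NULL skips it).
#' @param recipe An \code{adjustment_recipe}.
#' @param mask Optional logical matrix of masked outliers (same shape).
#' @return Matrix of adjusted values; attribute \code{"excluded_factors"}
#'   lists components dropped by the genetic check.
#' @export
latent_factor_adjust <- function(residuals, geno = NULL,
                                 recipe = adjustment_recipe(), mask = NULL) {
  nf <- recipe$n_factors
  n <- ncol(residuals)
  if (nf > n - 1) stopf("n_factors exceeds n samples - 1")
  if (nf == 0) return(rint_rows(residuals))
  vals <- residuals
  if (!is.null(mask) && any(mask)) {
    for (i in which(rowSums(mask) > 0)) {
      vals[i, mask[i, ]] <- mean(vals[i, !mask[i, ]])
    }
  }
  rv <- apply(vals, 1, var)
  top <- order(rv, decreasing = TRUE)[seq_len(min(recipe$pca_top, nrow(vals)))]
  pc <- prcomp(t(vals[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(nf, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  excluded <- integer(0)
  if (!is.null(geno)) {
    for (j in seq_len(k)) {
      p <- marginal_scan_p(scores[, j], geno$dosage)
      if (min(p) < recipe$genetic_p) excluded <- c(excluded, j)
    }
  }
  keep <- setdiff(seq_len(k), excluded)
  out <- if (length(keep)) {
    S <- scores[, keep, drop = FALSE]
    Q <- qr.Q(qr(cbind(1, S)))
    vals - (vals %*% Q) %*% t(Q)
  } else vals
  out <- rint_rows(out)
  attr(out, "excluded_factors") <- excluded
  out
}

## p-values of y ~ each variant row (simple linear scan), vectorized.
#' @keywords internal
#' @noRd
marginal_scan_p <- function(y, dosage) {
  n <- length(y)
  yc <- y - mean(y)
  gs <- dosage - rowMeans(dosage)
  sy <- sqrt(sum(yc^2))
  sg <- sqrt(rowSums(gs^2))
  r <- as.numeric(gs %*% yc) / (sg * sy)
  r[!is.finite(r)] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), n - 2)
}

#' Full methylation adjustment pipeline
#'
#' The four-step recipe used before QTL scanning: (1) iterative outlier
#' masking per probe; (2) rank-based inverse normal transform; (3)
#' covariate + kinship residualization in a linear mixed model, residuals
#' re-RINTed; (4) masked values restored to the probe mean, latent-factor
#' (PCA) adjustment with a genetic check on each factor, and a final RINT.
#' Each output row is standardized to mean 0, variance 1.
#'
#' @param pheno A \code{phenotype_matrix} (beta-values or abundances).
#' @param ped The \code{twin_pedigree} (for the kinship matrix).
#' @param covariates Optional sample-level design matrix.
#' @param geno Optional \code{genotype_matrix} for the factor genetic check.
#' @param recipe An \code{adjustment_recipe}.
#' @return A list of class \code{residual_matrix}: \code{values},
#'   \code{mask}, \code{recipe}, \code{features}, \code{samples}.
#' @export
adjust_phenotypes <- function(pheno, ped, covariates = NULL, geno = NULL,
                              recipe = adjustment_recipe()) {
  raw <- pheno$values
  mask <- t(apply(raw, 1, mask_outliers, recipe = recipe))
  work <- raw
  work[mask] <- NA
  work <- rint_rows(work)
  kin <- kinship_from_pedigree(ped)
  ## LMM residualization needs complete vectors; masked entries are filled
  ## with the row mean (0 after standardization) for the fit only
  filled <- work
  filled[is.na(filled)] <- 0
  resid <- lmm_residualize_matrix(filled, covariates, kin)
  resid <- rint_rows(resid)
  adj <- latent_factor_adjust(resid, geno, recipe,
                              mask = matrix(FALSE, nrow(raw), ncol(raw)))
  dimnames(adj) <- dimnames(raw)
  structure(list(values = adj, mask = mask, recipe = recipe,
                 features = pheno$features, samples = pheno$samples),
            class = "residual_matrix")
}

#' Choose the number of latent factors by eQTL discovery
#'
#' For each candidate factor count, adjusts the expression matrix with that
#' many latent factors and counts genes with a significant local eQTL at a
#' Benjamini-Hochberg FDR of 5% (per-gene best p, Bonferroni-corrected within
#' gene across its cis variants). Returns the candidate maximizing the eGene
#' count (ties resolve to the smallest candidate).
#'
#' @param expr A \code{phenotype_matrix} of expression values.
#' @param geno A \code{genotype_matrix}.
#' @param grid Candidate factor counts.
#' @param ped A \code{twin_pedigree} used during adjustment.
#' @param window Cis window in bp (default 1e6).
#' @param level FDR level (default 0.05).
#' @return The chosen factor count; attribute \code{"egenes"} holds the
#'   per-candidate counts.
#' @export
choose_n_factors <- function(expr, geno, grid, ped, window = 1e6,
                             level = 0.05) {
  if (!length(grid)) stopf("empty candidate grid")
  counts <- vapply(grid, function(k) {
    rec <- adjustment_recipe(n_factors = k, genetic_p = 0)  # keep all factors
    adj <- adjust_phenotypes(expr, ped, recipe = rec)
    count_egenes(adj, geno, window = window, level = level)
  }, numeric(1))
  choice <- grid[which(counts == max(counts))]
  out <- min(choice)
  attr(out, "egenes") <- stats::setNames(counts, grid)
  out
}

## eGene count at BH FDR `level`: per-gene best cis p, Bonferroni within gene.
#' @keywords internal
#' @noRd
count_egenes <- function(adj, geno, window = 1e6, level = 0.05) {
  fp <- vapply(seq_len(nrow(adj$values)), function(i) {
    f <- adj$features[i, ]
    cis <- which(geno$variants$chrom == f$chrom &
                   abs(geno$variants$pos - f$pos) < window)
    if (!length(cis)) return(NA_real_)
    p <- marginal_scan_p(adj$values[i, ], geno$dosage[cis, , drop = FALSE])
    min(min(p) * length(p), 1)
  }, numeric(1))
  fp <- fp[!is.na(fp)]
  if (!length(fp)) return(0)
  sum(p.adjust(fp, "BH") <= level)
}
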