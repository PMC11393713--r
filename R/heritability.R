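#' Falconer closed-form ACE decomposition
#'
#' From twin correlations: a2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ, e2 = 1 - rMZ.
#' The closed form can leave the unit simplex; values are returned unclamped
#' with a flag. Used as the oracle / starting point for the likelihood fit.
#'
#' @param r_mz,r_dz MZ and DZ intraclass correlations, in [-1, 1].
#' @return List: \code{a2}, \code{c2}, \code{e2}, \code{out_of_bounds}.
#' @export
falconer_estimate <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) stopf("correlations must be in [-1, 1]")
  a2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- 1 - r_mz
  list(a2 = a2, c2 = c2, e2 = e2,
       out_of_bounds = a2 < 0 || c2 < 0 || e2 < 0 || a2 > 1 || c2 > 1)
}

## Sufficient statistics for the bivariate-normal pair likelihood:
## per zygosity, n pairs, sum(x^2 + y^2), sum(xy).
#' @keywords internal
#' @noRd
pair_stats <- function(pairs) {
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  list(n = nrow(pairs),
       s2 = sum(pairs^2),
       s11 = sum(pairs[, 1] * pairs[, 2]))
}

## Log-likelihood of standardized pairs under within-pair correlation r
## (unit marginal variance). Vectorized over r.
#' @keywords internal
#' @noRd
pair_loglik <- function(st, r) {
  om <- 1 - r^2
  -st$n * log(2 * pi) - 0.5 * st$n * log(om) -
    (st$s2 - 2 * r * st$s11) / (2 * om)
}

#' @keywords internal
#' @noRd
ace_loglik <- function(a2, c2, st_mz, st_dz) {
  pair_loglik(st_mz, pmin(a2 + c2, 1 - 1e-10)) +
    pair_loglik(st_dz, pmin(0.5 * a2 + c2, 1 - 1e-10))
}

#' Maximum-likelihood ACE fit from twin pairs
#'
#' Maximizes the bivariate-normal log-likelihood with within-pair covariance
#' a2 + c2 (MZ) and 0.5 a2 + c2 (DZ), total variance constrained to 1
#' (equal means and variances across zygosity groups are assumed; values are
#' standardized internally), over the simplex \{a2, c2 >= 0, a2 + c2 <= 1\}.
#' Boundary solutions are permitted. The optimizer evaluates the likelihood
#' on a 0.005 simplex lattice (cheap: the likelihood depends on the data
#' only through three sufficient statistics per zygosity) and polishes the
#' best lattice point with Nelder-Mead under a boundary projection.
#'
#' @param mz_pairs,dz_pairs Two-column matrices of paired values, one row per
#'   twin pair.
#' @param standardize Standardize values to mean 0, variance 1 across all
#'   individuals first (default TRUE).
#' @return An object of class \code{ace_fit}: a2, c2, e2, loglik,
#'   convergence flag, pair counts.
#' @export
fit_ace_ml <- function(mz_pairs, dz_pairs, standardize = TRUE) {
  mz_pairs <- as.matrix(mz_pairs)
  dz_pairs <- as.matrix(dz_pairs)
  mz_pairs <- mz_pairs[stats::complete.cases(mz_pairs), , drop = FALSE]
  dz_pairs <- dz_pairs[stats::complete.cases(dz_pairs), , drop = FALSE]
  if (nrow(mz_pairs) < 2 || nrow(dz_pairs) < 2)
    stopf("need >= 2 complete pairs per zygosity")
  allv <- c(mz_pairs, dz_pairs)
  if (any(!is.finite(allv))) stopf("non-finite values")
  if (standardize) {
    mu <- mean(allv); sdv <- sd(allv)
    if (sdv == 0) stopf("zero variance")
    mz_pairs <- (mz_pairs - mu) / sdv
    dz_pairs <- (dz_pairs - mu) / sdv
  }
  st_mz <- pair_stats(mz_pairs)
  st_dz <- pair_stats(dz_pairs)

  lat <- ace_lattice(0.005)
  ll <- ace_loglik(lat$a2, lat$c2, st_mz, st_dz)
  i0 <- which.max(ll)
  ## polish: Nelder-Mead on (a2, c2) with projection onto the simplex
  obj <- function(p) {
    a2 <- min(max(p[1], 0), 1)
    c2 <- min(max(p[2], 0), 1 - a2)
    -ace_loglik(a2, c2, st_mz, st_dz)
  }
  starts <- list(c(lat$a2[i0], lat$c2[i0]))
  fal <- falconer_estimate(min(max(st_mz$s11 / st_mz$n, -1), 1),
                           min(max(st_dz$s11 / st_dz$n, -1), 1))
  starts <- c(starts, list(
    c(min(max(fal$a2, 0), 1), min(max(fal$c2, 0), 1 - min(max(fal$a2, 0), 1))),
    c(1 / 3, 1 / 3), c(0.99, 0)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  a2 <- min(max(best$par[1], 0), 1)
  c2 <- min(max(best$par[2], 0), 1 - a2)
  llbest <- ace_loglik(a2, c2, st_mz, st_dz)
  if (llbest < ll[i0]) { a2 <- lat$a2[i0]; c2 <- lat$c2[i0]; llbest <- ll[i0] }
  structure(list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2, loglik = llbest,
                 converged = TRUE, n_mz = st_mz$n, n_dz = st_dz$n),
            class = "ace_fit")
}

#' @keywords internal
#' @noRd
ace_lattice <- function(step = 0.005) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(a2 = g, c2 = g)
  grid[grid$a2 + grid$c2 <= 1 + 1e-12, ]
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE fit: a2 = %.3f, c2 = %.3f, e2 = %.3f (logL = %.2f; %d MZ, %d DZ pairs)\n",
              x$a2, x$c2, x$e2, x$loglik, x$n_mz, x$n_dz))
  invisible(x)
}

#' @export
coef.ace_fit <- function(object, ...) {
  c(a2 = object$a2, c2 = object$c2, e2 = object$e2)
}

## Split a feature vector into MZ / DZ pair matrices by the pedigree.
#' @keywords internal
#' @noRd
twin_pair_values <- function(values, ped) {
  idx <- pair_index(ped)
  out <- list(MZ = NULL, DZ = NULL)
  for (z in c("MZ", "DZ")) {
    sel <- which(idx$zygosity == z)
    if (length(sel)) {
      m <- t(vapply(idx$pairs[sel], function(i) values[i], numeric(2)))
      out[[z]] <- m
    }
  }
  out
}

#' ACE heritability scan over a phenotype matrix
#'
#' Drops singletons (the twin model uses complete pairs only) and, per
#' feature, pairs with a missing member, then fits the ACE model to every
#' feature.
#'
#' @param values Feature x sample matrix (e.g. a \code{residual_matrix}'s
#'   \code{values}) or a \code{residual_matrix} / \code{phenotype_matrix}.
#' @param ped The matching \code{twin_pedigree}.
#' @return data.frame: feature, a2, c2, e2, loglik, n_mz, n_dz; attributes
#'   \code{mean_a2} and \code{share_high_a2} (fraction with a2 > 0.5).
#' @export
heritability_scan <- function(values, ped) {
  if (is.list(values) && !is.null(values$values)) values <- values$values
  idx <- pair_index(ped)
  if (sum(idx$zygosity == "MZ") < 2 || sum(idx$zygosity == "DZ") < 2)
    stopf("need >= 2 complete pairs per zygosity")
  res <- lapply(seq_len(nrow(values)), function(i) {
    pv <- twin_pair_values(values[i, ], ped)
    fit <- fit_ace_ml(pv$MZ, pv$DZ)
    data.frame(feature = rownames(values)[i] %||% as.character(i),
               a2 = fit$a2, c2 = fit$c2, e2 = fit$e2, loglik = fit$loglik,
               n_mz = fit$n_mz, n_dz = fit$n_dz, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mean_a2") <- mean(out$a2)
  attr(out, "share_high_a2") <- mean(out$a2 > 0.5)
  out
}
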