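## Shared fixtures and independent oracles used across test files.

## Closed-form simple-regression summary (beta, se, t, p) for y ~ g.
ols_summary <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g)
  yc <- y - mean(y)
  b <- sum(gc * yc) / sum(gc^2)
  res <- yc - b * gc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum(gc^2))
  tt <- b / se
  list(beta = b, se = se, t = tt, p = 2 * pt(-abs(tt), n - 2))
}

## ACE log-likelihood on the 0.005 simplex lattice, written from the
## bivariate-normal density directly (independent of the package internals;
## vectorized over the lattice through the three sufficient statistics of
## the standardized pair likelihood).
ace_lattice_oracle <- function(mz, dz, step = 0.005) {
  mu <- mean(c(mz, dz)); sdv <- sd(c(mz, dz))
  mz <- (mz - mu) / sdv; dz <- (dz - mu) / sdv
  ll_pairs <- function(pm, r) {
    r <- pmin(r, 1 - 1e-10)
    n <- nrow(pm)
    s2 <- sum(pm^2); s11 <- sum(pm[, 1] * pm[, 2])
    -n * log(2 * pi) - 0.5 * n * log(1 - r^2) -
      (s2 - 2 * r * s11) / (2 * (1 - r^2))
  }
  g <- seq(0, 1, by = step)
  lat <- expand.grid(a2 = g, c2 = g)
  lat <- lat[lat$a2 + lat$c2 <= 1 + 1e-12, ]
  ll <- ll_pairs(mz, lat$a2 + lat$c2) + ll_pairs(dz, 0.5 * lat$a2 + lat$c2)
  i <- which.max(ll)
  list(loglik = ll[i], a2 = lat$a2[i], c2 = lat$c2[i])
}

## Direct enumeration of the five colocalization hypothesis weights.
coloc_enumeration_oracle <- function(lbf1, lbf2, p1, p2, p12) {
  n <- length(lbf1)
  b1 <- exp(lbf1); b2 <- exp(lbf2)
  w <- c(1, p1 * sum(b1), p2 * sum(b2), 0, p12 * sum(b1 * b2))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    w[4] <- w[4] + p1 * p2 * b1[i] * b2[j]
  w / sum(w)
}

## Two-sided Fisher exact p by hypergeometric enumeration.
fisher_enum_oracle <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  d_obs <- dhyper(a, m, n, k)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

## Exhaustive best-subset search under the stepwise constraints.
best_subset_oracle <- function(y, G, p_enter, r2_cap) {
  m <- nrow(G)
  best_rss <- Inf; best_set <- integer(0)
  subsets <- unlist(lapply(0:m, function(k) combn(m, k, simplify = FALSE)),
                    recursive = FALSE)
  for (s in subsets) {
    if (length(s) > 1) {
      r2 <- cor(t(G[s, , drop = FALSE]))^2
      if (max(r2[upper.tri(r2)]) > r2_cap) next
    }
    if (length(s)) {
      X <- cbind(1, t(G[s, , drop = FALSE]))
      if (qr(X)$rank < ncol(X)) next
      fit <- lm.fit(X, y)
      df <- length(y) - ncol(X)
      s2 <- sum(fit$residuals^2) / df
      XtXinv <- chol2inv(qr.R(qr(X)))
      tt <- fit$coefficients / sqrt(diag(XtXinv) * s2)
      ps <- 2 * pt(-abs(tt[-1]), df)
      if (any(ps >= p_enter)) next
      rss <- sum(fit$residuals^2)
    } else rss <- sum((y - mean(y))^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best_set <- s }
  }
  list(rss = best_rss, set = best_set)
}

## Small two-signal colocalization region: genotypes with LD plus two traits.
sim_coloc_region <- function(n = 400, n_var = 50, shared = TRUE,
                             effect = 0.35) {
  ped <- simulate_pedigree(0, 0, n)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = n,
                    n_variants = n_var, n_chromosomes = 1, n_cpgs = 1,
                    n_genes = 1, ld_rho = 0.6, seed = 1)
  geno <- simulate_genotypes(ped, cfg)
  G <- geno$dosage
  gs <- (G - rowMeans(G)) / apply(G, 1, sd)
  c1 <- sample(n_var, 1)
  c2 <- if (shared) c1 else {
    far <- which(abs(seq_len(n_var) - c1) > 10)
    if (length(far)) sample(far, 1) else ((c1 + 25 - 1) %% n_var) + 1
  }
  y1 <- effect * gs[c1, ] + rnorm(n) * sqrt(1 - effect^2)
  y2 <- effect * gs[c2, ] + rnorm(n) * sqrt(1 - effect^2)
  sm <- function(y) {
    out <- t(vapply(seq_len(n_var), function(j) {
      s <- ols_summary(y, G[j, ])
      c(s$beta, s$se)
    }, numeric(2)))
    out
  }
  s1 <- sm(y1); s2 <- sm(y2)
  list(beta1 = s1[, 1], se1 = s1[, 2], beta2 = s2[, 1], se2 = s2[, 2],
       causal1 = c1, causal2 = c2)
}

published_prior_counts <- list(n_indep_1 = 13550, n_tested_1 = 5275301,
                           n_indep_2 = 63976, n_tested_2 = 5253496)
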