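test_that("beta-values follow the intensity-ratio definition", {
  expect_equal(beta_from_intensities(0, 0), 0)
  expect_equal(beta_from_intensities(900, 0), 0.9)
  expect_equal(beta_from_intensities(200, 700), 0.2)
  expect_true(all(beta_from_intensities(runif(50, 0, 1e4),
                                        runif(50, 0, 1e4)) < 1))
  expect_error(beta_from_intensities(-1, 10), "nonnegative")
})

test_that("outlier masking is iterative and leaves clean data alone", {
  set.seed(1)
  x <- rnorm(500)
  x[100] <- 1e6
  m <- mask_outliers(x)
  expect_equal(which(m), 100)

  expect_equal(sum(mask_outliers(rnorm(500))), 0)

  ## cascade: second value becomes an outlier only after the first is masked.
  ## verified by manual iteration: with the 1e6 point in, SD is huge and 120
  ## is inside 10 SD; after masking it, 120 is far outside 10 SD of N(0,1).
  y <- c(rnorm(400), 120, 1e6)
  mu1 <- mean(y); s1 <- sd(y)
  expect_true(abs(120 - mu1) <= 10 * s1)        # survives round 1
  m2 <- mask_outliers(y)
  expect_true(m2[401] && m2[402])
  expect_equal(sum(m2), 2)

  expect_error(mask_outliers(c(1, 2)), ">= 3")
})

test_that("rank-based inverse normal transform matches its quantile law", {
  expect_equal(rint(c(10, 20, 30)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(round(rint(c(10, 20, 30)), 4), c(-0.9674, 0, 0.9674))
  ## odd n without ties: symmetric quantiles average to zero
  set.seed(2)
  z <- rint(rnorm(101))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_error(rint(c(5, 5)), "distinct")
  ## invariance under strictly monotone transforms
  x <- rexp(50)
  expect_equal(rint(x), rint(log(x)))
  expect_equal(rint(x), rint(x^3))
  ## missing entries propagate
  x[3] <- NA
  expect_true(is.na(rint(x)[3]))
})

test_that("pedigree kinship has the MZ/DZ/singleton block structure", {
  ped <- simulate_pedigree(2, 1, 1)
  K <- kinship_from_pedigree(ped)
  expect_true(isSymmetric(K))
  expect_equal(diag(K), rep(1, 7), ignore_attr = TRUE)
  up <- K[upper.tri(K)]
  expect_equal(sum(up == 1), 2)    # two MZ pairs
  expect_equal(sum(up == 0.5), 1)  # one DZ pair
  expect_equal(sum(up != 0), 3)
  solo <- simulate_pedigree(0, 0, 4)
  expect_equal(kinship_from_pedigree(solo), diag(4), ignore_attr = TRUE)
})

test_that("kinship LMM reduces to OLS when relatedness is absent", {
  set.seed(3)
  n <- 80
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- 1 + X %*% c(0.5, -0.3) + rnorm(n)
  r_lmm <- lmm_residualize(y, X, diag(n))
  r_ols <- resid(lm(y ~ X))
  expect_lt(max(abs(r_lmm - r_ols)), 1e-8)
  expect_error(lmm_residualize(y, cbind(X, X[, 1]), diag(n)), "singular")
})

test_that("LMM variance ratio piles at the zero boundary for unrelated data", {
  ped <- simulate_pedigree(100, 100, 0)
  K <- kinship_from_pedigree(ped)
  lam <- vapply(1:50, function(s) {
    set.seed(s)
    y <- rnorm(nrow(ped))
    attr(lmm_residualize(y, NULL, K), "lambda")
  }, numeric(1))
  ## boundary ML: about half the estimates sit exactly at 0, and large
  ## values are rare
  expect_gte(mean(lam == 0), 0.4)
  expect_gte(mean(lam <= 0.25), 0.9)
})

test_that("LMM removes a strong family component", {
  set.seed(4)
  ped <- simulate_pedigree(40, 40, 0)
  K <- kinship_from_pedigree(ped)
  idx <- which(!is.na(ped$pair_id))
  fam <- rnorm(80)[as.integer(factor(ped$pair_id))]
  y <- sqrt(0.7) * fam + sqrt(0.3) * rnorm(nrow(ped))
  r <- lmm_residualize(y, NULL, K)
  pm <- matrix(r, ncol = 2, byrow = TRUE)
  ## the positive family correlation is gone (the BLUP removes pair means,
  ## leaving a small negative within-pair correlation)
  expect_lt(cor(pm)[1, 2], 0.1)
  expect_gt(attr(r, "lambda"), 0.3)
})

test_that("latent-factor adjustment drops genetically driven components", {
  set.seed(5)
  ped <- simulate_pedigree(0, 0, 120)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 120,
                    n_variants = 50, n_cpgs = 40, n_genes = 2, seed = 5)
  geno <- simulate_genotypes(ped, cfg)
  ## a component that IS a linear function of one variant is excluded
  g <- as.numeric(scale(geno$dosage[7, ]))
  Mg <- matrix(rnorm(40 * 120, sd = 0.3), 40, 120) +
    outer(rnorm(40, sd = 2), g)
  adjg <- latent_factor_adjust(Mg, geno, adjustment_recipe(n_factors = 2))
  expect_true(1 %in% attr(adjg, "excluded_factors"))

  ## a planted batch shift (no genetic driver) is removed by the retained
  ## factors: batch-vs-feature associations become uniform
  batch <- rnorm(120)
  loadings <- runif(40, 1, 3) * sample(c(-1, 1), 40, replace = TRUE)
  M <- matrix(rnorm(40 * 120, sd = 0.3), 40, 120) + outer(loadings, batch)
  adj <- latent_factor_adjust(M, geno, adjustment_recipe(n_factors = 2))
  pb_before <- apply(M, 1, function(z)
    summary(lm(z ~ batch))$coefficients[2, 4])
  pb <- apply(adj, 1, function(z) summary(lm(z ~ batch))$coefficients[2, 4])
  ## the dominant batch factor is projected out exactly, so post-adjustment
  ## associations are null (if anything conservative, never significant)
  expect_lt(max(pb_before), 1e-20)
  expect_gt(min(pb), 0.05)

  ## n_factors = 0 is the plain (standardized) RINT path
  adj0 <- latent_factor_adjust(M, geno, adjustment_recipe(n_factors = 0))
  manual <- t(apply(M, 1, function(x) { z <- rint(x); (z - mean(z)) / sd(z) }))
  expect_equal(adj0, manual, ignore_attr = TRUE)
  expect_error(latent_factor_adjust(M, geno,
                                    adjustment_recipe(n_factors = 500)),
               "n_factors")
})

test_that("adjusted rows are standardized and the RINT core is idempotent", {
  cfg <- sim_config(n_mz_pairs = 20, n_dz_pairs = 20, n_singletons = 10,
                    n_variants = 100, n_cpgs = 30, n_genes = 5, seed = 6)
  co <- simulate_twin_cohort(cfg)
  adj <- adjust_phenotypes(co$meth, co$ped, geno = co$geno,
                           recipe = adjustment_recipe(n_factors = 2))
  expect_equal(rowMeans(adj$values), rep(0, 30),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(apply(adj$values, 1, var), rep(1, 30),
               ignore_attr = TRUE, tolerance = 1e-6)
  ## idempotence on its own output (exact when the kinship BLUP is inactive:
  ## singleton cohort, K = identity)
  cfg_s <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 90,
                      n_variants = 50, n_cpgs = 20, n_genes = 5, seed = 66)
  cos <- simulate_twin_cohort(cfg_s)
  adj1 <- adjust_phenotypes(cos$meth, cos$ped,
                            recipe = adjustment_recipe(n_factors = 0))
  ph <- list(values = adj1$values, features = cos$meth$features,
             samples = cos$meth$samples)
  class(ph) <- "phenotype_matrix"
  adj2 <- adjust_phenotypes(ph, cos$ped,
                            recipe = adjustment_recipe(n_factors = 0))
  expect_equal(adj2$values, adj1$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("factor count selection maximizes eGene discovery", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 150,
                    n_variants = 300, n_chromosomes = 1, n_cpgs = 2,
                    n_genes = 40,
                    eqtl_effects = data.frame(variant = seq(10, 290, by = 10),
                                              gene = 1:29, effect = 0.25),
                    expr_family_var = 0, seed = 7)
  co <- simulate_twin_cohort(cfg)
  ## overlay three strong non-genetic factors
  set.seed(7)
  F3 <- matrix(rnorm(3 * 150), 3, 150)
  load <- matrix(rnorm(40 * 3, sd = 1.2), 40, 3)
  expr2 <- co$expr
  expr2$values <- co$expr$values + load %*% F3
  k1 <- choose_n_factors(expr2, co$geno, grid = c(4), ped = co$ped)
  expect_equal(as.integer(k1), 4L)
  k <- choose_n_factors(expr2, co$geno, grid = c(0, 3), ped = co$ped)
  counts <- attr(k, "egenes")
  expect_gte(counts[["3"]], counts[["0"]])
  expect_error(choose_n_factors(expr2, co$geno, grid = integer(0),
                                ped = co$ped), "empty")
})
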