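test_that("cis/trans partition uses a strict 1 Mbp same-chromosome rule", {
  expect_equal(partition_cis_trans(1, 2999999, 1, 2000000), "cis")
  expect_equal(partition_cis_trans(1, 3000001, 1, 2000000), "trans")
  expect_equal(partition_cis_trans(2, 500, 1, 2000000), "trans")
  ## exactly 1 Mbp is assigned to trans
  expect_equal(partition_cis_trans(1, 3000000, 1, 2000000), "trans")
  expect_error(partition_cis_trans(NA, 1, 1, 1), "unknown chromosome")
})

make_scan_fixture <- function(seed, n_s = 400, n_var = 150, n_cpg = 40,
                              effects = NULL, ace = c(0.3, 0.05, 0.65),
                              ld_rho = 0.7) {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = n_s,
                    n_variants = n_var, n_cpgs = n_cpg, n_genes = 2,
                    ace_targets = ace, meqtl_effects = effects,
                    ld_rho = ld_rho, seed = seed)
  co <- simulate_twin_cohort(cfg)
  vals <- t(apply(co$meth$latent, 1, function(x) {
    z <- rint(x); (z - mean(z)) / sd(z)
  }))
  dimnames(vals) <- dimnames(co$meth$values)
  resid <- list(values = vals, features = co$meth$features,
                samples = co$meth$samples)
  list(co = co, resid = resid)
}

test_that("scan statistics equal the closed-form simple regression", {
  fx <- make_scan_fixture(61, n_s = 120, n_var = 40, n_cpg = 6)
  sc <- association_scan(fx$resid, fx$co$geno,
                         scan_config(cis_p = 0.999, trans_p = 0.999))
  expect_gt(nrow(sc$hits), 50)
  for (k in sample(nrow(sc$hits), 20)) {
    h <- sc$hits[k, ]
    y <- fx$resid$values[match(h$feature, fx$resid$features$id), ]
    g <- fx$co$geno$dosage[match(h$variant, fx$co$geno$variants$id), ]
    o <- ols_summary(y, g)
    expect_equal(h$t, o$t, tolerance = 1e-10)
    expect_equal(h$beta, o$beta, tolerance = 1e-10)
    expect_equal(h$p, o$p, tolerance = 1e-10)
  }
})

test_that("planted effect size is recovered within sampling error", {
  eff <- data.frame(variant = 10, cpg = 1, effect = 0.45, class = "cis")
  fx <- make_scan_fixture(62, n_s = 400, effects = eff,
                          ace = c(0.3, 0.05, 0.65))
  sc <- association_scan(fx$resid, fx$co$geno, scan_config())
  hit <- sc$hits[sc$hits$feature == "cg00001" &
                   sc$hits$variant == "var00010", ]
  expect_equal(nrow(hit), 1)
  g <- fx$co$geno$dosage[10, ]
  beta_std <- hit$beta * sd(g)       # per-SD effect on the rint scale
  expect_lt(abs(beta_std - 0.45), 0.15)
})

test_that("a majority-coded variant is re-oriented before emission", {
  fx <- make_scan_fixture(63, n_s = 200, n_var = 30, n_cpg = 4)
  geno2 <- fx$co$geno
  ## force variant 1 to majority coding
  geno2$dosage[1, ] <- 2L - geno2$dosage[1, ]
  sc1 <- association_scan(fx$resid, fx$co$geno,
                          scan_config(cis_p = 0.999, trans_p = 0.999))
  sc2 <- association_scan(fx$resid, geno2,
                          scan_config(cis_p = 0.999, trans_p = 0.999))
  h1 <- sc1$hits[sc1$hits$variant == "var00001", ]
  h2 <- sc2$hits[sc2$hits$variant == "var00001", ]
  expect_equal(h2$beta, h1$beta, tolerance = 1e-12)
  expect_equal(h2$p, h1$p, tolerance = 1e-12)
})

test_that("null scans retain about the nominal cis fraction", {
  ## unlinked variants so retained counts are near-Poisson (with strong LD
  ## the hits cluster and the 20-seed count is overdispersed)
  frac <- vapply(1:20, function(s) {
    fx <- make_scan_fixture(700 + s, n_s = 200, n_var = 100, n_cpg = 50,
                            ace = c(0, 0.0, 1.0), ld_rho = 0)
    sc <- association_scan(fx$resid, fx$co$geno, scan_config())
    v <- fx$co$geno$variants
    f <- fx$resid$features
    n_cis_tested <- sum(vapply(seq_len(nrow(f)), function(i)
      sum(v$chrom == f$chrom[i] & abs(v$pos - f$pos[i]) < 1e6), numeric(1)))
    sum(sc$hits$class == "cis") / n_cis_tested
  }, numeric(1))
  expect_lt(abs(mean(frac) - 1e-3), 0.5e-3)
})

test_that("twin-aware permutation preserves pairs, zygosity and columns", {
  cfg <- sim_config(n_mz_pairs = 8, n_dz_pairs = 8, n_singletons = 6,
                    n_variants = 50, n_cpgs = 2, n_genes = 2, seed = 64)
  co <- simulate_twin_cohort(cfg)
  gp <- twin_aware_permutation(co$geno, co$ped, seed = 99)
  ## column multiset unchanged
  key <- function(m) sort(unname(apply(m, 2, paste, collapse = ",")))
  expect_identical(key(gp$dosage), key(co$geno$dosage))
  ## MZ co-twins still identical
  for (p in unique(co$ped$pair_id[co$ped$zygosity == "MZ"])) {
    cols <- which(co$ped$pair_id %in% p)
    expect_identical(gp$dosage[, cols[1]], gp$dosage[, cols[2]])
  }
  ## every receiving slot got a source column of the same zygosity group
  src <- apply(gp$dosage, 2, paste, collapse = ",")
  orig <- apply(co$geno$dosage, 2, paste, collapse = ",")
  zyg_of <- co$ped$zygosity[match(src, orig)]
  expect_identical(zyg_of, co$ped$zygosity)
})

test_that("permutation FDR thresholds follow the counting formula", {
  ## hand enumeration: candidates are the observed best p values.
  ## FDR(1e-8) = 0/1; FDR(0.2) = mean#{perm <= .2}/2 = 1/2; FDR(0.3) = 1/3.
  obs <- c(1e-8, 0.2, 0.3)
  perm <- matrix(c(0.05, 0.6, 0.7), ncol = 1)
  th <- permutation_fdr_thresholds(obs, perm, level = 0.05)
  expect_equal(th$threshold, 1e-8)
  expect_equal(th$n_discoveries, 1L)
  ## with a laxer level the largest qualifying candidate is returned
  th2 <- permutation_fdr_thresholds(obs, perm, level = 0.4)
  expect_equal(th2$threshold, 0.3)
  ## exchangeable null: permuted distribution identical to observed
  th3 <- permutation_fdr_thresholds(obs, matrix(obs, ncol = 1), level = 0.05)
  expect_true(is.na(th3$threshold))
  expect_equal(th3$n_discoveries, 0L)
  ## order invariance
  th4 <- permutation_fdr_thresholds(rev(obs), perm, level = 0.05)
  expect_equal(th4$threshold, th$threshold)
  expect_error(permutation_fdr_thresholds(numeric(0), perm), "no observed")
})

test_that("per-pair p values are uniform under an exchangeable null", {
  fx <- make_scan_fixture(65, n_s = 250, n_var = 40, n_cpg = 25,
                          ace = c(0, 0, 1))
  sc <- association_scan(fx$resid, fx$co$geno,
                         scan_config(cis_p = 0.9999999, trans_p = 0.9999999))
  expect_gt(ks.test(sc$hits$p, "punif")$p.value, 0.01)
})

test_that("beta-approximated permutation p values track the rank oracle", {
  set.seed(66)
  n_feat <- 60
  M <- 100                      # variants per feature under the null
  n_perm <- 1000
  perm <- t(vapply(seq_len(n_feat), function(i)
    vapply(seq_len(n_perm), function(b) min(runif(M)), numeric(1)),
    numeric(n_perm)))
  obs <- vapply(seq_len(n_feat), function(i) min(runif(M)), numeric(1))
  res <- gene_level_beta_fdr(obs, perm, level = 0.05)
  ## minima of M uniforms follow Beta(1, M)
  expect_lt(abs(mean(res$shape1) - 1), 0.2)
  expect_lt(abs(mean(res$shape2) - M), 0.2 * M)
  rank_p <- vapply(seq_len(n_feat), function(i)
    (1 + sum(perm[i, ] <= obs[i])) / (1 + n_perm), numeric(1))
  agree <- abs(res$empirical_p - rank_p) <= 0.02
  expect_gte(mean(agree), 0.95)
  ## an observed minimum below every permutation minimum is extreme
  obs2 <- obs; obs2[1] <- min(perm[1, ]) / 10
  res2 <- gene_level_beta_fdr(obs2, perm, level = 0.05)
  expect_lt(res2$empirical_p[1], 1 / n_perm)
  expect_error(gene_level_beta_fdr(obs, perm[, 1:50]), ">= 100")
  expect_error(gene_level_beta_fdr(obs[1], matrix(0.5, 1, 200)), "degenerate")
})

test_that("Storey q values behave like a pi0-scaled BH procedure", {
  set.seed(67)
  p <- c(runif(50, 0, 1e-4), runif(150))
  q <- storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(q[1:50] < 0.05))
  ## monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})
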