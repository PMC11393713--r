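test_that("pedigree construction counts pairs and singletons correctly", {
  ped <- simulate_pedigree(2, 3, 1)
  expect_equal(nrow(ped), 11)
  expect_equal(sum(ped$zygosity == "MZ"), 4)
  expect_equal(sum(ped$zygosity == "DZ"), 6)
  expect_equal(sum(ped$zygosity == "singleton"), 1)
  expect_equal(length(unique(na.omit(ped$pair_id))), 5)

  solo <- simulate_pedigree(0, 0, 5)
  expect_equal(nrow(solo), 5)
  expect_true(all(is.na(solo$pair_id)))

  one <- simulate_pedigree(1, 0, 0)
  expect_equal(one$zygosity, c("MZ", "MZ"))
  expect_equal(one$pair_id[1], one$pair_id[2])

  expect_error(simulate_pedigree(0, 0, 0), "empty cohort")
})

test_that("MZ co-twins have identical genotypes at every variant", {
  set.seed(42)
  ped <- simulate_pedigree(10, 10, 5)
  cfg <- sim_config(n_mz_pairs = 10, n_dz_pairs = 10, n_singletons = 5,
                    n_variants = 300, n_cpgs = 1, n_genes = 1, seed = 42)
  geno <- simulate_genotypes(ped, cfg)
  for (p in unique(ped$pair_id[ped$zygosity == "MZ"])) {
    cols <- which(ped$pair_id %in% p)
    expect_identical(geno$dosage[, cols[1]], geno$dosage[, cols[2]])
  }
  expect_true(all(geno$variants$maf <= 0.5 + 1e-12))
  by_chr <- split(geno$variants$pos, geno$variants$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("DZ co-twin genotype correlation averages one half", {
  set.seed(7)
  ped <- simulate_pedigree(0, 200, 0)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 200, n_singletons = 0,
                    n_variants = 5000, n_chromosomes = 4,
                    n_cpgs = 1, n_genes = 1, seed = 7)
  geno <- simulate_genotypes(ped, cfg)
  t1 <- seq(1, 400, by = 2); t2 <- seq(2, 400, by = 2)
  g1 <- geno$dosage[, t1]; g2 <- geno$dosage[, t2]
  rr <- vapply(seq_len(5000), function(v)
    suppressWarnings(cor(g1[v, ], g2[v, ])), numeric(1))
  expect_lt(abs(mean(rr, na.rm = TRUE) - 0.5), 0.05)
})

test_that("ld_rho = 0 gives uncorrelated adjacent founder dosages", {
  set.seed(11)
  ped <- simulate_pedigree(0, 0, 500)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 500,
                    n_variants = 1000, n_chromosomes = 1, ld_rho = 0,
                    n_cpgs = 1, n_genes = 1, seed = 11)
  geno <- simulate_genotypes(ped, cfg)
  r2 <- vapply(2:1000, function(j)
    suppressWarnings(cor(geno$dosage[j, ], geno$dosage[j - 1, ]))^2,
    numeric(1))
  expect_lt(abs(mean(r2, na.rm = TRUE)), 0.02)
})

test_that("methylation realizes target twin correlations", {
  ## 4000 pairs per zygosity: the +-0.03 band is then ~3 sampling SDs
  cfg <- sim_config(n_mz_pairs = 4000, n_dz_pairs = 4000, n_singletons = 0,
                    n_variants = 2, n_cpgs = 3, n_genes = 1,
                    ace_targets = c(0.4, 0.2, 0.4), seed = 21)
  co <- simulate_twin_cohort(cfg)
  mz <- co$ped$zygosity == "MZ"; dz <- co$ped$zygosity == "DZ"
  for (i in 1:3) {
    y <- co$meth$latent[i, ]
    rmz <- cor(matrix(y[mz], ncol = 2, byrow = TRUE))[1, 2]
    rdz <- cor(matrix(y[dz], ncol = 2, byrow = TRUE))[1, 2]
    expect_lt(abs(rmz - 0.6), 0.03)
    expect_lt(abs(rdz - 0.4), 0.03)
  }
  expect_lt(max(abs(as.matrix(co$truth$ace[, c("a2", "c2", "e2")]) -
                    matrix(c(0.4, 0.2, 0.4), 3, 3, byrow = TRUE))), 0.03)

  cfg0 <- sim_config(n_mz_pairs = 2000, n_dz_pairs = 2000, n_singletons = 0,
                     n_variants = 2, n_cpgs = 2, n_genes = 1,
                     ace_targets = c(0, 0.3, 0.7), seed = 22)
  co0 <- simulate_twin_cohort(cfg0)
  y <- co0$meth$latent[1, ]
  rmz <- cor(matrix(y[co0$ped$zygosity == "MZ"], ncol = 2, byrow = TRUE))[1, 2]
  rdz <- cor(matrix(y[co0$ped$zygosity == "DZ"], ncol = 2, byrow = TRUE))[1, 2]
  expect_lt(abs(rmz - 0.3), 0.03)
  expect_lt(abs(rdz - 0.3), 0.03)
})

test_that("a planted meQTL explains its configured share of latent variance", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 2000,
                    n_variants = 20, n_cpgs = 2, n_genes = 1,
                    ace_targets = c(0.5, 0.1, 0.4),
                    meqtl_effects = data.frame(variant = 5, cpg = 1,
                                               effect = sqrt(0.2),
                                               class = "cis"),
                    seed = 31)
  co <- simulate_twin_cohort(cfg)
  g <- co$geno$dosage[5, ]
  r2 <- summary(lm(co$meth$latent[1, ] ~ g))$r.squared
  expect_lt(abs(r2 - 0.20), 0.03)
  expect_error(
    simulate_twin_cohort(sim_config(
      n_mz_pairs = 5, n_dz_pairs = 5, n_singletons = 0, n_variants = 10,
      n_cpgs = 1, n_genes = 1, ace_targets = c(0.1, 0.1, 0.8),
      meqtl_effects = data.frame(variant = 1, cpg = 1, effect = 0.9,
                                 class = "cis"), seed = 1)),
    "exceeds the target a2")
})

test_that("full SME mediation leaves no direct SNP path to the gene", {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 2000,
                    n_variants = 10, n_cpgs = 2, n_genes = 2,
                    ace_targets = c(0.4, 0.1, 0.5),
                    meqtl_effects = data.frame(variant = 3, cpg = 1,
                                               effect = 0.55, class = "cis"),
                    mediation_specs = data.frame(variant = 3, cpg = 1,
                                                 gene = 1, model = "SME",
                                                 prop = 1.0),
                    expr_family_var = 0, seed = 41)
  co <- simulate_twin_cohort(cfg)
  g <- co$geno$dosage[3, ]
  m <- co$meth$latent[1, ]
  y <- co$expr$values[1, ]
  pc <- cor(resid(lm(y ~ m)), resid(lm(g ~ m)))
  expect_lt(abs(pc), 0.05)
  expect_error(sim_config(n_mz_pairs = 1, n_dz_pairs = 1, n_singletons = 0,
                          n_variants = 5, n_cpgs = 1, n_genes = 1,
                          mediation_specs = data.frame(
                            variant = 1, cpg = 1, gene = 1, model = "SME",
                            prop = 1.5)),
               "proportion outside")
})

test_that("exports round-trip through VCF and TSV", {
  cfg <- sim_config(n_mz_pairs = 4, n_dz_pairs = 4, n_singletons = 3,
                    n_variants = 60, n_cpgs = 10, n_genes = 5, seed = 51)
  co <- simulate_twin_cohort(cfg)
  td <- withr::local_tempdir()

  vcf <- file.path(td, "g.vcf")
  write_vcf(co$geno, vcf)
  back <- read_vcf_genotypes(vcf)
  expect_identical(unname(back$dosage), unname(co$geno$dosage))
  expect_identical(back$variants$coded, co$geno$variants$coded)

  dtsv <- file.path(td, "g.tsv")
  write_dosage_tsv(co$geno, dtsv)
  back2 <- read_dosage_tsv(dtsv)
  expect_identical(unname(back2$dosage), unname(co$geno$dosage))

  ptsv <- file.path(td, "ped.tsv")
  write_pedigree_tsv(co$ped, ptsv)
  expect_identical(as.data.frame(read_pedigree_tsv(ptsv)),
                   as.data.frame(co$ped))

  mtsv <- file.path(td, "m.tsv")
  write_phenotype_tsv(co$meth, mtsv)
  back3 <- read_phenotype_tsv(mtsv)
  expect_identical(unname(back3$values), unname(co$meth$values))
})

test_that("the package VCF writer agrees with an independent VCF reader", {
  skip_if_not_installed("vcfR")
  cfg <- sim_config(n_mz_pairs = 3, n_dz_pairs = 3, n_singletons = 2,
                    n_variants = 40, n_cpgs = 2, n_genes = 2, seed = 61)
  co <- simulate_twin_cohort(cfg)
  td <- withr::local_tempdir()
  vcf <- file.path(td, "g.vcf")
  write_vcf(co$geno, vcf)
  v <- suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE))
  gt <- vcfR::extract.gt(v)
  alt_dos <- matrix(0L, nrow(gt), ncol(gt))
  alt_dos[gt == "0/1"] <- 1L
  alt_dos[gt == "1/1"] <- 2L
  coded_dos <- alt_dos
  flip <- co$geno$variants$coded == co$geno$variants$ref
  coded_dos[flip, ] <- 2L - alt_dos[flip, ]
  expect_identical(unname(coded_dos), unname(co$geno$dosage))
})
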