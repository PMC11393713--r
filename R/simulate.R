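#' Configuration for the synthetic twin cohort
#'
#' Bundles all generator parameters: cohort composition, genotype
#' architecture (variant count, chromosomes, MAF range, adjacent-variant LD),
#' methylome ACE structure, planted meQTL/eQTL effects and mediated triplets.
#' Defaults reproduce the study design the package emulates: 35 MZ pairs,
#' 70 DZ pairs and 204 singletons (414 individuals), variants with MAF > 0.05,
#' and CpGs whose average narrow-sense heritability is low (~10%) with most
#' variance unique-environmental.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons Cohort composition.
#' @param n_variants,n_chromosomes,chrom_length Genotype map; variant
#'   positions are uniform on chromosomes of \code{chrom_length} bp so both
#'   cis and trans configurations arise.
#' @param maf_range Per-variant minor-allele frequency range, in (0, 0.5].
#' @param ld_rho Adjacent-variant haplotype correlation in [0, 1) of the
#'   first-order Markov chain generating founder haplotypes.
#' @param n_cpgs,n_genes Feature counts.
#' @param ace_targets Per-CpG (a2, c2, e2) variance proportions: a length-3
#'   vector recycled to all CpGs or an \code{n_cpgs} x 3 matrix. Each row
#'   must be nonnegative and sum to 1.
#' @param beta_slope Slope of the logistic map from latent methylation to
#'   beta-values (nuisance shape parameter; downstream analysis is
#'   rank-based so only monotonicity matters).
#' @param meqtl_effects data.frame(variant, cpg, effect, class) of planted
#'   methylation QTLs; \code{variant}/\code{cpg} are indices, \code{effect}
#'   the coefficient on the standardized dosage (variance explained =
#'   effect^2), \code{class} "cis" or "trans" (controls CpG placement).
#' @param eqtl_effects data.frame(variant, gene, effect) of planted local
#'   expression QTLs.
#' @param mediation_specs data.frame(variant, cpg, gene, model, prop,
#'   total) of mediated triplets; \code{model} is "SME" (methylation mediates
#'   the SNP effect on expression) or "SEM" (expression mediates the SNP
#'   effect on methylation); \code{prop} is the target proportion mediated in
#'   [0, 1]; \code{total} the total SNP effect on the outcome (default 0.5).
#' @param expr_family_var Variance proportion of a family-shared component in
#'   non-mediated gene expression.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_mz_pairs = 35, n_dz_pairs = 70, n_singletons = 204,
                       n_variants = 2000, n_chromosomes = 2,
                       chrom_length = 1e7, maf_range = c(0.05, 0.5),
                       ld_rho = 0.7, n_cpgs = 500, n_genes = 200,
                       ace_targets = c(0.10, 0.05, 0.85), beta_slope = 1,
                       meqtl_effects = NULL, eqtl_effects = NULL,
                       mediation_specs = NULL, expr_family_var = 0.1,
                       seed = 1L) {
  if (is.vector(ace_targets) && length(ace_targets) == 3L)
    ace_targets <- matrix(ace_targets, n_cpgs, 3, byrow = TRUE)
  ace_targets <- as.matrix(ace_targets)
  colnames(ace_targets) <- c("a2", "c2", "e2")
  cfg <- structure(list(
    n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
    n_singletons = n_singletons, n_variants = n_variants,
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    maf_range = maf_range, ld_rho = ld_rho, n_cpgs = n_cpgs,
    n_genes = n_genes, ace_targets = ace_targets, beta_slope = beta_slope,
    meqtl_effects = meqtl_effects, eqtl_effects = eqtl_effects,
    mediation_specs = mediation_specs, expr_family_var = expr_family_var,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  a <- cfg$ace_targets
  if (nrow(a) != cfg$n_cpgs) stopf("ace_targets must have one row per CpG")
  if (any(a < -1e-12)) stopf("ace_targets must be nonnegative")
  if (any(abs(rowSums(a) - 1) > 1e-9)) stopf("each (a2, c2, e2) must sum to 1")
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stopf("maf_range must lie within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stopf("ld_rho must be in [0, 1)")
  if (cfg$n_variants < 1) stopf("n_variants must be >= 1")
  chk <- function(idx, n, what)
    if (length(idx) && (any(idx < 1) || any(idx > n)))
      stopf("%s index out of range", what)
  if (!is.null(cfg$meqtl_effects)) {
    chk(cfg$meqtl_effects$variant, cfg$n_variants, "meQTL variant")
    chk(cfg$meqtl_effects$cpg, cfg$n_cpgs, "meQTL CpG")
  }
  if (!is.null(cfg$eqtl_effects)) {
    chk(cfg$eqtl_effects$variant, cfg$n_variants, "eQTL variant")
    chk(cfg$eqtl_effects$gene, cfg$n_genes, "eQTL gene")
  }
  if (!is.null(cfg$mediation_specs)) {
    ms <- cfg$mediation_specs
    chk(ms$variant, cfg$n_variants, "mediation variant")
    chk(ms$cpg, cfg$n_cpgs, "mediation CpG")
    chk(ms$gene, cfg$n_genes, "mediation gene")
    if (any(ms$prop < 0 | ms$prop > 1))
      stopf("mediation proportion outside [0,1]")
    if (!all(ms$model %in% c("SME", "SEM"))) stopf("model must be SME or SEM")
    for (k in seq_len(nrow(ms))) {
      if (ms$model[k] == "SME") {
        ok <- !is.null(cfg$meqtl_effects) &&
          any(cfg$meqtl_effects$variant == ms$variant[k] &
              cfg$meqtl_effects$cpg == ms$cpg[k])
        if (!ok) stopf("SME triplet %d needs a planted meQTL for its (variant, CpG)", k)
      } else {
        ok <- !is.null(cfg$eqtl_effects) &&
          any(cfg$eqtl_effects$variant == ms$variant[k] &
              cfg$eqtl_effects$gene == ms$gene[k])
        if (!ok) stopf("SEM triplet %d needs a planted eQTL for its (variant, gene)", k)
      }
    }
  }
  invisible(cfg)
}

## Founder haplotypes for one chromosome: binary matrix (n_hap x n_var),
## first-order Markov chain with adjacent-allele correlation rho.
#' @keywords internal
#' @noRd
draw_haplotypes <- function(n_hap, mafs, rho) {
  n_var <- length(mafs)
  H <- matrix(0L, n_hap, n_var)
  H[, 1] <- rbinom(n_hap, 1L, mafs[1])
  if (n_var > 1) for (j in 2:n_var) {
    p0 <- mafs[j - 1]; p1 <- mafs[j]
    s <- sqrt(p1 * (1 - p1))
    q1 <- min(max(p1 + rho * s * sqrt((1 - p0) / p0), 0), 1)
    q0 <- min(max(p1 - rho * s * sqrt(p0 / (1 - p0)), 0), 1)
    pr <- ifelse(H[, j - 1] == 1L, q1, q0)
    H[, j] <- rbinom(n_hap, 1L, pr)
  }
  H
}

#' Simulate genotypes for a twin pedigree
#'
#' Founder haplotypes are drawn per chromosome by a first-order Markov chain
#' with adjacent-allele correlation \code{ld_rho} and per-variant MAF uniform
#' on \code{maf_range}. Each family has one simulated parent pair; DZ
#' co-twins receive independent whole-chromosome transmissions (so per-locus
#' IBD varies realistically around an expectation of 1/2), MZ co-twins
#' duplicate one offspring's genotype, and singletons draw two founder
#' haplotypes directly. Dosages are oriented to the minor allele.
#'
#' @param ped A \code{twin_pedigree}.
#' @param cfg A \code{sim_config}.
#' @return A \code{genotype_matrix}: list with \code{dosage} (variants x
#'   samples, values 0/1/2), \code{variants} (id, chrom, pos, ref, alt,
#'   coded, maf) and \code{samples}.
#' @export
simulate_genotypes <- function(ped, cfg) {
  validate_sim_config(cfg)
  if (cfg$n_variants < 1) stopf("n_variants must be positive")
  n <- nrow(ped)
  idx <- pair_index(ped)
  n_chr <- cfg$n_chromosomes
  per_chr <- diff(floor(seq(0, cfg$n_variants, length.out = n_chr + 1)))
  chrom <- rep(seq_len(n_chr), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(cfg$chrom_length, k))), use.names = FALSE)
  mafs <- runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])

  n_fam <- length(idx$pairs)
  n_single <- length(idx$singletons)
  dosage <- matrix(0L, cfg$n_variants, n)
  for (cc in seq_len(n_chr)) {
    vj <- which(chrom == cc)
    H <- draw_haplotypes(4L * n_fam + 2L * n_single, mafs[vj], cfg$ld_rho)
    ## haplotype rows: per family (pat1, pat2, mat1, mat2), then singletons
    for (f in seq_len(n_fam)) {
      base <- 4L * (f - 1L)
      members <- idx$pairs[[f]]
      if (idx$zygosity[f] == "MZ") {
        child <- H[base + sample(1:2, 1), ] + H[base + 2L + sample(1:2, 1), ]
        dosage[vj, members[1]] <- child
        dosage[vj, members[2]] <- child
      } else {
        for (m in 1:2) {
          dosage[vj, members[m]] <-
            H[base + sample(1:2, 1), ] + H[base + 2L + sample(1:2, 1), ]
        }
      }
    }
    for (s in seq_len(n_single)) {
      base <- 4L * n_fam + 2L * (s - 1L)
      dosage[vj, idx$singletons[s]] <- H[base + 1L, ] + H[base + 2L, ]
    }
  }

  ## random distinct ref/alt nucleotides, then orient dosage to minor allele
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, cfg$n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  f_alt <- rowMeans(dosage) / 2
  flip <- f_alt > 0.5
  if (any(flip)) dosage[flip, ] <- 2L - dosage[flip, ]
  coded <- ifelse(flip, ref, alt)
  maf_obs <- rowMeans(dosage) / 2

  variants <- data.frame(
    id = sprintf("var%05d", seq_len(cfg$n_variants)),
    chrom = chrom, pos = pos, ref = ref, alt = alt, coded = coded,
    maf = maf_obs, stringsAsFactors = FALSE
  )
  rownames(dosage) <- variants$id
  colnames(dosage) <- ped$id
  structure(list(dosage = dosage, variants = variants, samples = ped$id),
            class = "genotype_matrix")
}

## ACE component draws with the required twin correlation structure.
## Returns n_feat x n_sample matrices of unit-variance components.
#' @keywords internal
#' @noRd
draw_ace_components <- function(n_feat, ped) {
  n <- nrow(ped)
  idx <- pair_index(ped)
  A <- matrix(rnorm(n_feat * n), n_feat, n)
  C <- matrix(rnorm(n_feat * n), n_feat, n)
  for (j in seq_along(idx$pairs)) {
    i <- idx$pairs[[j]]
    C[, i[2]] <- C[, i[1]]
    if (idx$zygosity[j] == "MZ") {
      A[, i[2]] <- A[, i[1]]
    } else {
      shared <- rnorm(n_feat)
      A[, i[1]] <- sqrt(0.5) * shared + sqrt(0.5) * A[, i[1]]
      A[, i[2]] <- sqrt(0.5) * shared + sqrt(0.5) * A[, i[2]]
    }
  }
  E <- matrix(rnorm(n_feat * n), n_feat, n)
  list(A = A, C = C, E = E)
}

## Place feature positions honouring declared cis/trans effect classes.
#' @keywords internal
#' @noRd
place_features <- function(n_feat, prefix, cfg, variants, effects,
                           feat_col, window = 1e6) {
  n_chr <- cfg$n_chromosomes
  chrom <- sample.int(n_chr, n_feat, replace = TRUE)
  pos <- sample.int(cfg$chrom_length, n_feat, replace = TRUE)
  if (!is.null(effects) && nrow(effects)) {
    for (k in seq_len(nrow(effects))) {
      f <- effects[[feat_col]][k]
      v <- effects$variant[k]
      cls <- if ("class" %in% names(effects)) effects$class[k] else "cis"
      if (cls == "cis") {
        chrom[f] <- variants$chrom[v]
        lo <- max(1, variants$pos[v] - (window - 1))
        hi <- min(cfg$chrom_length, variants$pos[v] + (window - 1))
        pos[f] <- sample(seq(lo, hi), 1)
      } else {
        ## trans: force a different chromosome when possible, else > window away
        if (n_chr > 1) {
          chrom[f] <- sample(setdiff(seq_len(n_chr), variants$chrom[v]), 1)
        } else if (abs(pos[f] - variants$pos[v]) <= window) {
          pos[f] <- ((variants$pos[v] + round(cfg$chrom_length / 2)) %%
                       cfg$chrom_length) + 1
        }
      }
    }
  }
  data.frame(id = sprintf("%s%05d", prefix, seq_len(n_feat)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate an A/C/E-structured methylome with planted meQTLs
#'
#' Each CpG's latent value is \eqn{y = \sum_k \beta_k g_k + A + C + E} where
#' the additive component A correlates 1 within MZ and 0.5 within DZ pairs,
#' C is shared within all pairs and E is independent; component variances are
#' scaled so the genetic term (planted meQTLs plus residual A) realizes the
#' target a2, C realizes c2 and E realizes e2. Latent values are mapped to
#' (0,1) beta-values by a logistic map around a per-CpG baseline.
#'
#' @param geno A \code{genotype_matrix}.
#' @param ped The matching \code{twin_pedigree}.
#' @param cfg A \code{sim_config}.
#' @return List with \code{meth} (a \code{phenotype_matrix}: \code{values}
#'   beta-value matrix, \code{latent}, \code{features}, \code{samples}) and
#'   \code{truth} (planted effects with realized variance explained and
#'   per-CpG realized ACE proportions).
#' @export
simulate_methylation <- function(geno, ped, cfg) {
  validate_sim_config(cfg)
  n <- nrow(ped)
  a <- cfg$ace_targets
  eff <- cfg$meqtl_effects
  qtl_var <- numeric(cfg$n_cpgs)
  if (!is.null(eff) && nrow(eff))
    qtl_var <- vapply(seq_len(cfg$n_cpgs), function(j)
      sum(eff$effect[eff$cpg == j]^2), numeric(1))
  resid_a <- a[, "a2"] - qtl_var
  if (any(resid_a < -1e-9))
    stopf("planted meQTL variance exceeds the target a2 for CpG(s) %s",
          paste(which(resid_a < -1e-9), collapse = ", "))
  resid_a <- pmax(resid_a, 0)

  comp <- draw_ace_components(cfg$n_cpgs, ped)
  Y <- sqrt(resid_a) * comp$A + sqrt(a[, "c2"]) * comp$C +
    sqrt(a[, "e2"]) * comp$E
  gstd <- row_standardize(geno$dosage)
  if (!is.null(eff) && nrow(eff))
    for (k in seq_len(nrow(eff)))
      Y[eff$cpg[k], ] <- Y[eff$cpg[k], ] + eff$effect[k] * gstd[eff$variant[k], ]

  features <- place_features(cfg$n_cpgs, "cg", cfg, geno$variants, eff, "cpg")
  baseline <- runif(cfg$n_cpgs, 0.05, 0.95)
  B <- plogis(qlogis(baseline) + cfg$beta_slope * Y)
  dimnames(Y) <- dimnames(B) <- list(features$id, ped$id)

  vy <- apply(Y, 1, var)
  realized <- data.frame(
    cpg = features$id,
    a2 = (resid_a * apply(comp$A, 1, var) + qtl_var) / vy,
    c2 = a[, "c2"] * apply(comp$C, 1, var) / vy,
    e2 = a[, "e2"] * apply(comp$E, 1, var) / vy,
    row.names = NULL
  )
  truth_eff <- NULL
  if (!is.null(eff) && nrow(eff)) {
    truth_eff <- data.frame(
      variant = geno$variants$id[eff$variant],
      feature = features$id[eff$cpg],
      effect = eff$effect,
      var_explained = vapply(seq_len(nrow(eff)), function(k)
        var(eff$effect[k] * gstd[eff$variant[k], ]) / vy[eff$cpg[k]],
        numeric(1)),
      class = if ("class" %in% names(eff)) eff$class else
        ifelse(features$chrom[eff$cpg] == geno$variants$chrom[eff$variant] &
                 abs(features$pos[eff$cpg] - geno$variants$pos[eff$variant]) < 1e6,
               "cis", "trans"),
      stringsAsFactors = FALSE
    )
  }
  meth <- structure(list(values = B, latent = Y, features = features,
                         samples = ped$id), class = "phenotype_matrix")
  list(meth = meth,
       truth = list(effects = truth_eff, ace = realized))
}

#' Simulate gene expression with planted eQTLs and mediated triplets
#'
#' Non-mediated genes are a sum of planted standardized-dosage eQTL effects,
#' an optional family-shared component and independent noise, scaled to unit
#' variance. SME triplets route a configurable proportion of the total SNP
#' effect on the gene through the CpG's latent methylation; SEM triplets
#' rewrite the CpG so the SNP effect on methylation flows through the gene's
#' abundance, so the (possibly updated) methylation matrix is returned too.
#'
#' @param geno,meth,ped,cfg Simulated genotypes, methylation (from
#'   \code{\link{simulate_methylation}}), pedigree, configuration.
#' @return List with \code{expr} (a \code{phenotype_matrix} with gene TSS
#'   coordinates), \code{meth} (possibly updated) and \code{truth}
#'   (planted eQTLs and mediation ground truth).
#' @export
simulate_expression <- function(geno, meth, ped, cfg) {
  validate_sim_config(cfg)
  n <- nrow(ped)
  eff <- cfg$eqtl_effects
  ms <- cfg$mediation_specs
  gstd <- row_standardize(geno$dosage)

  qtl_var <- numeric(cfg$n_genes)
  if (!is.null(eff) && nrow(eff))
    qtl_var <- vapply(seq_len(cfg$n_genes), function(j)
      sum(eff$effect[eff$gene == j]^2), numeric(1))
  fam_var <- cfg$expr_family_var
  noise_var <- 1 - qtl_var - fam_var
  if (any(noise_var < 0)) stopf("planted eQTL variance exceeds 1")

  comp_fam <- draw_ace_components(cfg$n_genes, ped)$C
  Eg <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  X <- sqrt(fam_var) * comp_fam + sqrt(noise_var) * Eg
  if (!is.null(eff) && nrow(eff))
    for (k in seq_len(nrow(eff)))
      X[eff$gene[k], ] <- X[eff$gene[k], ] + eff$effect[k] * gstd[eff$variant[k], ]

  features <- place_features(cfg$n_genes, "gene", cfg, geno$variants, eff, "gene")
  meth_out <- meth
  truth_med <- NULL

  if (!is.null(ms) && nrow(ms)) {
    truth_med <- ms
    truth_med$total <- if ("total" %in% names(ms)) ms$total else 0.5
    for (k in seq_len(nrow(ms))) {
      v <- ms$variant[k]; j <- ms$cpg[k]; g <- ms$gene[k]
      tau <- truth_med$total[k]; pr <- ms$prop[k]
      if (ms$model[k] == "SME") {
        a_m <- cfg$meqtl_effects$effect[
          cfg$meqtl_effects$variant == v & cfg$meqtl_effects$cpg == j][1]
        b <- pr * tau / a_m
        cdir <- (1 - pr) * tau
        mlat <- meth_out$latent[j, ]
        sig_var <- cdir^2 + b^2 + 2 * cdir * b * a_m
        if (sig_var >= 1) stopf("SME triplet %d signal variance >= 1", k)
        X[g, ] <- cdir * gstd[v, ] + b * mlat +
          sqrt(1 - sig_var) * rnorm(n)
        ## gene TSS near the variant (colocalization-style local triplet)
        features$chrom[g] <- geno$variants$chrom[v]
        features$pos[g] <- min(max(1, geno$variants$pos[v] +
                                     sample(-5e5:5e5, 1)), cfg$chrom_length)
      } else {
        a_g <- cfg$eqtl_effects$effect[
          cfg$eqtl_effects$variant == v & cfg$eqtl_effects$gene == g][1]
        b <- pr * tau / a_g
        cdir <- (1 - pr) * tau
        sig_var <- cdir^2 + b^2 + 2 * cdir * b * a_g
        if (sig_var >= 1) stopf("SEM triplet %d signal variance >= 1", k)
        ylat <- cdir * gstd[v, ] + b * X[g, ] + sqrt(1 - sig_var) * rnorm(n)
        meth_out$latent[j, ] <- ylat
        base_j <- qlogis(mean(meth_out$values[j, ]))
        meth_out$values[j, ] <- plogis(base_j + cfg$beta_slope * ylat)
        meth_out$features$chrom[j] <- geno$variants$chrom[v]
        meth_out$features$pos[j] <- min(max(1, geno$variants$pos[v] +
                                              sample(-5e5:5e5, 1)),
                                        cfg$chrom_length)
      }
    }
    truth_med <- data.frame(
      variant = geno$variants$id[ms$variant],
      cpg = meth_out$features$id[ms$cpg],
      gene = features$id[ms$gene],
      model = ms$model, prop = ms$prop, total = truth_med$total,
      stringsAsFactors = FALSE
    )
  }

  dimnames(X) <- list(features$id, ped$id)
  truth_eff <- NULL
  if (!is.null(eff) && nrow(eff)) {
    vx <- apply(X, 1, var)
    truth_eff <- data.frame(
      variant = geno$variants$id[eff$variant],
      feature = features$id[eff$gene],
      effect = eff$effect,
      var_explained = vapply(seq_len(nrow(eff)), function(k)
        eff$effect[k]^2 / vx[eff$gene[k]], numeric(1)),
      class = "cis", stringsAsFactors = FALSE
    )
  }
  expr <- structure(list(values = X, latent = NULL, features = features,
                         samples = ped$id), class = "phenotype_matrix")
  list(expr = expr, meth = meth_out,
       truth = list(effects = truth_eff, mediation = truth_med))
}

#' Simulate a complete twin cohort
#'
#' Orchestrates pedigree, genotypes, methylome and transcriptome generation
#' with deterministic per-stage seeds derived from the master seed.
#'
#' @param cfg A \code{sim_config}.
#' @return List: \code{ped}, \code{geno}, \code{meth}, \code{expr},
#'   \code{truth} (effects, realized ACE, mediation).
#' @export
simulate_twin_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, 1L))
  ped <- simulate_pedigree(cfg$n_mz_pairs, cfg$n_dz_pairs, cfg$n_singletons)
  set.seed(stage_seed(cfg$seed, 2L))
  geno <- simulate_genotypes(ped, cfg)
  set.seed(stage_seed(cfg$seed, 3L))
  sm <- simulate_methylation(geno, ped, cfg)
  set.seed(stage_seed(cfg$seed, 4L))
  se <- simulate_expression(geno, sm$meth, ped, cfg)
  list(ped = ped, geno = geno, meth = se$meth, expr = se$expr,
       truth = list(meqtl = sm$truth$effects, ace = sm$truth$ace,
                    eqtl = se$truth$effects, mediation = se$truth$mediation))
}
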