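#' Pipeline configuration
#'
#' Single source of parameters for an end-to-end run: the simulation
#' configuration (or paths to pre-simulated inputs), stage toggles and all
#' stage parameters.
#'
#' @param sim A \code{sim_config}.
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("simulate", "preprocess", "herit", "scan", "conditional",
#'   "coloc", "mediate", "compare", "enrich")}.
#' @param scan A \code{scan_config}.
#' @param n_factors Latent factors removed during preprocessing.
#' @param eqtl_n_perm Per-gene permutations for the gene-level FDR
#'   (default 200).
#' @param r2_cap Collinearity cap for stepwise selection.
#' @param shared_fraction_candidates Candidate p12 shared fractions.
#' @param prior_sd ABF prior effect-size SD.
#' @param annotations Optional list of \code{annotation_set}s for the
#'   enrichment stage (a two-arm chromosome tiling is used if NULL).
#' @param catalog Optional named list trait -> feature IDs for catalog
#'   enrichment.
#' @param seed Master seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "preprocess", "herit",
                                       "scan", "conditional", "coloc",
                                       "mediate", "compare", "enrich"),
                            scan = scan_config(), n_factors = 5,
                            eqtl_n_perm = 200, r2_cap = 0.9,
                            shared_fraction_candidates = c(0.10, 0.25, 0.50, 0.75),
                            prior_sd = 0.15, annotations = NULL,
                            catalog = NULL, seed = 1L) {
  known <- c("simulate", "preprocess", "herit", "scan", "conditional",
             "coloc", "mediate", "compare", "enrich")
  if (!all(stages %in% known)) stopf("unknown stage(s)")
  structure(list(sim = sim, stages = stages, scan = scan,
                 n_factors = n_factors, eqtl_n_perm = eqtl_n_perm,
                 r2_cap = r2_cap,
                 shared_fraction_candidates = shared_fraction_candidates,
                 prior_sd = prior_sd, annotations = annotations,
                 catalog = catalog, seed = as.integer(seed)),
            class = "pipeline_config")
}

## Require that an upstream product exists for an enabled stage.
#' @keywords internal
#' @noRd
need_stage <- function(state, what, stage) {
  if (is.null(state[[what]]))
    stopf("%s requires %s output (stage disabled or failed)", stage, what)
  state[[what]]
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> herit -> scan -> conditional -> coloc
#' -> mediate -> compare -> enrich, skipping disabled stages (an enabled
#' stage whose upstream product is missing raises an error naming the
#' stage). Summary tables are written as TSV under \code{out_dir} together
#' with a JSON manifest recording the package version, seeds and per-stage
#' record counts. Two runs with identical configuration produce identical
#' outputs.
#'
#' @param cfg A \code{pipeline_config}.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with all in-memory stage products.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- list()
  manifest <- list(package = "twinqtl",
                   version = as.character(utils::packageVersion("twinqtl")),
                   seed = cfg$seed, stages = cfg$stages, counts = list())
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("simulate" %in% cfg$stages) {
    st$cohort <- simulate_twin_cohort(cfg$sim)
    write_pedigree_tsv(st$cohort$ped, file.path(out_dir, "pedigree.tsv"))
    write_vcf(st$cohort$geno, file.path(out_dir, "genotypes.vcf"))
    write_phenotype_tsv(st$cohort$meth, file.path(out_dir, "methylation.tsv"))
    write_phenotype_tsv(st$cohort$expr, file.path(out_dir, "expression.tsv"))
    if (!is.null(st$cohort$truth$meqtl))
      wtsv(st$cohort$truth$meqtl, "truth_meqtl.tsv")
    wtsv(st$cohort$truth$ace, "truth_ace.tsv")
    manifest$counts$simulate <- list(samples = nrow(st$cohort$ped),
                                     variants = nrow(st$cohort$geno$variants))
  }

  if ("preprocess" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "preprocess")
    rec <- adjustment_recipe(n_factors = cfg$n_factors)
    set.seed(stage_seed(cfg$seed, 10L))
    st$meth_adj <- adjust_phenotypes(co$meth, co$ped, geno = co$geno,
                                     recipe = rec)
    st$expr_adj <- adjust_phenotypes(co$expr, co$ped, geno = co$geno,
                                     recipe = rec)
    wtsv(data.frame(st$meth_adj$features,
                    as.data.frame(st$meth_adj$values)), "meth_residuals.tsv")
    manifest$counts$preprocess <- list(cpgs = nrow(st$meth_adj$values),
                                       genes = nrow(st$expr_adj$values))
  }

  if ("herit" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "herit")
    vals <- rint_rows(co$meth$values)
    dimnames(vals) <- dimnames(co$meth$values)
    st$herit <- heritability_scan(vals, co$ped)
    wtsv(st$herit, "heritability.tsv")
    manifest$counts$herit <- list(features = nrow(st$herit),
                                  mean_a2 = attr(st$herit, "mean_a2"))
  }

  if ("scan" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "scan")
    ma <- need_stage(st, "meth_adj", "scan")
    st$scan <- association_scan(ma, co$geno, cfg$scan)
    ## twin-aware permutation FDR on the methylation scan
    perm_cis <- perm_trans <- matrix(NA_real_, nrow(st$scan$best), cfg$scan$n_perm)
    for (b in seq_len(cfg$scan$n_perm)) {
      gp <- twin_aware_permutation(co$geno, co$ped,
                                   seed = stage_seed(cfg$seed, 100L + b))
      sp <- association_scan(ma, gp, cfg$scan)
      perm_cis[, b] <- sp$best$best_cis_p
      perm_trans[, b] <- sp$best$best_trans_p
    }
    st$fdr_cis <- permutation_fdr_thresholds(st$scan$best$best_cis_p,
                                             perm_cis, cfg$scan$fdr_level)
    st$fdr_trans <- permutation_fdr_thresholds(st$scan$best$best_trans_p,
                                               perm_trans, cfg$scan$fdr_level)
    ## eQTL scan: cis only, gene-level beta-approximated FDR
    ea <- need_stage(st, "expr_adj", "scan")
    st$escan <- association_scan(ea, co$geno,
                                 scan_config(cis_p = 0.999999,
                                             trans_p = 1e-300,
                                             seed = cfg$seed))
    set.seed(stage_seed(cfg$seed, 200L))
    st$egene_fdr <- egene_beta_fdr(ea, co$geno, n_perm = cfg$eqtl_n_perm,
                                   level = cfg$scan$fdr_level)
    wtsv(st$scan$hits, "meqtl_hits.tsv")
    jsonlite::write_json(list(cis = unclass(st$fdr_cis),
                              trans = unclass(st$fdr_trans)),
                         file.path(out_dir, "meqtl_thresholds.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    wtsv(st$egene_fdr, "egene_fdr.tsv")
    manifest$counts$scan <- list(meqtl_hits = nrow(st$scan$hits),
                                 egenes = sum(st$egene_fdr$significant))
  }

  if ("conditional" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "conditional")
    ma <- need_stage(st, "meth_adj", "conditional")
    sc <- need_stage(st, "scan", "conditional")
    st$signals <- conditional_stage(co, ma, sc, st$fdr_cis, st$fdr_trans,
                                    cfg$r2_cap)
    wtsv(st$signals, "independent_signals.tsv")
    manifest$counts$conditional <- list(signals = nrow(st$signals))
  }

  if ("coloc" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "coloc")
    need_stage(st, "scan", "coloc")
    sig <- need_stage(st, "signals", "coloc")
    st$coloc <- coloc_stage(co, st, cfg)
    if (nrow(st$coloc$results)) wtsv(st$coloc$results, "coloc.tsv")
    manifest$counts$coloc <- list(pairs = nrow(st$coloc$results),
                                  shared_fraction = st$coloc$shared_fraction)
  }

  if ("mediate" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "mediate")
    cl <- need_stage(st, "coloc", "mediate")
    st$mediation <- mediation_stage(co, st, cl)
    if (nrow(st$mediation)) wtsv(st$mediation, "mediation.tsv")
    manifest$counts$mediate <- list(triplets = nrow(st$mediation))
  }

  if ("compare" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "compare")
    ma <- need_stage(st, "meth_adj", "compare")
    st$compare <- compare_stage(co, ma, cfg)
    jsonlite::write_json(st$compare, file.path(out_dir, "replication.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest$counts$compare <- st$compare["pi1"]
  }

  if ("enrich" %in% cfg$stages) {
    co <- need_stage(st, "cohort", "enrich")
    sc <- need_stage(st, "scan", "enrich")
    st$enrich <- enrich_stage(co, sc, st$fdr_cis, cfg)
    wtsv(st$enrich, "enrichment.tsv")
    manifest$counts$enrich <- list(annotations = nrow(st$enrich))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(st)
}

## Gene-level FDR for the expression scan: per-gene minima over cis
## variants for observed and permuted phenotypes, then the beta fit.
#' @keywords internal
#' @noRd
egene_beta_fdr <- function(expr_adj, geno, n_perm = 200, level = 0.05,
                           window = 1e6) {
  Y <- expr_adj$values
  n <- ncol(Y)
  obs <- rep(NA_real_, nrow(Y))
  pm <- matrix(NA_real_, nrow(Y), n_perm)
  for (i in seq_len(nrow(Y))) {
    f <- expr_adj$features[i, ]
    cis <- which(geno$variants$chrom == f$chrom &
                   abs(geno$variants$pos - f$pos) < window)
    if (length(cis) < 2) next
    G <- geno$dosage[cis, , drop = FALSE]
    gc <- G - rowMeans(G)
    sg <- sqrt(rowSums(gc^2))
    keep <- sg > 0
    if (!any(keep)) next
    gc <- gc[keep, , drop = FALSE] / sg[keep]
    y <- Y[i, ]
    P <- vapply(seq_len(n_perm), function(b) sample(y), numeric(n))
    yall <- cbind(y - mean(y), P - rep(colMeans(P), each = n))
    yall <- sweep(yall, 2, sqrt(colSums(yall^2)), "/")
    r <- crossprod(t(gc), yall)  # variants x (1 + n_perm) correlations
    r2 <- r^2
    tt2 <- r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps)
    pmin_all <- apply(2 * pt(-sqrt(tt2), n - 2), 2, min)
    obs[i] <- pmin_all[1]
    pm[i, ] <- pmin_all[-1]
  }
  ok <- !is.na(obs)
  res <- data.frame(feature = expr_adj$features$id, observed_min_p = obs,
                    shape1 = NA_real_, shape2 = NA_real_,
                    empirical_p = NA_real_, q = NA_real_,
                    significant = FALSE, nominal_threshold = NA_real_)
  if (any(ok)) {
    sub <- gene_level_beta_fdr(obs[ok], pm[ok, , drop = FALSE], level = level)
    res$shape1[ok] <- sub$shape1
    res$shape2[ok] <- sub$shape2
    res$empirical_p[ok] <- sub$empirical_p
    res$q[ok] <- sub$q
    res$significant[ok] <- sub$significant
    res$nominal_threshold[ok] <- sub$nominal_threshold
  }
  res
}

#' @keywords internal
#' @noRd
conditional_stage <- function(co, ma, sc, fdr_cis, fdr_trans, r2_cap) {
  thr_cis <- fdr_cis$threshold
  thr_trans <- fdr_trans$threshold
  out <- NULL
  for (f in unique(sc$hits$feature)) {
    hf <- sc$hits[sc$hits$feature == f, ]
    i <- match(f, ma$features$id)
    y <- ma$values[i, ]
    cis_ids <- hf$variant[hf$class == "cis" &
                            (!is.na(thr_cis) & hf$p <= thr_cis)]
    trans_ids <- hf$variant[hf$class == "trans" &
                              (!is.na(thr_trans) & hf$p <= thr_trans)]
    sel_cis <- NULL
    if (length(cis_ids)) {
      gsub1 <- subset_geno(co$geno, cis_ids)
      sel_cis <- stepwise_select(y, gsub1, thr_cis, r2_cap)
      if (length(sel_cis$variants))
        out <- rbind(out, cbind(feature = f, sel_cis$joint,
                                class = "cis", cis_confounded = FALSE))
    }
    if (length(trans_ids)) {
      gtr <- subset_geno(co$geno, trans_ids)
      gcs <- if (!is.null(sel_cis) && length(sel_cis$variants))
        subset_geno(co$geno, sel_cis$variants) else NULL
      jt <- joint_cis_trans_conditional(y, gtr, gcs, thr_trans, r2_cap)
      if (length(jt$trans_retained)) {
        jj <- jt$joint[jt$joint$variant %in% jt$trans_retained, , drop = FALSE]
        out <- rbind(out, cbind(feature = f, jj, class = "trans",
                                cis_confounded = FALSE))
      }
      if (length(jt$cis_confounded))
        out <- rbind(out, data.frame(feature = f, variant = jt$cis_confounded,
                                     beta = NA, se = NA, t = NA, p = NA,
                                     order = NA, class = "trans",
                                     cis_confounded = TRUE))
    }
  }
  if (is.null(out)) out <- data.frame(feature = character(0),
                                      variant = character(0), beta = numeric(0),
                                      se = numeric(0), t = numeric(0),
                                      p = numeric(0), order = integer(0),
                                      class = character(0),
                                      cis_confounded = logical(0))
  out
}

#' @keywords internal
#' @noRd
subset_geno <- function(geno, ids) {
  j <- match(ids, geno$variants$id)
  list(dosage = geno$dosage[j, , drop = FALSE],
       variants = geno$variants[j, , drop = FALSE],
       samples = geno$samples)
}

#' @keywords internal
#' @noRd
coloc_stage <- function(co, st, cfg, window = 1e6) {
  eg <- st$egene_fdr[st$egene_fdr$significant, , drop = FALSE]
  sig_cis <- st$signals[st$signals$class == "cis" & !st$signals$cis_confounded, ]
  results <- NULL
  regions <- list()
  meta <- NULL
  for (g in eg$feature) {
    gi <- match(g, st$expr_adj$features$id)
    gf <- st$expr_adj$features[gi, ]
    cis <- which(co$geno$variants$chrom == gf$chrom &
                   abs(co$geno$variants$pos - gf$pos) < window)
    if (length(cis) < 2) next
    ## lead eQTL variants: best-associated among gene's cis hits
    ehits <- st$escan$hits[st$escan$hits$feature == g, ]
    if (!nrow(ehits)) next
    leads <- ehits$variant[which.min(ehits$p)]
    ## pairing rule: CpGs significantly cis-associated with a lead variant
    cand_cpgs <- unique(st$scan$hits$feature[
      st$scan$hits$variant %in% leads & st$scan$hits$class == "cis" &
        !is.na(st$fdr_cis$threshold) & st$scan$hits$p <= st$fdr_cis$threshold])
    for (cpg in cand_cpgs) {
      ci <- match(cpg, st$meth_adj$features$id)
      y1 <- st$expr_adj$values[gi, ]
      y2 <- st$meth_adj$values[ci, ]
      G <- co$geno$dosage[cis, , drop = FALSE]
      sm1 <- per_variant_summaries(y1, G)
      sm2 <- per_variant_summaries(y2, G)
      regions[[length(regions) + 1L]] <-
        list(beta1 = sm1[, 1], se1 = sm1[, 2],
             beta2 = sm2[, 1], se2 = sm2[, 2])
      meta <- rbind(meta, data.frame(gene = g, cpg = cpg,
                                     lead_variant = leads,
                                     stringsAsFactors = FALSE))
    }
  }
  if (!length(regions))
    return(list(results = data.frame(), shared_fraction = NA, priors = NULL))
  counts <- list(
    n_indep_1 = max(sum(st$egene_fdr$significant), 1),
    n_tested_1 = nrow(co$geno$variants),
    n_indep_2 = max(nrow(sig_cis), 1),
    n_tested_2 = nrow(co$geno$variants))
  sel <- select_shared_fraction(regions, counts,
                                cfg$shared_fraction_candidates, cfg$prior_sd)
  pps <- t(vapply(regions, function(rg)
    coloc_abf(rg, sel$priors, cfg$prior_sd)$pp, numeric(5)))
  res <- cbind(meta, as.data.frame(pps))
  names(res)[4:8] <- paste0("PP", 0:4)
  res$pp4 <- res$PP4
  list(results = res, shared_fraction = sel$shared_fraction,
       priors = sel$priors)
}

#' @keywords internal
#' @noRd
per_variant_summaries <- function(y, G) {
  t(vapply(seq_len(nrow(G)), function(j) {
    s <- joint_stats(y, cbind(1, G[j, ]))
    c(s$beta[2], s$se[2])
  }, numeric(2)))
}

#' @keywords internal
#' @noRd
mediation_stage <- function(co, st, cl, q_level = 0.05) {
  tri <- build_triplets(cl$results)
  if (!nrow(tri)) return(data.frame())
  rows <- NULL
  for (k in seq_len(nrow(tri))) {
    g <- co$geno$dosage[match(tri$variant[k], co$geno$variants$id), ]
    mv <- st$meth_adj$values[match(tri$cpg[k], st$meth_adj$features$id), ]
    ev <- st$expr_adj$values[match(tri$gene[k], st$expr_adj$features$id), ]
    both <- mediation_test_both(g, mv, ev)
    for (mod in c("SME", "SEM")) {
      r <- both[[mod]]
      rows <- rbind(rows, data.frame(
        variant = tri$variant[k], cpg = tri$cpg[k], gene = tri$gene[k],
        model = mod, beta_unadjusted = r$beta_unadjusted,
        beta_adjusted = r$beta_adjusted,
        proportion_mediated = r$proportion_mediated,
        sobel_z = r$sobel_z, sobel_p = r$sobel_p, stringsAsFactors = FALSE))
    }
  }
  rows$q <- NA_real_
  for (mod in c("SME", "SEM")) {
    sel <- rows$model == mod
    rows$q[sel] <- p.adjust(rows$sobel_p[sel], "BH")
  }
  rows$chosen <- NA_character_
  for (k in seq_len(nrow(tri))) {
    sme <- rows[rows$model == "SME" & rows$cpg == tri$cpg[k] &
                  rows$gene == tri$gene[k], ][1, ]
    sem <- rows[rows$model == "SEM" & rows$cpg == tri$cpg[k] &
                  rows$gene == tri$gene[k], ][1, ]
    ch <- resolve_model(list(q = sme$q, proportion_mediated = sme$proportion_mediated),
                        list(q = sem$q, proportion_mediated = sem$proportion_mediated),
                        q_level)
    rows$chosen[rows$cpg == tri$cpg[k] & rows$gene == tri$gene[k]] <- ch
  }
  rows
}

## Split-half replication demo: scan each half, harmonize, pi1 + r_b.
#' @keywords internal
#' @noRd
compare_stage <- function(co, ma, cfg) {
  idx <- pair_index(co$ped)
  npair <- length(idx$pairs)
  h1 <- sort(c(unlist(idx$pairs[seq_len(npair %/% 2)]),
               idx$singletons[seq_len(length(idx$singletons) %/% 2)]))
  h2 <- setdiff(seq_len(nrow(co$ped)), h1)
  scan_half <- function(keep) {
    ped_h <- co$ped[keep, ]
    class(ped_h) <- class(co$ped)
    geno_h <- co$geno
    geno_h$dosage <- geno_h$dosage[, keep, drop = FALSE]
    geno_h$samples <- geno_h$samples[keep]
    res_h <- list(values = ma$values[, keep, drop = FALSE],
                  features = ma$features)
    association_scan(res_h, geno_h, scan_config(cis_p = 1 - 1e-9,
                                                trans_p = 1e-300))
  }
  s1 <- scan_half(h1)
  s2 <- scan_half(h2)
  key1 <- paste(s1$hits$variant, s1$hits$feature)
  key2 <- paste(s2$hits$variant, s2$hits$feature)
  strong <- s1$hits$p < 1e-4 & s1$hits$class == "cis"
  common <- intersect(key1[strong], key2)
  j1 <- match(common, key1)
  j2 <- match(common, key2)
  pi1 <- if (length(j2)) estimate_pi1(s2$hits$p[j2]) else NA
  rb <- if (length(j2) >= 10)
    tryCatch(estimate_rb(s1$hits$beta[j1], s1$hits$se[j1],
                         s2$hits$beta[j2], s2$hits$se[j2]),
             error = function(e) NA_real_) else NA
  list(n_lookup = length(common), pi1 = pi1, r_b = rb)
}

#' @keywords internal
#' @noRd
enrich_stage <- function(co, sc, fdr_cis, cfg) {
  anns <- cfg$annotations
  if (is.null(anns)) {
    half <- floor(cfg$sim$chrom_length / 2)
    anns <- list(
      annotation_set("left_arm", data.frame(
        chrom = seq_len(cfg$sim$n_chromosomes), start = 0, end = half)),
      annotation_set("right_arm", data.frame(
        chrom = seq_len(cfg$sim$n_chromosomes), start = half,
        end = cfg$sim$chrom_length)))
  }
  feats <- co$meth$features
  thr <- fdr_cis$threshold
  cis_cpgs <- unique(sc$hits$feature[sc$hits$class == "cis" & !is.na(thr) &
                                       sc$hits$p <= thr])
  memb <- map_to_annotations(feats$chrom, feats$pos, anns)
  out <- NULL
  for (a in colnames(memb)) {
    fin <- sum(feats$id %in% cis_cpgs & memb[, a])
    fr <- fisher_enrichment(fin, max(length(cis_cpgs), 1),
                            sum(memb[, a]), nrow(feats))
    out <- rbind(out, data.frame(annotation = a, feature_in = fin,
                                 feature_total = length(cis_cpgs),
                                 universe_in = sum(memb[, a]),
                                 universe_total = nrow(feats),
                                 or = fr$or, p = fr$p,
                                 stringsAsFactors = FALSE))
  }
  out$q <- p.adjust(out$p, "BH")
  out
}
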