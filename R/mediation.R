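#' Build SNP-CpG-gene triplets from colocalization results
#'
#' Emits one triplet per gene-CpG pair whose posterior probability of a
#' shared causal variant exceeds the threshold, using the lead eQTL variant
#' of the shared signal.
#'
#' @param coloc_results data.frame with columns gene, cpg, pp4 and
#'   lead_variant.
#' @param pp4_threshold Posterior threshold (default 0.8).
#' @return data.frame: variant, cpg, gene (possibly empty).
#' @export
build_triplets <- function(coloc_results, pp4_threshold = 0.8) {
  keep <- coloc_results$pp4 > pp4_threshold
  data.frame(variant = coloc_results$lead_variant[keep],
             cpg = coloc_results$cpg[keep],
             gene = coloc_results$gene[keep],
             stringsAsFactors = FALSE)
}

#' Mediation test for one SNP-mediator-outcome triplet
#'
#' Fits (i) outcome ~ SNP giving the unadjusted SNP effect; (ii)
#' outcome ~ SNP + mediator giving the adjusted SNP effect and the mediator
#' path b; (iii) mediator ~ SNP giving path a. The proportion of effect
#' mediated is (beta_unadjusted - beta_adjusted) / beta_unadjusted and the
#' Sobel test is z = a b / sqrt(a^2 se_b^2 + b^2 se_a^2),
#' p = 2 (1 - Phi(|z|)).
#'
#' @param g Variant dosages.
#' @param m Mediator vector (e.g. adjusted methylation for the SME model).
#' @param y Outcome vector (e.g. adjusted expression for SME).
#' @param covariates Optional design matrix added to every fit.
#' @return List of class \code{mediation_result}: beta_unadjusted,
#'   beta_adjusted, proportion_mediated, a, se_a, b, se_b, sobel_z, sobel_p,
#'   n.
#' @export
mediation_test <- function(g, m, y, covariates = NULL) {
  ok <- stats::complete.cases(g, m, y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  if (sum(ok) < 30) stopf("need >= 30 complete-case samples")
  g <- g[ok]; m <- m[ok]; y <- y[ok]
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE]
  des <- function(...) cbind(1, ..., C)
  f1 <- joint_stats(y, des(g))
  f2 <- joint_stats(y, des(g, m))
  f3 <- joint_stats(m, des(g))
  b_un <- unname(f1$beta[2])
  b_adj <- unname(f2$beta[2])
  if (abs(b_un) < .Machine$double.eps^0.5 * sd(y))
    stopf("unadjusted SNP effect is zero; proportion mediated undefined")
  a <- unname(f3$beta[2]); se_a <- unname(f3$se[2])
  b <- unname(f2$beta[3]); se_b <- unname(f2$se[3])
  z <- a * b / sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  structure(list(beta_unadjusted = b_un, beta_adjusted = b_adj,
                 proportion_mediated = (b_un - b_adj) / b_un,
                 a = a, se_a = se_a, b = b, se_b = se_b,
                 sobel_z = z, sobel_p = 2 * pnorm(-abs(z)), n = sum(ok)),
            class = "mediation_result")
}

#' Test a triplet under both mediation models
#'
#' Runs \code{\link{mediation_test}} once with methylation as mediator and
#' expression as outcome (SME) and once with the roles swapped (SEM).
#'
#' @param g Variant dosages.
#' @param meth,expr Adjusted methylation and expression vectors.
#' @param covariates Optional design matrix.
#' @return List with elements \code{SME} and \code{SEM}.
#' @export
mediation_test_both <- function(g, meth, expr, covariates = NULL) {
  list(SME = mediation_test(g, m = meth, y = expr, covariates = covariates),
       SEM = mediation_test(g, m = expr, y = meth, covariates = covariates))
}

#' Resolve the mediation model for a triplet
#'
#' With q values assigned per model family (Benjamini-Hochberg across
#' triplets): if only one model passes q <= level that model is chosen; if
#' both pass, the model with the larger proportion mediated (when the
#' correct model is specified, the proportion mediated is the higher one);
#' otherwise none.
#'
#' @param sme,sem \code{mediation_result}s (or lists) carrying \code{q} and
#'   \code{proportion_mediated}.
#' @param q_level FDR level (default 0.05).
#' @return "SME", "SEM" or "none".
#' @export
resolve_model <- function(sme, sem, q_level = 0.05) {
  pass_sme <- sme$q <= q_level
  pass_sem <- sem$q <= q_level
  if (pass_sme && pass_sem) {
    if (sme$proportion_mediated >= sem$proportion_mediated) "SME" else "SEM"
  } else if (pass_sme) "SME" else if (pass_sem) "SEM" else "none"
}

#' Cluster co-methylated CpGs
#'
#' Single-linkage clusters of CpGs whose pairwise absolute correlation is at
#' least \code{r_threshold}; used to collapse mediation triplets to one
#' representative per (cluster, gene, variant), keeping the smallest Sobel p.
#'
#' @param cpg_matrix CpGs x samples value matrix (>= 2 CpGs).
#' @param r_threshold Absolute-correlation threshold (default 0.9).
#' @return Integer cluster membership named by CpG.
#' @export
cluster_comethylated <- function(cpg_matrix, r_threshold = 0.9) {
  if (nrow(cpg_matrix) < 2) stopf("need >= 2 CpGs")
  r <- abs(cor(t(cpg_matrix)))
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "single")
  cl <- cutree(hc, h = 1 - r_threshold)
  names(cl) <- rownames(cpg_matrix)
  cl
}

#' Collapse mediation triplets by co-methylation cluster
#'
#' @param triplets data.frame with cpg, gene, variant and sobel_p columns.
#' @param clusters Named cluster membership from
#'   \code{\link{cluster_comethylated}}.
#' @return The triplets data.frame reduced to one row (smallest Sobel p) per
#'   (cluster, gene, variant), with a \code{cluster} column added.
#' @export
collapse_triplets <- function(triplets, clusters) {
  triplets$cluster <- clusters[triplets$cpg]
  key <- paste(triplets$cluster, triplets$gene, triplets$variant)
  keep <- unlist(lapply(split(seq_len(nrow(triplets)), key), function(i)
    i[which.min(triplets$sobel_p[i])]), use.names = FALSE)
  triplets[sort(keep), , drop = FALSE]
}
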