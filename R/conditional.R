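#' Stepwise selection of independent QTL signals
#'
#' Exact individual-level stepwise regression: the forward step adds the
#' candidate with the smallest conditional p value if it is below
#' \code{p_enter} and its r-squared with every already-selected variant is at
#' most \code{r2_cap}; the backward step removes any selected variant whose
#' joint p value rises above \code{p_enter}; the two alternate to a fixpoint.
#' Ties break deterministically by (p, then genomic position). Candidates
#' too collinear with the selected set are recorded separately.
#'
#' @param y Adjusted phenotype vector for one feature.
#' @param candidates A \code{genotype_matrix} restricted to this feature's
#'   retained candidate variants (or a dosage matrix plus \code{variants}).
#' @param p_enter Selection threshold (e.g. the genome-wide FDR threshold).
#' @param r2_cap Pairwise collinearity cap (default 0.9).
#' @return List of class \code{signal_set}: \code{variants} (selected IDs in
#'   selection order), \code{joint} (data.frame variant, beta, se, t, p,
#'   order), \code{dropped_collinear}, \code{warning_overfit}.
#' @export
stepwise_select <- function(y, candidates, p_enter, r2_cap = 0.9) {
  G <- if (is.list(candidates)) candidates$dosage else candidates
  vinfo <- if (is.list(candidates) && !is.null(candidates$variants))
    candidates$variants else
      data.frame(id = rownames(G) %||% paste0("v", seq_len(nrow(G))),
                 chrom = 1L, pos = seq_len(nrow(G)))
  n <- length(y)
  m <- nrow(G)
  selected <- integer(0)
  dropped <- character(0)
  overfit <- FALSE
  Gt <- t(G)  # samples x variants
  cors2 <- function(a, b) suppressWarnings(cor(a, b))^2

  repeat {
    changed <- FALSE
    ## forward step
    avail <- setdiff(seq_len(m), selected)
    if (length(avail) && length(selected) < n - 2) {
      ## collinearity screen against the selected set
      if (length(selected)) {
        r2max <- vapply(avail, function(j)
          max(cors2(Gt[, j], Gt[, selected, drop = FALSE]), na.rm = TRUE),
          numeric(1))
        r2max[is.na(r2max)] <- 1
        collinear <- avail[r2max > r2_cap]
        dropped <- union(dropped, vinfo$id[collinear])
        avail <- avail[r2max <= r2_cap]
      }
      if (length(avail)) {
        ps <- vapply(avail, function(j) {
          X <- cbind(1, Gt[, c(selected, j), drop = FALSE])
          conditional_p(y, X, ncol(X))
        }, numeric(1))
        ord <- order(ps, vinfo$pos[avail])
        bestj <- avail[ord[1]]
        if (is.finite(ps[ord[1]]) && ps[ord[1]] < p_enter) {
          selected <- c(selected, bestj)
          changed <- TRUE
          if (length(selected) >= n) { overfit <- TRUE; break }
        }
      }
    }
    ## backward step
    if (length(selected) > 1) {
      repeat {
        X <- cbind(1, Gt[, selected, drop = FALSE])
        ps <- vapply(seq_along(selected) + 1L, function(k)
          conditional_p(y, X, k), numeric(1))
        worst <- which.max(ps)
        if (ps[worst] > p_enter) {
          selected <- selected[-worst]
          changed <- TRUE
          if (length(selected) <= 1) break
        } else break
      }
    }
    if (!changed) break
  }

  joint <- NULL
  if (length(selected)) {
    X <- cbind(1, Gt[, selected, drop = FALSE])
    fit <- lm.fit(X, y)
    s <- joint_stats(y, X)
    joint <- data.frame(variant = vinfo$id[selected],
                        beta = s$beta[-1], se = s$se[-1], t = s$t[-1],
                        p = s$p[-1], order = seq_along(selected),
                        stringsAsFactors = FALSE)
  }
  structure(list(variants = vinfo$id[selected], joint = joint,
                 dropped_collinear = dropped, warning_overfit = overfit,
                 index = selected), class = "signal_set")
}

## p value of the k-th coefficient in the OLS fit y ~ X (X includes intercept)
#' @keywords internal
#' @noRd
conditional_p <- function(y, X, k) {
  s <- joint_stats(y, X)
  s$p[k]
}

#' @keywords internal
#' @noRd
joint_stats <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(list(beta = rep(NA, ncol(X)),
                                      se = rep(NA, ncol(X)),
                                      t = rep(NA, ncol(X)),
                                      p = rep(Inf, ncol(X))))
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * s2)
  tt <- beta / se
  list(beta = beta, se = se, t = tt, p = 2 * pt(-abs(tt), df))
}

#' Joint cis + trans conditional analysis for one feature
#'
#' Reruns stepwise selection over the union of the feature's selected cis
#' variants and its trans candidates. Trans signals that are not retained
#' conditional on the cis signals (their conditional p exceeds
#' \code{p_enter}) are flagged cis-confounded and removed; this is the
#' second-pass test for trans associations driven by long-range LD with a
#' cis effect.
#'
#' @param y Adjusted phenotype vector.
#' @param trans_candidates,cis_selected \code{genotype_matrix}-like objects
#'   (dosage + variants) for the feature's trans candidates and selected cis
#'   signals (\code{cis_selected} may have zero rows).
#' @param p_enter Selection threshold for trans signals.
#' @param r2_cap Collinearity cap.
#' @return A \code{signal_set} over the union; extra elements
#'   \code{trans_retained} and \code{cis_confounded} list trans variant IDs.
#' @export
joint_cis_trans_conditional <- function(y, trans_candidates, cis_selected,
                                        p_enter, r2_cap = 0.9) {
  Gt <- if (is.list(trans_candidates)) trans_candidates$dosage else trans_candidates
  vt <- if (is.list(trans_candidates) && !is.null(trans_candidates$variants))
    trans_candidates$variants else
      data.frame(id = rownames(Gt), chrom = 1L, pos = seq_len(nrow(Gt)))
  if (!nrow(Gt)) stopf("feature has no trans candidates")
  has_cis <- !is.null(cis_selected) &&
    nrow(if (is.list(cis_selected)) cis_selected$dosage else cis_selected) > 0
  if (!has_cis) {
    sel <- stepwise_select(y, trans_candidates, p_enter, r2_cap)
    sel$trans_retained <- sel$variants
    sel$cis_confounded <- setdiff(vt$id, sel$variants)
    return(sel)
  }
  Gc <- if (is.list(cis_selected)) cis_selected$dosage else cis_selected
  vc <- if (is.list(cis_selected) && !is.null(cis_selected$variants))
    cis_selected$variants else
      data.frame(id = rownames(Gc), chrom = 0L, pos = seq_len(nrow(Gc)))
  union_geno <- list(dosage = rbind(Gc, Gt),
                     variants = rbind(vc[, c("id", "chrom", "pos")],
                                      vt[, c("id", "chrom", "pos")]))
  sel <- stepwise_select(y, union_geno, p_enter, r2_cap)
  sel$trans_retained <- intersect(sel$variants, vt$id)
  sel$cis_confounded <- setdiff(vt$id, sel$variants)
  sel
}
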