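#' Read a BED file as an annotation set
#'
#' BED intervals are 0-based half-open; overlapping intervals are allowed.
#'
#' @param path BED file path (first three columns used).
#' @param name Annotation name (default: file name).
#' @return List of class \code{annotation_set}: \code{name},
#'   \code{intervals} (chrom, start, end).
#' @export
read_bed <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  annotation_set(name, df)
}

#' @rdname read_bed
#' @param intervals data.frame(chrom, start, end), 0-based half-open.
#' @export
annotation_set <- function(name, intervals) {
  if (any(intervals$start >= intervals$end))
    stopf("annotation intervals must have start < end")
  structure(list(name = name, intervals = intervals),
            class = "annotation_set")
}

#' Map 1-based point positions to annotation membership
#'
#' A 1-based point p maps to the 0-based coordinate p - 1 and is inside
#' [start, end) iff start < p <= end. Strand is ignored; membership is set
#' membership (a point overlapping two intervals of the same annotation
#' counts once).
#'
#' @param chrom,pos Point coordinates (1-based), vectorized.
#' @param annotations A single \code{annotation_set} or a list of them.
#' @return Logical matrix: positions x annotations.
#' @export
map_to_annotations <- function(chrom, pos, annotations) {
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  out <- vapply(annotations, function(ann) {
    iv <- ann$intervals
    inside <- rep(FALSE, length(pos))
    for (cc in unique(iv$chrom)) {
      sel <- iv$chrom == cc
      qp <- which(chrom == cc)
      if (!length(qp)) next
      ## merge to disjoint intervals, then binary search
      o <- order(iv$start[sel])
      s <- iv$start[sel][o]; e <- iv$end[sel][o]
      ms <- s[1]; me <- e[1]; S <- c(); E <- c()
      if (length(s) > 1) for (k in 2:length(s)) {
        if (s[k] <= me) me <- max(me, e[k]) else { S <- c(S, ms); E <- c(E, me); ms <- s[k]; me <- e[k] }
      }
      S <- c(S, ms); E <- c(E, me)
      p0 <- pos[qp] - 1  # 0-based point
      j <- findInterval(p0, S)
      inside[qp] <- j >= 1 & p0 < E[pmax(j, 1)]
    }
    inside
  }, logical(length(pos)))
  out <- matrix(out, nrow = length(pos))
  colnames(out) <- vapply(annotations, `[[`, "", "name")
  out
}

#' Fisher exact enrichment of a feature set in an annotation
#'
#' Builds the 2x2 table \{features in/out of annotation\} x \{non-feature
#' universe in/out\}, computes the two-sided exact p value, and reports the
#' sample cross-product odds ratio with a Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param feature_in,feature_total Features inside the annotation / total.
#' @param universe_in,universe_total Universe counts (the universe includes
#'   the feature set).
#' @return List of class \code{enrichment_result}: \code{table}, \code{or},
#'   \code{p}.
#' @export
fisher_enrichment <- function(feature_in, feature_total, universe_in,
                              universe_total) {
  if (feature_total <= 0) stopf("feature_total must be > 0")
  if (universe_total <= feature_total)
    stopf("universe must be larger than the feature set")
  a <- feature_in
  b <- feature_total - feature_in
  cc <- universe_in - feature_in
  d <- (universe_total - feature_total) - cc
  if (min(a, b, cc, d) < 0) stopf("inconsistent counts")
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("feature", "background"),
                                c("in", "out")))
  p <- fisher.test(tab)$p.value
  h <- if (min(a, b, cc, d) == 0) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  structure(list(table = tab, or = or, p = p), class = "enrichment_result")
}

#' Catalog (trait) enrichment of feature sets
#'
#' One Fisher exact test per catalog trait with at least \code{min_signals}
#' signals present in the universe, Benjamini-Hochberg correction across
#' traits, and the call rule: "enriched" iff OR > 1, q < 0.05 and at least
#' \code{min_signals} signals in the tested feature set; "depleted" iff
#' OR < 1 and q < 0.05; otherwise "ns".
#'
#' @param feature_set Character vector of feature IDs (e.g. cis-CpGs).
#' @param catalog Named list: trait -> character vector of signal IDs.
#' @param universe Character vector of all tested feature IDs. For
#'   GWAS-style enrichment pass the background the design requires (e.g.
#'   meQTL variants plus variants not associated with methylation).
#' @param min_signals Minimum signals in the tested set (default 5).
#' @param q_level FDR level for calls (default 0.05).
#' @return data.frame: trait, counts, or, p, q, n_signals_in_set, call.
#' @export
catalog_enrichment <- function(feature_set, catalog, universe,
                               min_signals = 5, q_level = 0.05) {
  if (!length(catalog)) stopf("empty catalog")
  feature_set <- intersect(feature_set, universe)
  rows <- lapply(names(catalog), function(tr) {
    sig <- intersect(catalog[[tr]], universe)
    if (length(sig) < min_signals) return(NULL)
    a <- length(intersect(feature_set, sig))
    fr <- fisher_enrichment(a, length(feature_set), length(sig),
                            length(universe))
    data.frame(trait = tr, in_set = a, set_size = length(feature_set),
               n_signals = length(sig), universe = length(universe),
               or = fr$or, p = fr$p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) stopf("no catalog trait has enough signals in the universe")
  rows$q <- p.adjust(rows$p, "BH")
  rows$call <- ifelse(rows$or > 1 & rows$q < q_level & rows$in_set >= min_signals,
                      "enriched",
                      ifelse(rows$or < 1 & rows$q < q_level, "depleted", "ns"))
  rows
}
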