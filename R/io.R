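## Standard-format export/import for simulated cohorts. Phenotype values are
## written with full double precision (%.17g) so write -> read round-trips
## bit-exactly.

#' Write genotypes to a minimal VCF (GT field, one sample per individual)
#'
#' @param geno A \code{genotype_matrix}.
#' @param path Output file path (uncompressed VCF).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples), collapse = "\t")), con)
  v <- geno$variants
  ## dosage counts the coded (minor) allele; GT is written on REF/ALT
  alt_dos <- geno$dosage
  flip <- v$coded == v$ref
  if (any(flip)) alt_dos[flip, ] <- 2L - alt_dos[flip, ]
  gt <- matrix(c("0/0", "0/1", "1/1")[alt_dos + 1L], nrow(alt_dos))
  lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from a VCF written by \code{\link{write_vcf}}
#'
#' Parses GT fields and re-orients dosages to the minor allele.
#'
#' @param path VCF file path.
#' @return A \code{genotype_matrix}.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- strsplit(lines[(hdr + 1):length(lines)], "\t")
  v <- data.frame(
    chrom = as.integer(vapply(body, `[`, "", 1)),
    pos = as.integer(vapply(body, `[`, "", 2)),
    id = vapply(body, `[`, "", 3),
    ref = vapply(body, `[`, "", 4),
    alt = vapply(body, `[`, "", 5),
    stringsAsFactors = FALSE
  )
  gt <- t(vapply(body, function(x) x[-(1:9)], character(length(samples))))
  if (length(samples) == 1L) gt <- matrix(gt, ncol = 1L)
  dosage <- matrix(0L, nrow(v), length(samples))
  dosage[gt == "0/1" | gt == "1/0"] <- 1L
  dosage[gt == "1/1"] <- 2L
  f_alt <- rowMeans(dosage) / 2
  flip <- f_alt > 0.5
  if (any(flip)) dosage[flip, ] <- 2L - dosage[flip, ]
  v$coded <- ifelse(flip, v$ref, v$alt)
  v$maf <- rowMeans(dosage) / 2
  v <- v[, c("id", "chrom", "pos", "ref", "alt", "coded", "maf")]
  rownames(dosage) <- v$id
  colnames(dosage) <- samples
  structure(list(dosage = dosage, variants = v, samples = samples),
            class = "genotype_matrix")
}

#' Write a dosage matrix as TSV
#'
#' Columns: id, chrom, pos, ref, alt, coded, maf, then one column per sample.
#' @param geno A \code{genotype_matrix}.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- cbind(geno$variants, as.data.frame(geno$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- df[, 1:7]
  dosage <- as.matrix(df[, -(1:7), drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- meta$id
  structure(list(dosage = dosage, variants = meta,
                 samples = colnames(dosage)), class = "genotype_matrix")
}

#' Write a twin pedigree as a FAM-like TSV with a zygosity column
#'
#' @param ped A \code{twin_pedigree}.
#' @param path Output path.
#' @export
write_pedigree_tsv <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE)
  ped$pair_id <- as.character(ped$pair_id)
  class(ped) <- c("twin_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Write a phenotype matrix (features x samples) as TSV
#'
#' Rows carry feature id, chrom and pos followed by per-sample values at full
#' double precision.
#' @param pheno A \code{phenotype_matrix}.
#' @param path Output path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  vals <- apply(pheno$values, 2, function(x) sprintf("%.17g", x))
  df <- cbind(pheno$features, as.data.frame(vals, stringsAsFactors = FALSE))
  colnames(df) <- c(colnames(pheno$features), pheno$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  meta <- df[, 1:3]
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(vals) <- meta$id
  structure(list(values = vals, latent = NULL, features = meta,
                 samples = colnames(vals)), class = "phenotype_matrix")
}
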