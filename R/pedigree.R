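#' Simulate a twin-cohort pedigree
#'
#' Builds a pedigree of monozygotic (MZ) pairs, dizygotic (DZ) pairs and
#' unpaired singletons. MZ co-twins share all segregating variation, DZ
#' co-twins share half on average; the pedigree drives genotype sharing,
#' the kinship matrix and the twin-aware permutation scheme downstream.
#'
#' @param n_mz Number of MZ twin pairs.
#' @param n_dz Number of DZ twin pairs.
#' @param n_single Number of singletons.
#' @return A data.frame of class \code{twin_pedigree} with columns
#'   \code{id}, \code{pair_id} (\code{NA} for singletons) and
#'   \code{zygosity} (\code{"MZ"}, \code{"DZ"} or \code{"singleton"}).
#' @examples
#' ped <- simulate_pedigree(2, 3, 1)
#' table(ped$zygosity)
#' @export
simulate_pedigree <- function(n_mz, n_dz, n_single) {
  if (any(c(n_mz, n_dz, n_single) < 0)) stopf("counts must be >= 0")
  n <- 2L * n_mz + 2L * n_dz + n_single
  if (n < 1L) stopf("empty cohort: all counts are zero")
  pair_id <- character(0)
  zyg <- character(0)
  if (n_mz > 0) {
    pair_id <- c(pair_id, rep(sprintf("MZ%03d", seq_len(n_mz)), each = 2L))
    zyg <- c(zyg, rep("MZ", 2L * n_mz))
  }
  if (n_dz > 0) {
    pair_id <- c(pair_id, rep(sprintf("DZ%03d", seq_len(n_dz)), each = 2L))
    zyg <- c(zyg, rep("DZ", 2L * n_dz))
  }
  if (n_single > 0) {
    pair_id <- c(pair_id, rep(NA_character_, n_single))
    zyg <- c(zyg, rep("singleton", n_single))
  }
  ped <- data.frame(
    id = sprintf("IND%04d", seq_len(n)),
    pair_id = pair_id,
    zygosity = zyg,
    stringsAsFactors = FALSE
  )
  class(ped) <- c("twin_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @keywords internal
#' @noRd
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stopf("duplicate individual IDs in pedigree")
  paired <- ped[!is.na(ped$pair_id), , drop = FALSE]
  if (nrow(paired)) {
    tab <- table(paired$pair_id)
    if (any(tab != 2L)) stopf("each pair ID must occur exactly twice")
    zz <- tapply(paired$zygosity, paired$pair_id, function(z) length(unique(z)))
    if (any(zz != 1L)) stopf("zygosity must be constant within a pair")
  }
  invisible(ped)
}

## Index of pair members: list of integer pairs plus singleton indices.
#' @keywords internal
#' @noRd
pair_index <- function(ped) {
  paired <- which(!is.na(ped$pair_id))
  pairs <- split(paired, ped$pair_id[paired])
  zyg <- vapply(pairs, function(i) ped$zygosity[i[1]], character(1))
  list(
    pairs = pairs,
    zygosity = zyg,
    singletons = which(is.na(ped$pair_id))
  )
}

#' Expected-relatedness (kinship) matrix from a twin pedigree
#'
#' Block-diagonal matrix of expected additive-genetic relatedness: 1 on the
#' diagonal and between MZ co-twins, 0.5 between DZ co-twins, 0 otherwise.
#' Used as the random-effect covariance when residualizing phenotypes.
#'
#' @param ped A \code{twin_pedigree}.
#' @return A symmetric numeric matrix with sample IDs as dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  K <- diag(1, n)
  dimnames(K) <- list(ped$id, ped$id)
  idx <- pair_index(ped)
  for (j in seq_along(idx$pairs)) {
    i <- idx$pairs[[j]]
    r <- if (idx$zygosity[j] == "MZ") 1 else 0.5
    K[i[1], i[2]] <- K[i[2], i[1]] <- r
  }
  K
}
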