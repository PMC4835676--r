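# Single-trait stepwise pairwise-eQTL mappers used as comparison baselines.
# No significance cutoff is applied here: evaluation sweeps cutoffs over the
# reported pair P-values when building ROC curves.

#' Residual-based stepwise regression (RBSR)
#'
#' Per trait: the primary eQTL is the best variant of a plain one-locus scan;
#' the secondary eQTL is the best variant of a scan on the residuals after
#' removing the primary's fitted effect (the primary variant itself is
#' excluded from the second scan). The pair P-value is the maximum of the two
#' association P-values.
#'
#' @inheritParams scan_associations
#' @return Tibble with one row per trait: `trait_id`, `primary_variant`,
#'   `secondary_variant`, `primary_p`, `secondary_p`, `pair_p`.
#' @export
map_rbsr <- function(traits, genotypes) {
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  check_aligned(traits, genotypes)
  scan1 <- scan_associations(traits, genotypes)
  A1 <- scan1$scores
  prim <- max.col(A1, ties.method = "first")
  map <- tibble::tibble(trait_id = rownames(A1),
                        variant_id = colnames(A1)[prim])
  scan2 <- scan_associations(traits, genotypes, condition_on = map)
  A2 <- scan2$scores
  A2[cbind(seq_len(nrow(A2)), prim)] <- -Inf   # exclude the primary variant
  sec <- max.col(A2, ties.method = "first")
  tibble::tibble(
    trait_id = rownames(A1),
    primary_variant = colnames(A1)[prim],
    secondary_variant = colnames(A1)[sec],
    primary_p = 10^(-A1[cbind(seq_len(nrow(A1)), prim)]),
    secondary_p = 10^(-A2[cbind(seq_len(nrow(A2)), sec)]),
  ) |>
    dplyr::mutate(pair_p = pmax(.data$primary_p, .data$secondary_p))
}

#' Partition-based stepwise regression (PBSR)
#'
#' Per trait: the primary eQTL is the best variant of a plain scan; the
#' individuals are then partitioned by the primary's allele and a separate
#' one-locus scan is run within each partition (of at least `min_partition`
#' individuals), yielding two allele-specific secondary candidates. The more
#' significant of the two is reported. Tailored to allele-specific (epistatic)
#' secondary effects.
#'
#' @inheritParams scan_associations
#' @param min_partition Minimum partition size for a within-partition scan.
#' @return Tibble as in [map_rbsr()], with `secondary_allele` indicating the
#'   primary-allele partition (-1 or +1) in which the secondary was found
#'   (NA when neither partition yielded one).
#' @export
map_pbsr <- function(traits, genotypes, min_partition = 4) {
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  check_aligned(traits, genotypes)
  Y <- traits$values; G <- genotypes$values
  scan1 <- scan_associations(traits, genotypes)
  A1 <- scan1$scores
  prim <- max.col(A1, ties.method = "first")
  l <- ncol(Y)
  out <- vector("list", l)
  for (j in seq_len(l)) {
    gp <- G[, prim[j]]
    best_p <- 1; best_v <- NA_integer_; best_allele <- NA_real_
    for (allele in c(-1, 1)) {
      idx <- which(gp == allele)
      if (length(idx) < min_partition) next
      P <- scan_p_matrix(Y[idx, j, drop = FALSE], G[idx, , drop = FALSE])
      P[prim[j]] <- 1                      # monomorphic there anyway
      v <- which.min(P)
      if (P[v] < best_p) { best_p <- P[v]; best_v <- v; best_allele <- allele }
    }
    out[[j]] <- tibble::tibble(
      trait_id = colnames(Y)[j],
      primary_variant = colnames(G)[prim[j]],
      secondary_variant = if (is.na(best_v)) NA_character_ else colnames(G)[best_v],
      primary_p = 10^(-A1[j, prim[j]]),
      secondary_p = if (is.na(best_v)) NA_real_ else best_p,
      secondary_allele = best_allele)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(pair_p = pmax(.data$primary_p, .data$secondary_p))
}
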