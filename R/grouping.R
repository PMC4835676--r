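# Agglomerative construction of co-association groups.
#
# A co-association group is a set of traits jointly associated with one
# representative variant. Groups start as singletons (each trait with its
# best-scoring variant) and are merged greedily: at each step the admissible
# pair of groups whose merged group attains the best achievable group score
# is merged, provided that (i) the score clears the significance cutoff,
# (ii) every member of the merged group is itself associated with the new
# representative above the cutoff, and (iii) the merged score is not below
# the weaker parent's score (merging must not degrade the groups it joins).
# The group score is the median of the member traits' association scores to
# the representative; the per-member gate is what keeps unrelated traits from
# riding along on a strong group's median.
#
# "Nearby" representatives: when variant coordinates are available, two
# groups may merge only if their representatives lie on the same chromosome
# within `window_bp` (recombinant-inbred linkage blocks are megabase-scale).
# A merge extends the more coherent parent: the
# candidate representatives are drawn from the higher-scoring group's side
# (its representative, or the window around it when coordinates exist), so a
# weak group can be absorbed into a strong group's locus but can never drag
# the merged group onto its own representative. Without coordinates (the
# synthetic benchmark: unlinked variants sampled independently) proximity is
# vacuous: any two groups may attempt a merge and the candidate set is the
# stronger parent's representative alone. This rescues traits whose own
# best-scoring variant was a noise variant while keeping null traits out of
# groups whose representative they are not associated with.

#' Initialize co-association groups from an association scan
#'
#' One singleton group per trait whose best association score exceeds the
#' cutoff; the representative is that trait's best-scoring variant.
#'
#' @param scan A `poem_scan` from [scan_associations()].
#' @param score_cutoff Minimum -log10 P; default 2 (P = 0.01).
#' @return A `poem_grouping` object.
#' @export
initialize_groups <- function(scan, score_cutoff = 2) {
  stopifnot(inherits(scan, "poem_scan"), score_cutoff >= 0)
  A <- scan$scores
  best <- max.col(A, ties.method = "first")
  sc <- A[cbind(seq_len(nrow(A)), best)]
  keep <- which(sc > score_cutoff)
  new_grouping(
    members = as.list(keep),
    reps = best[keep],
    scores = sc[keep],
    scan = scan)
}

#' Best representative variant for a set of traits
#'
#' Among the candidate variants, returns the one maximizing the median of the
#' member traits' association scores (ties broken toward the lowest variant
#' index), together with that median (the group score).
#'
#' @param trait_ids Character vector of member trait ids.
#' @param scan A `poem_scan`.
#' @param candidate_variants Character vector of candidate variant ids.
#' @return A list with `variant_id` and `group_score`.
#' @export
update_representative <- function(trait_ids, scan, candidate_variants) {
  stopifnot(inherits(scan, "poem_scan"))
  if (length(candidate_variants) == 0) {
    stop("candidate set must be non-empty", call. = FALSE)
  }
  rows <- match(trait_ids, rownames(scan$scores))
  cols <- match(candidate_variants, colnames(scan$scores))
  if (anyNA(rows) || anyNA(cols)) stop("unknown trait or variant id", call. = FALSE)
  cols <- sort(cols)                 # ties break toward the lowest index
  meds <- col_medians(scan$scores, rows, cols)
  k <- which.max(meds)
  list(variant_id = colnames(scan$scores)[cols[k]],
       group_score = unname(meds[k]))
}

# median of A[rows, col] for each col in cols; rows/cols are integer indices
col_medians <- function(A, rows, cols) {
  if (length(rows) == 1L) return(A[rows, cols])
  sub <- A[rows, cols, drop = FALSE]
  apply(sub, 2, stats::median)
}

#' Agglomerate co-association groups
#'
#' Greedy best-first merging of the groups in `grouping` (see the comment at
#' the top of this file for the merge rule). Deterministic given its inputs:
#' ties in the merge order and in representative choice are broken toward the
#' lowest variant index.
#'
#' @param grouping A `poem_grouping` from [initialize_groups()] or a previous
#'   agglomeration.
#' @param scan The `poem_scan` the grouping was built from.
#' @param genotypes A [genotype_matrix()]; its coordinates (when present)
#'   define which representatives are "nearby".
#' @param window_bp Linkage window for merging and candidate representatives;
#'   ignored when the genotypes carry no coordinates.
#' @param score_cutoff Significance gate for merged groups and the final
#'   filtration; default 2 (P = 0.01).
#' @return A `poem_grouping`.
#' @export
agglomerate_groups <- function(grouping, scan, genotypes,
                               window_bp = 2e6, score_cutoff = 2) {
  stopifnot(inherits(grouping, "poem_grouping"), inherits(scan, "poem_scan"))
  genotypes <- as_genotype_matrix(genotypes)
  A <- scan$scores
  m <- ncol(A)
  members <- grouping$.members
  reps <- grouping$.reps
  scores <- grouping$.scores
  ng <- length(members)
  if (ng <= 1) return(filter_groups(members, reps, scores, scan, score_cutoff))

  chrom <- genotypes$variants$chrom
  pos <- genotypes$variants$pos_bp
  has_coords <- !all(is.na(chrom))

  # per-group column minima over member rows: the per-member gate
  gmin <- lapply(members, function(mm) {
    if (length(mm) == 1L) A[mm, ] else do.call(pmin, asplit(A[mm, , drop = FALSE], 1))
  })

  admissible <- function(a, b) {
    if (!has_coords) return(TRUE)
    va <- reps[a]; vb <- reps[b]
    identical(chrom[va], chrom[vb]) && !is.na(chrom[va]) &&
      abs(pos[va] - pos[vb]) <= window_bp
  }
  candidates <- function(a, b) {
    # a merge extends the more coherent parent: candidate representatives
    # come from the higher-scoring group's side (both on a tie), so a strong
    # group can absorb traits associated with its locus but cannot be taken
    # over by a weak group's representative
    anchor <- if (scores[a] > scores[b]) reps[a]
              else if (scores[b] > scores[a]) reps[b]
              else unique(c(reps[a], reps[b]))
    if (!has_coords) return(anchor)
    keep <- rep(FALSE, m)
    for (va in anchor) {
      keep <- keep | (!is.na(chrom) & chrom == chrom[va] &
                        abs(pos - pos[va]) <= window_bp)
    }
    which(keep)
  }
  pair_eval <- function(a, b) {
    # best achievable merged (rep, score); -Inf when no candidate passes the
    # per-member gate above the cutoff, or when even the best merged score
    # would degrade the group below the weaker parent (a merge must not make
    # the merged group worse at describing its members than its parts were)
    cand <- candidates(a, b)
    gate <- pmin(gmin[[a]][cand], gmin[[b]][cand])
    cand <- cand[gate > score_cutoff]
    if (!length(cand)) return(c(NA_real_, -Inf))
    meds <- col_medians(A, c(members[[a]], members[[b]]), cand)
    k <- which.max(meds)
    if (meds[k] < min(scores[a], scores[b])) return(c(NA_real_, -Inf))
    c(cand[k], meds[k])
  }

  S <- matrix(-Inf, ng, ng)      # merged score cache (upper triangle)
  Rp <- matrix(NA_real_, ng, ng) # merged representative cache
  alive <- rep(TRUE, ng)
  for (a in seq_len(ng - 1)) for (b in seq((a + 1), ng)) {
    if (admissible(a, b)) {
      pe <- pair_eval(a, b); Rp[a, b] <- pe[1]; S[a, b] <- pe[2]
    }
  }

  repeat {
    if (!any(is.finite(S))) break
    idx <- which(S == max(S), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    a <- idx[1, 1]; b <- idx[1, 2]
    if (S[a, b] <= score_cutoff) break
    # merge b into a
    members[[a]] <- c(members[[a]], members[[b]])
    reps[a] <- Rp[a, b]
    scores[a] <- S[a, b]
    gmin[[a]] <- pmin(gmin[[a]], gmin[[b]])
    alive[b] <- FALSE
    S[b, ] <- -Inf; S[, b] <- -Inf
    for (o in which(alive)) {
      if (o == a) next
      lo <- min(a, o); hi <- max(a, o)
      if (admissible(a, o)) {
        pe <- pair_eval(a, o); Rp[lo, hi] <- pe[1]; S[lo, hi] <- pe[2]
      } else {
        S[lo, hi] <- -Inf
      }
    }
  }

  keep <- which(alive)
  filter_groups(members[keep], reps[keep], scores[keep], scan, score_cutoff)
}

filter_groups <- function(members, reps, scores, scan, score_cutoff) {
  ok <- scores > score_cutoff
  new_grouping(members[ok], reps[ok], scores[ok], scan)
}

new_grouping <- function(members, reps, scores, scan) {
  A <- scan$scores
  ord <- order(reps, purrr::map_int(members, 1))
  members <- members[ord]; reps <- reps[ord]; scores <- scores[ord]
  groups <- tibble::tibble(
    group_id = seq_along(members),
    representative = colnames(A)[reps],
    group_score = as.numeric(scores),
    n_traits = lengths(members),
    trait_ids = purrr::map(members, ~ rownames(A)[.x]))
  structure(
    list(groups = groups, source = scan$provenance,
         .members = members, .reps = reps, .scores = as.numeric(scores)),
    class = "poem_grouping")
}

#' @export
print.poem_grouping <- function(x, ...) {
  cat(sprintf("<poem_grouping> %d groups, %d traits (%s scan)\n",
              nrow(x$groups), sum(x$groups$n_traits), x$source))
  invisible(x)
}

#' Tidy a grouping into one row per trait
#'
#' @param x A `poem_grouping`.
#' @param ... Unused.
#' @return Tibble with `trait_id`, `group_id`, `representative`, `group_score`.
#' @method tidy poem_grouping
#' @export
tidy.poem_grouping <- function(x, ...) {
  x$groups |>
    dplyr::select("group_id", "representative", "group_score", "trait_ids") |>
    tidyr::unnest_longer("trait_ids", values_to = "trait_id") |>
    dplyr::select("trait_id", "group_id", "representative", "group_score")
}

#' Build co-association groups from traits and genotypes
#'
#' Convenience wrapper: scan, initialize, agglomerate.
#'
#' @inheritParams scan_associations
#' @inheritParams agglomerate_groups
#' @param condition_on Optional eQTL map for a conditioned scan.
#' @return A `poem_grouping`.
#' @export
co_association_groups <- function(traits, genotypes, condition_on = NULL,
                                  score_cutoff = 2, window_bp = 2e6) {
  scan <- scan_associations(traits, genotypes, condition_on)
  g0 <- initialize_groups(scan, score_cutoff)
  agglomerate_groups(g0, scan, genotypes, window_bp, score_cutoff)
}

#' Group-based eQTL map
#'
#' Maps every trait in every group to the group's representative variant
#' (with per-trait refitted one-locus coefficients). Ungrouped traits are
#' absent from the map.
#'
#' @param grouping A `poem_grouping`.
#' @param traits,genotypes The underlying matrices.
#' @return Tibble map: `trait_id`, `variant_id`, `score`, `mu_hat`, `beta_hat`.
#' @export
group_eqtl_map <- function(grouping, traits, genotypes) {
  stopifnot(inherits(grouping, "poem_grouping"))
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  asn <- tidy(grouping)
  if (nrow(asn) == 0) return(empty_eqtl_map())
  G <- genotypes$values[, asn$representative, drop = FALSE]
  Ym <- traits$values[, asn$trait_id, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  sgg <- colSums(Gc^2)
  beta <- colSums(Gc * sweep(Ym, 2, colMeans(Ym))) / ifelse(sgg > 0, sgg, 1)
  mu <- colMeans(Ym) - beta * colMeans(G)
  tibble::tibble(
    trait_id = asn$trait_id,
    variant_id = asn$representative,
    score = asn$group_score,
    mu_hat = unname(mu),
    beta_hat = unname(beta))
}
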