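# Single-locus association scans, plain and residual-conditioned.
#
# The association score of trait j and variant x is -log10 of the P-value of
# the F-test for the genetic fixed effect in y_j = mu + g_x beta + e, so that
# the best eQTL of a trait is the argmax over its row of scores. P-values that
# underflow are floored at .p_floor to keep scores finite.

.p_floor <- 1e-300
.score_cap <- -log10(.p_floor)

#' Fit the one-locus fixed-effect model for a single trait/variant pair
#'
#' Ordinary least squares of `y = mu + g * beta + e` with `g` coded -1/+1,
#' tested with the standard ANOVA F-test on 1 and n-2 degrees of freedom.
#' Equivalent to a two-group one-way ANOVA on the allele classes.
#'
#' @param y Numeric vector of trait values.
#' @param g Numeric vector of -1/+1 genotypes, same length.
#' @return A list with `mu_hat`, `beta_hat`, `fstat`, `p_value`.
#'   A monomorphic `g` makes the effect unidentifiable: `beta_hat` is NA and
#'   `p_value` is 1 (callers record association score 0).
#' @examples
#' g <- rep(c(-1, 1), each = 5)
#' fit_single_locus(g * 2 + rnorm(10, sd = .1), g)
#' @export
fit_single_locus <- function(y, g) {
  stopifnot(length(y) == length(g))
  n <- length(y)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (!all(g %in% c(-1, 1))) stop("g must be coded -1/+1", call. = FALSE)
  if (length(unique(g)) < 2) {
    return(list(mu_hat = mean(y), beta_hat = NA_real_,
                fstat = NA_real_, p_value = 1, monomorphic = TRUE))
  }
  gc <- g - mean(g); yc <- y - mean(y)
  sgg <- sum(gc^2)
  beta <- sum(gc * yc) / sgg
  mu <- mean(y) - beta * mean(g)
  ssr <- beta^2 * sgg
  sse <- sum(yc^2) - ssr
  if (sum(yc^2) <= 0) { # constant trait
    return(list(mu_hat = mu, beta_hat = 0, fstat = 0, p_value = 1,
                monomorphic = FALSE))
  }
  if (sse <= .Machine$double.eps * sum(yc^2)) {
    # perfect fit: zero residual variance with non-zero signal
    return(list(mu_hat = mu, beta_hat = beta, fstat = Inf, p_value = .p_floor,
                monomorphic = FALSE))
  }
  fstat <- ssr / (sse / (n - 2))
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(mu_hat = mu, beta_hat = beta, fstat = fstat,
       p_value = max(p, .p_floor), monomorphic = FALSE)
}

# Vectorised P-value matrix (l x m) for all trait/variant pairs.
# Monomorphic variants get P = 1 (score 0); constant traits get P = 1.
scan_p_matrix <- function(Y, G) {
  n <- nrow(G)
  Gc <- sweep(G, 2, colMeans(G))
  Yc <- sweep(Y, 2, colMeans(Y))
  sgg <- colSums(Gc^2)
  syy <- colSums(Yc^2)
  mono <- sgg <= 0
  sgg[mono] <- 1 # avoid 0/0; overwritten below
  sgy <- crossprod(Yc, Gc)                      # l x m
  ssr <- sweep(sgy^2, 2, sgg, "/")
  sse <- sweep(-ssr, 1, syy, "+")
  # guard tiny negative sse from cancellation
  sse[sse < 0] <- 0
  fstat <- ssr / (sse / (n - 2))
  P <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  P[!is.finite(fstat) & ssr > 0] <- .p_floor    # perfect fits
  P[, mono] <- 1
  P[syy <= 0, ] <- 1                            # constant traits
  P[P < .p_floor] <- .p_floor
  dimnames(P) <- list(colnames(Y), colnames(G))
  P
}

#' One-locus association scan across all traits and variants
#'
#' Computes the l x m association matrix whose entries are -log10 P of the
#' per-(trait, variant) F-test. With `condition_on` set to an eQTL map, the
#' scan is run on the residuals of each mapped trait with respect to its
#' mapped variant (traits absent from the map are scanned unchanged).
#'
#' @param traits A [trait_matrix()] (or plain matrix, individuals in rows).
#' @param genotypes A [genotype_matrix()] (or plain -1/+1 matrix).
#' @param condition_on Optional eQTL map tibble from [best_eqtl_map()] or
#'   [group_eqtl_map()].
#' @return A `poem_scan` object: the score matrix plus a provenance flag
#'   (`"plain"` or `"conditioned"`). Use [tidy()] for a long tibble.
#' @export
scan_associations <- function(traits, genotypes, condition_on = NULL) {
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  check_aligned(traits, genotypes)
  Y <- traits$values
  provenance <- "plain"
  if (!is.null(condition_on) && nrow(condition_on) > 0) {
    Y <- residual_values(traits, genotypes, condition_on)
    provenance <- "conditioned"
  }
  P <- scan_p_matrix(Y, genotypes$values)
  structure(list(scores = -log10(P), provenance = provenance),
            class = "poem_scan")
}

#' @export
print.poem_scan <- function(x, ...) {
  cat(sprintf("<poem_scan> %d traits x %d variants (%s)\n",
              nrow(x$scores), ncol(x$scores), x$provenance))
  invisible(x)
}

#' Tidy an association scan into a long tibble
#'
#' @param x A `poem_scan`.
#' @param ... Unused.
#' @return Tibble with `trait_id`, `variant_id`, `score` (-log10 P).
#' @method tidy poem_scan
#' @export
tidy.poem_scan <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "trait_id") |>
    tidyr::pivot_longer(-"trait_id", names_to = "variant_id",
                        values_to = "score")
}

# Residual trait values under an eQTL map: r_j = y_j - mu_hat - g_v beta_hat
# with (mu, beta) re-estimated from the full data, traits without a map entry
# pass through unchanged. Returns a plain matrix aligned with traits$values.
residual_values <- function(traits, genotypes, map) {
  Y <- traits$values
  if (is.null(map) || nrow(map) == 0) return(Y)
  miss <- setdiff(map$variant_id, colnames(genotypes$values))
  if (length(miss)) stop("map references unknown variants: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  R <- Y
  j <- match(map$trait_id, colnames(Y))
  if (anyNA(j)) stop("map references unknown traits", call. = FALSE)
  G <- genotypes$values[, map$variant_id, drop = FALSE]
  Ym <- Y[, j, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  sgg <- colSums(Gc^2)
  beta <- colSums(Gc * sweep(Ym, 2, colMeans(Ym))) / ifelse(sgg > 0, sgg, 1)
  beta[sgg <= 0] <- 0
  mu <- colMeans(Ym) - beta * colMeans(G)
  R[, j] <- Ym - rep(mu, each = nrow(Y)) - sweep(G, 2, beta, "*")
  R
}

#' Residual-valued trait matrix under an eQTL map
#'
#' For every trait with a map entry, removes the fitted one-locus effect of
#' its mapped variant (intercept and slope re-estimated by OLS); other traits
#' are returned unchanged.
#'
#' @inheritParams scan_associations
#' @param map eQTL map tibble (`trait_id`, `variant_id`, ...).
#' @return A [trait_matrix()] of residuals.
#' @export
compute_residuals <- function(traits, genotypes, map) {
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  check_aligned(traits, genotypes)
  out <- traits
  out$values <- residual_values(traits, genotypes, map)
  out
}

#' Best-eQTL map from an association scan
#'
#' For each trait whose best score exceeds the cutoff, emits the best-scoring
#' variant together with the refitted one-locus intercept and slope. Ties are
#' broken toward the lowest variant index, so the map is deterministic.
#'
#' @param scan A `poem_scan` from [scan_associations()].
#' @param traits,genotypes The matrices the scan was computed from (used to
#'   refit per-pair coefficients).
#' @param score_cutoff Minimum -log10 P to call an eQTL. The default 2
#'   corresponds to the grouping significance P = 0.01.
#' @return Tibble map: `trait_id`, `variant_id`, `score`, `mu_hat`, `beta_hat`.
#' @export
best_eqtl_map <- function(scan, traits, genotypes, score_cutoff = 2) {
  stopifnot(inherits(scan, "poem_scan"), score_cutoff >= 0)
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  A <- scan$scores
  best <- max.col(A, ties.method = "first")
  keep <- A[cbind(seq_len(nrow(A)), best)] > score_cutoff
  if (!any(keep)) return(empty_eqtl_map())
  jj <- which(keep)
  vv <- best[keep]
  G <- genotypes$values[, vv, drop = FALSE]
  Ym <- traits$values[, jj, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  sgg <- colSums(Gc^2)
  beta <- colSums(Gc * sweep(Ym, 2, colMeans(Ym))) / ifelse(sgg > 0, sgg, 1)
  mu <- colMeans(Ym) - beta * colMeans(G)
  tibble::tibble(
    trait_id = rownames(A)[jj],
    variant_id = colnames(A)[vv],
    score = A[cbind(jj, vv)],
    mu_hat = unname(mu),
    beta_hat = unname(beta))
}

empty_eqtl_map <- function() {
  tibble::tibble(trait_id = character(), variant_id = character(),
                 score = numeric(), mu_hat = numeric(), beta_hat = numeric())
}
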