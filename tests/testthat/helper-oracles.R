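# Independent oracles and small fixtures shared across tests. The oracles
# deliberately use a different computational route than the package code.

# Two-group ANOVA via explicit group-mean formulas (oracle for the one-locus
# F-test: the -1/+1 regression is algebraically a two-group ANOVA).
anova_oracle <- function(y, g) {
  y1 <- y[g == 1]; y0 <- y[g == -1]
  n1 <- length(y1); n0 <- length(y0); n <- n1 + n0
  gm <- mean(y)
  ssb <- n1 * (mean(y1) - gm)^2 + n0 * (mean(y0) - gm)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(fstat = f, p_value = pf(f, 1, n - 2, lower.tail = FALSE))
}

# Brute-force hypergeometric upper tail by direct summation of the pmf.
hyper_oracle <- function(n1, n2, overlap, l) {
  ks <- overlap:min(n1, n2)
  sum(choose(n1, ks) * choose(l - n1, n2 - ks)) / choose(l, n2)
}

# lm()/anova()-based oracle for the two-locus interaction test.
epistasis_oracle <- function(y, g1, g2) {
  full <- lm(y ~ g1 + g2 + I(g1 * g2))
  reduced <- lm(y ~ g1 + g2)
  anova(reduced, full)[2, "Pr(>F)"]
}

# Exhaustive two-covariate OLS over all variant pairs: the best pair by
# residual sum of squares (oracle for stepwise mappers on strong signals).
best_pair_oracle <- function(y, G) {
  m <- ncol(G)
  best <- c(NA, NA); best_sse <- Inf
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, m)) {
      sse <- sum(lm.fit(cbind(1, G[, a], G[, b]), y)$residuals^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(a, b) }
    }
  }
  colnames(G)[best]
}

# A tiny deterministic -1/+1 genotype matrix with both alleles per column.
toy_genotypes <- function(n = 12, m = 6, seed = 7) {
  set.seed(seed)
  repeat {
    G <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
    if (all(abs(colSums(G)) < n)) break
  }
  colnames(G) <- paste0("V", seq_len(m))
  rownames(G) <- paste0("I", seq_len(n))
  G
}

# Fabricate a poem_grouping from a list of trait-id vectors and reps, with a
# score matrix consistent enough for the module construction to consume.
fake_grouping <- function(trait_sets, reps, scores = NULL) {
  if (is.null(scores)) scores <- rep(10, length(trait_sets))
  structure(list(
    groups = tibble::tibble(
      group_id = seq_along(trait_sets),
      representative = reps,
      group_score = scores,
      n_traits = lengths(trait_sets),
      trait_ids = trait_sets),
    source = "plain"), class = "poem_grouping")
}

# Rand index between two partitions given as named membership vectors.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
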