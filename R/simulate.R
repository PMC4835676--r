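# Synthetic two-locus benchmark collections with known ground truth.
#
# A collection plants two causal variants v1, v2 among m unlinked variants
# (alleles -1/+1 sampled with equal probability) and generates four trait
# classes: dual traits affected by both loci through the two-locus model
# y = mu + g1 b1 + g2 b2 + (g1 g2) b12 + e, single-effect traits affected by
# one locus (y = mu + g gamma + e), and unassociated null traits (y = e).
# Under the additive setting b1 = b2 = gamma, b12 = 0; under the epistatic
# (co-adaptive) setting b1 = b2 = 0, b12 = gamma, so each planted locus has
# no marginal effect and only the joint effect is visible.

#' Simulation settings for a synthetic collection
#'
#' Defaults are the benchmark conditions: 100 variants, 10 dual-effect
#' traits, 10 + 10 single-effect traits, 50 null traits, error variance 0.5.
#'
#' @param model `"additive"` or `"epistatic"` joint effect for dual traits.
#' @param gamma Genetic effect size (the regression coefficient on the -1/+1
#'   genotype; half the difference between the allele-class means).
#' @param n_individuals Number of individuals.
#' @param m_variants Number of variants (>= 2).
#' @param l_dual,l_only1,l_only2,l_null Trait-class counts.
#' @param sigma2 Error variance of the Gaussian noise.
#' @param mu Global mean of the genetic models.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(model = c("additive", "epistatic"), gamma = 0.6,
                     n_individuals = 100, m_variants = 100,
                     l_dual = 10, l_only1 = 10, l_only2 = 10, l_null = 50,
                     sigma2 = 0.5, mu = 0) {
  model <- match.arg(model)
  stopifnot(gamma >= 0, sigma2 > 0, m_variants >= 2, n_individuals >= 4,
            l_dual >= 0, l_only1 >= 0, l_only2 >= 0, l_null >= 0)
  structure(list(model = model, gamma = gamma,
                 n_individuals = n_individuals, m_variants = m_variants,
                 l_dual = l_dual, l_only1 = l_only1, l_only2 = l_only2,
                 l_null = l_null, sigma2 = sigma2, mu = mu),
            class = "sim_spec")
}

#' Simulate one synthetic collection
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed; the collection is fully reproducible from
#'   (spec, seed).
#' @return A `poem_collection`: list with `traits` ([trait_matrix()]),
#'   `genotypes` ([genotype_matrix()]), `truth` (tibble of `trait_id`,
#'   `class`) and the planted variant ids `v1`, `v2`.
#' @export
simulate_collection <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  n <- spec$n_individuals; m <- spec$m_variants
  G <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  # monomorphic variants would be unidentifiable downstream: resample
  mono <- which(abs(colSums(G)) == n)
  while (length(mono)) {
    G[, mono] <- sample(c(-1, 1), n * length(mono), replace = TRUE)
    mono <- mono[abs(colSums(G[, mono, drop = FALSE])) == n]
  }
  colnames(G) <- sprintf("V%03d", seq_len(m))
  rownames(G) <- sprintf("I%03d", seq_len(n))
  g1 <- G[, 1]; g2 <- G[, 2]
  sd_e <- sqrt(spec$sigma2)
  gamma <- spec$gamma; mu <- spec$mu

  dual_mean <- switch(spec$model,
    additive = mu + gamma * g1 + gamma * g2,
    epistatic = mu + gamma * g1 * g2)
  mk <- function(mean_vec, count) {
    if (count == 0) return(NULL)
    matrix(mean_vec, n, count) + matrix(stats::rnorm(n * count, 0, sd_e), n, count)
  }
  Y <- cbind(mk(dual_mean, spec$l_dual),
             mk(mu + gamma * g1, spec$l_only1),
             mk(mu + gamma * g2, spec$l_only2),
             mk(0, spec$l_null))
  classes <- rep(c("dual", "only_v1", "only_v2", "null"),
                 c(spec$l_dual, spec$l_only1, spec$l_only2, spec$l_null))
  prefix <- c(dual = "dual", only_v1 = "one1_", only_v2 = "one2_", null = "null")
  within <- as.integer(stats::ave(seq_along(classes), classes, FUN = seq_along))
  ids <- sprintf("%s%02d", prefix[classes], within)
  colnames(Y) <- ids
  rownames(Y) <- rownames(G)
  structure(
    list(traits = trait_matrix(Y),
         genotypes = genotype_matrix(G),
         truth = tibble::tibble(trait_id = ids, class = classes),
         v1 = colnames(G)[1], v2 = colnames(G)[2],
         spec = spec, seed = seed),
    class = "poem_collection")
}

#' @export
print.poem_collection <- function(x, ...) {
  cat(sprintf("<poem_collection> %s model, gamma = %g: %d individuals, %d variants, %d traits\n",
              x$spec$model, x$spec$gamma, nrow(x$genotypes$values),
              ncol(x$genotypes$values), ncol(x$traits$values)))
  invisible(x)
}

#' Simulate a dataset of independent collections
#'
#' @param spec A [sim_spec()].
#' @param n_collections Number of collections.
#' @param seed Master seed; per-collection seeds are derived substreams, so
#'   the dataset is reproducible and collections are independent.
#' @return A list of `poem_collection`s (class `poem_dataset`).
#' @export
simulate_dataset <- function(spec, n_collections = 500, seed = 1) {
  stopifnot(n_collections >= 1)
  seeds <- derive_seeds(seed, n_collections)
  structure(purrr::map(seq_len(n_collections),
                       function(i) simulate_collection(spec, seeds[i])),
            class = "poem_dataset", spec = spec, seed = seed)
}

#' @export
print.poem_dataset <- function(x, ...) {
  cat(sprintf("<poem_dataset> %d collections\n", length(x)))
  invisible(x)
}
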