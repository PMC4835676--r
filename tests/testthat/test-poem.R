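test_that("overlap_pvalue equals brute-force hypergeometric summation", {
  # closed-form anchors
  expect_equal(overlap_pvalue(5, 5, 5, 5), 1)
  expect_equal(overlap_pvalue(5, 5, 5, 100), 1 / choose(100, 5))
  expect_equal(overlap_pvalue(3, 4, 0, 10), 1)
  # brute force over a small grid (the acceptance suite covers l <= 20)
  for (l in c(5, 9, 13)) {
    for (n1 in 1:l) for (n2 in 1:l) {
      ov <- min(n1, n2)
      expect_equal(overlap_pvalue(n1, n2, ov, l), hyper_oracle(n1, n2, ov, l),
                   tolerance = 1e-12)
    }
  }
  expect_error(overlap_pvalue(5, 5, 6, 10), "inconsistent")
})

test_that("poeModules are significant primary/secondary overlaps with dual cutoffs", {
  # fabricated groupings over l = 80 traits
  tp <- paste0("t", 1:10)
  cP <- fake_grouping(list(tp, paste0("t", 21:30)), c("V1", "V5"))
  cS <- fake_grouping(list(tp, paste0("t", 41:50)), c("V2", "V9"))
  mods <- build_poemodules(cP, cS, l = 80)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$n_traits, 10L)
  expect_setequal(mods$trait_ids[[1]], tp)
  expect_lt(mods$overlap_p, 1e-3)
  expect_setequal(c(mods$primary_variant, mods$secondary_variant),
                  c("V1", "V2"))

  # disjoint families produce nothing
  cS2 <- fake_grouping(list(paste0("t", 61:70)), "V2")
  expect_equal(nrow(build_poemodules(cP, cS2, l = 80)), 0)

  # identical representatives are never tested as a pair
  cSsame <- fake_grouping(list(tp), "V1")
  expect_equal(nrow(build_poemodules(cP, cSsame, l = 80)), 0)

  # two-trait overlaps face the stricter cutoff: an overlap of 2 out of
  # small groups in l = 30 has P ~ 1e-2, far above 1e-6
  cP3 <- fake_grouping(list(paste0("t", 1:3)), "V1")
  cS3 <- fake_grouping(list(c("t1", "t2", "t9")), "V2")
  p2 <- overlap_pvalue(3, 3, 2, 30)
  expect_gt(p2, 1e-6)
  expect_equal(nrow(build_poemodules(cP3, cS3, l = 30)), 0)
  # the same configuration passes when offered as a >= 3 overlap elsewhere
  cS4 <- fake_grouping(list(paste0("t", 1:3)), "V2")
  expect_equal(nrow(build_poemodules(cP3, cS4, l = 30)), 1)
})

test_that("mirrored role assignments consolidate into one module", {
  # half the dual traits carry (V1 primary, V2 secondary), half the mirror
  cP <- fake_grouping(list(paste0("t", 1:5), paste0("t", 6:10)), c("V1", "V2"))
  cS <- fake_grouping(list(paste0("t", 6:10), paste0("t", 1:5)), c("V1", "V2"))
  mods <- build_poemodules(cP, cS, l = 80)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$n_traits, 10L)
  expect_setequal(c(mods$primary_variant, mods$secondary_variant),
                  c("V1", "V2"))
})

test_that("nested module removal keeps maximal trait sets and best P on ties", {
  mods <- tibble::tibble(
    module_id = paste0("M", 1:4),
    primary_variant = "V1", secondary_variant = "V2",
    n_traits = c(2L, 3L, 2L, 2L),
    overlap_p = c(1e-8, 1e-5, 1e-9, 1e-7),
    trait_ids = list(c("a", "b"), c("a", "b", "c"), c("d", "e"), c("d", "e")))
  out <- remove_nested(mods)
  sets <- lapply(out$trait_ids, sort)
  expect_equal(length(sets), 2)
  expect_true(any(vapply(sets, identical, TRUE, c("a", "b", "c"))))
  expect_true(any(vapply(sets, identical, TRUE, c("d", "e"))))
  # among the identical {d,e} sets the smaller P survived
  expect_equal(out$overlap_p[vapply(sets, identical, TRUE, c("d", "e"))], 1e-9)
  # pairwise-incomparable modules are all retained
  inc <- tibble::tibble(
    module_id = paste0("M", 1:2), primary_variant = "V1",
    secondary_variant = "V2", n_traits = 2L, overlap_p = 1e-8,
    trait_ids = list(c("a", "b"), c("b", "c")))
  expect_equal(nrow(remove_nested(inc)), 2)
})

test_that("the interaction test matches an lm/anova oracle and its anchors", {
  set.seed(30)
  G <- toy_genotypes(n = 40, m = 2, seed = 30)
  g1 <- G[, 1]; g2 <- G[, 2]
  # exact pure interaction: floored P; exact additive: P = 1 with beta12 = 0
  expect_equal(epistasis_score(g1 * g2, g1, g2)$p_value, 1e-300)
  es <- epistasis_score(g1 + g2, g1, g2)
  expect_equal(es$p_value, 1)
  expect_equal(es$beta12, 0, tolerance = 1e-12)
  # collinear interaction column
  ec <- epistasis_score(rnorm(40), g1, g1)
  expect_true(ec$collinear)
  expect_equal(ec$p_value, 1)
  # random instances against the oracle
  for (i in 1:25) {
    y <- 0.3 * g1 - 0.2 * g2 + 0.4 * g1 * g2 + rnorm(40)
    expect_equal(epistasis_score(y, g1, g2)$p_value,
                 epistasis_oracle(y, g1, g2), tolerance = 1e-10)
  }
})

test_that("epistasis classification flags planted interactions at module level", {
  set.seed(31)
  n <- 100
  G <- toy_genotypes(n = n, m = 6, seed = 31)
  Y <- cbind(add1 = 1.4 * (G[, 1] + G[, 2]) + rnorm(n, sd = 0.7),
             add2 = 1.4 * (G[, 1] + G[, 2]) + rnorm(n, sd = 0.7),
             epi1 = 1.8 * G[, 1] * G[, 2] + rnorm(n, sd = 0.7))
  rownames(Y) <- rownames(G)
  mods <- tibble::tibble(
    module_id = c("M1", "M2"),
    primary_variant = "V1", secondary_variant = "V2",
    n_traits = c(2L, 1L), overlap_p = 1e-9,
    trait_ids = list(c("add1", "add2"), "epi1"))
  out <- classify_epistatic(mods, Y, G, fdr_level = 0.01)
  expect_false(out$is_epistatic[out$module_id == "M1"])
  expect_true(out$is_epistatic[out$module_id == "M2"])
  # empty module set passes through
  expect_equal(nrow(classify_epistatic(mods[0, ], Y, G)), 0)
})

test_that("cis/trans annotation follows the distance window and strict fraction", {
  vals <- matrix(rep(c(-1, 1), 10), 10, 2)
  G <- genotype_matrix(vals, variant_ids = c("V1", "V2"),
                       chrom = c("1", "2"), pos_bp = c(5e6, 5e6))
  mkY <- function(chroms, pos) {
    trait_matrix(matrix(rnorm(10 * length(chroms)), 10),
                 trait_ids = paste0("t", seq_along(chroms)),
                 gene_chrom = chroms, gene_pos_bp = pos)
  }
  mods <- tibble::tibble(
    module_id = "M1", primary_variant = "V1", secondary_variant = "V2",
    n_traits = 3L, overlap_p = 1e-9,
    trait_ids = list(c("t1", "t2", "t3")))

  # all genes on chromosome 3: both loci trans for every trait
  Y <- mkY(c("3", "3", "3"), c(1e6, 2e6, 3e6))
  out <- classify_cis_trans(mods, G, Y)
  expect_equal(out$cis_trans_label, "trans-acting")
  expect_true(all(out$cis_trans[[1]]$pair_class == "trans-trans"))

  # a gene 4 Mbp from V1 on chr1 is cis to it ("< 10 Mbp")
  Y2 <- mkY(c("1", "3", "3"), c(9e6, 1e6, 1e6))
  out2 <- classify_cis_trans(mods, G, Y2)
  expect_equal(out2$cis_trans[[1]]$pair_class[1], "cis-trans")

  # trans fraction exactly at the threshold: neither label (strict above/below)
  mods3 <- dplyr::mutate(mods, trait_ids = list(paste0("t", 1:3)))
  Y3 <- mkY(c("1", "3", "3"), c(9e6, 1e6, 1e6))   # 2/3 trans-trans
  out3 <- classify_cis_trans(mods3, G, Y3, trans_fraction = 2 / 3)
  expect_equal(out3$cis_trans_label, "unannotated")

  # no locatable genes: unannotated
  Y4 <- mkY(rep(NA_character_, 3), rep(NA_real_, 3))
  expect_equal(classify_cis_trans(mods, G, Y4)$cis_trans_label, "unannotated")
})

test_that("module graphs are labelled singleton, multifurcating or composite", {
  mk <- function(prim, sec) tibble::tibble(
    module_id = paste0("M", seq_along(prim)),
    primary_variant = prim, secondary_variant = sec,
    n_traits = 2L, overlap_p = 1e-9,
    trait_ids = replicate(length(prim), c("a", "b"), simplify = FALSE))

  g1 <- module_graph(mk("V1", "V2"))
  expect_equal(g1$components$structure, "singleton")

  # five modules share one secondary hub with private primaries
  g2 <- module_graph(mk(paste0("P", 1:5), rep("S1", 5)))
  expect_equal(g2$components$structure, "multifurcating")
  expect_equal(g2$components$n_modules, 5L)

  # sharing on both sides: two modules share a primary AND two of them share
  # a secondary with a third -> composite
  g3 <- module_graph(mk(c("P1", "P1", "P2"), c("S1", "S2", "S2")))
  expect_equal(g3$components$structure, "composite")

  # empty module set
  g0 <- module_graph(mk(character(0), character(0))[0, ])
  expect_equal(nrow(g0$components), 0)
})

test_that("poem returns a coherent fit with a bounded iteration trace", {
  coll <- simulate_collection(sim_spec("additive", 1.2, 120), seed = 33)
  fit <- poem(coll$traits, coll$genotypes, k = 2)
  expect_s3_class(fit, "poem_fit")
  tr <- fit$iteration_trace
  expect_equal(tr$stage[1], "initialization")
  expect_true(all(tr$n_groups >= 0) && all(tr$n_traits >= 0))
  expect_true(all(fit$primary_groups$groups$group_score > 2))
  expect_true(all(fit$secondary_groups$groups$group_score > 2))
  # every module is the intersection/union of groups of its two variants
  for (i in seq_len(nrow(fit$modules))) {
    asnP <- tidy(fit$primary_groups); asnS <- tidy(fit$secondary_groups)
    tr_i <- fit$modules$trait_ids[[i]]
    expect_true(all(tr_i %in% asnP$trait_id))
    expect_true(all(tr_i %in% asnS$trait_id))
  }
  gl <- glance(fit)
  expect_equal(gl$n_modules, nrow(fit$modules))
})

test_that("permutation FDR is small for planted structure and honest on noise", {
  coll <- simulate_collection(sim_spec("additive", 1.4, 120), seed = 34)
  res <- permutation_fdr(coll$traits, coll$genotypes, k = 1, n_perm = 5,
                         seed = 9)
  expect_gte(res$real_modules, 1)
  expect_lt(res$fdr_modules, 0.5)
  # n_perm = 1 is degenerate but legal
  res1 <- permutation_fdr(coll$traits, coll$genotypes, k = 1, n_perm = 1,
                          seed = 10)
  expect_equal(nrow(res1$perm_counts), 1)
  # with no real modules the ratio is undefined
  noise <- simulate_collection(sim_spec("additive", 0, 40,
                                        l_dual = 0, l_only1 = 0, l_only2 = 0,
                                        l_null = 20), seed = 11)
  resn <- permutation_fdr(noise$traits, noise$genotypes, k = 1, n_perm = 2,
                          seed = 12)
  if (resn$real_modules == 0) expect_true(is.na(resn$fdr_modules))
})
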