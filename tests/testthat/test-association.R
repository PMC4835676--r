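test_that("fit_single_locus matches an independent two-group ANOVA", {
  # the worked six-point example: three individuals per allele class
  y <- c(1.2, 0.8, 1.1, -0.9, -1.3, -1.0)
  g <- c(1, 1, 1, -1, -1, -1)
  fit <- fit_single_locus(y, g)
  orc <- anova_oracle(y, g)
  expect_equal(fit$fstat, orc$fstat, tolerance = 1e-12)
  expect_equal(fit$p_value, orc$p_value, tolerance = 1e-12)
  expect_equal(fit$beta_hat, (mean(y[g == 1]) - mean(y[g == -1])) / 2,
               tolerance = 1e-12)

  # random small instances, including unbalanced allele classes
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    g <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- rnorm(n) + g * runif(1, 0, 2)
    fit <- fit_single_locus(y, g)
    orc <- anova_oracle(y, g)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
    # and the F statistic is the squared pooled-variance t statistic
    tt <- t.test(y[g == 1], y[g == -1], var.equal = TRUE)
    expect_equal(fit$fstat, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("fit_single_locus handles degenerate inputs", {
  g <- rep(c(-1, 1), each = 5)
  # perfect fit: P at the floor, slope recovered exactly
  fit <- fit_single_locus(g, g)
  expect_equal(fit$beta_hat, 1)
  expect_equal(fit$p_value, 1e-300)
  # constant trait: no effect, P = 1
  fit <- fit_single_locus(rep(2, 10), g)
  expect_equal(fit$beta_hat, 0)
  expect_equal(fit$p_value, 1)
  expect_equal(fit$fstat, 0)
  # monomorphic variant: unidentifiable
  fit <- fit_single_locus(rnorm(10), rep(1, 10))
  expect_true(fit$monomorphic)
  expect_equal(fit$p_value, 1)
  expect_error(fit_single_locus(rnorm(3), c(-1, 1, 1)), "4 observations")
  expect_error(fit_single_locus(rnorm(4), c(0, 1, 1, -1)), "-1/\\+1")
})

test_that("one-locus scan localizes planted signals and reduces to the single fit", {
  G <- toy_genotypes(n = 30, m = 8, seed = 1)
  set.seed(2)
  y <- 2 * G[, 5] + rnorm(30, sd = 0.3)
  scan <- scan_associations(matrix(y, dimnames = list(rownames(G), "t1")), G)
  expect_s3_class(scan, "poem_scan")
  expect_equal(unname(which.max(scan$scores[1, ])), 5)
  expect_equal(scan$provenance, "plain")

  # l = 1, m = 1 agrees with fit_single_locus
  one <- scan_associations(matrix(y, dimnames = list(rownames(G), "t1")),
                           G[, 3, drop = FALSE])
  expect_equal(10^(-one$scores[1, 1]),
               fit_single_locus(y, G[, 3])$p_value, tolerance = 1e-10)

  # monomorphic variants keep the matrix shape with score 0
  G2 <- cbind(G, Vmono = rep(1, 30))
  scan2 <- scan_associations(matrix(y, dimnames = list(rownames(G), "t1")), G2)
  expect_equal(unname(scan2$scores[1, "Vmono"]), 0)
  expect_equal(ncol(scan2$scores), 9)
})

test_that("residuals are orthogonal to the conditioning variant and pass through unmapped traits", {
  G <- toy_genotypes(n = 24, m = 5, seed = 3)
  set.seed(4)
  Y <- cbind(a = 3 + 2 * G[, 2],                 # exact linear in V2
             b = rnorm(24),                      # mapped, arbitrary
             c = rnorm(24))                      # not mapped
  rownames(Y) <- rownames(G)
  map <- tibble::tibble(trait_id = c("a", "b"), variant_id = c("V2", "V4"))
  res <- compute_residuals(Y, G, map)
  expect_equal(unname(res$values[, "a"]), rep(0, 24), tolerance = 1e-12)
  expect_equal(res$values[, "c"], Y[, "c"])
  # OLS normal equations: residuals sum to zero and are orthogonal to g
  expect_equal(sum(res$values[, "b"]), 0, tolerance = 1e-10)
  expect_equal(sum(res$values[, "b"] * G[, 4]), 0, tolerance = 1e-10)
})

test_that("conditioning on an empty map is identical to the plain scan", {
  G <- toy_genotypes(n = 20, m = 6, seed = 5)
  set.seed(6)
  Y <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(rownames(G), paste0("t", 1:3)))
  plain <- scan_associations(Y, G)
  cond <- scan_associations(Y, G, condition_on = empty_map <- tibble::tibble(
    trait_id = character(), variant_id = character()))
  expect_identical(cond$scores, plain$scores)

  # conditioning a trait on its own best eQTL drives that score to ~0
  y <- 2 * G[, 1] + rnorm(20, sd = 0.4)
  Y2 <- matrix(y, dimnames = list(rownames(G), "t"))
  cond2 <- scan_associations(Y2, G, condition_on = tibble::tibble(
    trait_id = "t", variant_id = "V1"))
  expect_lt(cond2$scores[1, 1], 1e-10)
  expect_equal(cond2$provenance, "conditioned")
})

test_that("best_eqtl_map picks argmax rows above the cutoff with deterministic ties", {
  G <- toy_genotypes(n = 30, m = 8, seed = 8)
  set.seed(9)
  Y <- cbind(hit = G[, 7] * 2 + rnorm(30, sd = 0.2),
             flat = rnorm(30, sd = 0.1))
  rownames(Y) <- rownames(G)
  scan <- scan_associations(Y, G)
  map <- best_eqtl_map(scan, Y, G, score_cutoff = 2)
  expect_equal(map$variant_id[map$trait_id == "hit"], "V7")
  # infinite cutoff: empty map
  expect_equal(nrow(best_eqtl_map(scan, Y, G, score_cutoff = Inf)), 0)
  # tie broken toward the lowest variant index
  fake <- scan
  fake$scores[] <- 0
  fake$scores[1, c(3, 6)] <- 5
  tied <- best_eqtl_map(fake, Y, G, score_cutoff = 2)
  expect_equal(tied$variant_id, "V3")
})

test_that("null scan P-values are approximately uniform", {
  # fraction of null scores above -log10(0.01) should be about 1%
  set.seed(10)
  G <- toy_genotypes(n = 40, m = 50, seed = 10)
  Y <- matrix(rnorm(40 * 40), 40, 40,
              dimnames = list(rownames(G), paste0("t", 1:40)))
  scan <- scan_associations(Y, G)
  frac <- mean(scan$scores > 2)
  expect_gt(frac, 0.004)
  expect_lt(frac, 0.02)
})
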