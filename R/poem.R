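# The POEM algorithm: iterative residual-based refinement of primary and
# secondary eQTL maps over co-association groups, and construction of
# poeModules as significant overlaps between primary and secondary groups.

#' Run POEM
#'
#' Initialization: a plain one-locus scan grouped into primary co-association
#' groups. Each iteration then learns secondary eQTLs by scanning residuals
#' conditioned on the primary map (stage 2) and, between iterations,
#' re-learns primary eQTLs by scanning residuals conditioned on the secondary
#' map (stage 1), always using the most recent available map. `k = 1` is the
#' non-iterative variant: exactly two sequential scans, which for a single
#' trait reduces to residual-based stepwise regression. poeModules are the
#' significant primary-by-secondary group overlaps (hypergeometric test),
#' consolidated over the unordered eQTL pair, with nested modules removed and
#' epistasis classified via the two-locus interaction test.
#'
#' @inheritParams scan_associations
#' @param k Number of iterations (paper-style default 6).
#' @param group_p Association P-value cutoff for grouping (default 0.01).
#' @param window_bp Linkage window for agglomeration when the genotypes carry
#'   coordinates; ignored for coordinate-less panels.
#' @param overlap_p_pairs Overlap P cutoff for two-trait modules (1e-6).
#' @param overlap_p_larger Overlap P cutoff for modules with >= 3 traits (1e-3).
#' @param min_overlap Minimum module size (2).
#' @param epistasis_fdr FDR level for calling a module epistatic (0.01).
#' @param cis_window_bp Window for cis eQTL calls when gene locations are
#'   available (10 Mbp).
#' @param trans_fraction Trans-trans trait fraction above (below) which a
#'   module is labelled trans-acting (cis-acting); 0.66.
#' @return A `poem_fit` with groupings, maps, the module table, scans and an
#'   iteration trace. See [tidy.poem_fit()] and [glance.poem_fit()].
#' @export
poem <- function(traits, genotypes, k = 6, group_p = 0.01, window_bp = 2e6,
                 overlap_p_pairs = 1e-6, overlap_p_larger = 1e-3,
                 min_overlap = 2, epistasis_fdr = 0.01,
                 cis_window_bp = 1e7, trans_fraction = 0.66) {
  stopifnot(k >= 1, group_p > 0, group_p <= 1)
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  check_aligned(traits, genotypes)
  cutoff <- -log10(group_p)

  trace <- list()
  note <- function(stage, iteration, grouping) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      iteration = iteration, stage = stage,
      n_groups = nrow(grouping$groups),
      n_traits = sum(grouping$groups$n_traits))
  }

  scanP <- scan_associations(traits, genotypes)
  cP <- agglomerate_groups(initialize_groups(scanP, cutoff), scanP, genotypes,
                           window_bp, cutoff)
  VP <- group_eqtl_map(cP, traits, genotypes)
  note("initialization", 0L, cP)

  scanS <- NULL; cS <- NULL; VS <- empty_eqtl_map()
  for (i in seq_len(k)) {
    # stage 2: learn secondary eQTLs conditioned on the primary map
    scanS <- scan_associations(traits, genotypes, condition_on = VP)
    cS <- agglomerate_groups(initialize_groups(scanS, cutoff), scanS, genotypes,
                             window_bp, cutoff)
    VS <- group_eqtl_map(cS, traits, genotypes)
    note("secondary", i, cS)
    if (i < k) {
      # stage 1: refresh primary eQTLs conditioned on the secondary map
      scanP <- scan_associations(traits, genotypes, condition_on = VS)
      cP <- agglomerate_groups(initialize_groups(scanP, cutoff), scanP,
                               genotypes, window_bp, cutoff)
      VP <- group_eqtl_map(cP, traits, genotypes)
      note("primary", i, cP)
    }
  }

  modules <- build_poemodules(cP, cS, l = ncol(traits$values),
                              overlap_p_pairs, overlap_p_larger, min_overlap)
  modules <- remove_nested(modules)
  modules <- classify_epistatic(modules, traits, genotypes, epistasis_fdr)
  modules <- classify_cis_trans(modules, genotypes, traits,
                                cis_window_bp, trans_fraction)

  structure(
    list(primary_groups = cP, secondary_groups = cS,
         primary_map = VP, secondary_map = VS,
         primary_scan = scanP, secondary_scan = scanS,
         modules = modules,
         iteration_trace = dplyr::bind_rows(trace),
         params = list(k = k, group_p = group_p, window_bp = window_bp,
                       overlap_p_pairs = overlap_p_pairs,
                       overlap_p_larger = overlap_p_larger,
                       min_overlap = min_overlap,
                       epistasis_fdr = epistasis_fdr,
                       cis_window_bp = cis_window_bp,
                       trans_fraction = trans_fraction)),
    class = "poem_fit")
}

#' @export
print.poem_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<poem_fit> k = %d\n  %d primary groups, %d secondary groups\n",
    "  %d poeModules covering %d traits (%d epistatic)\n"),
    x$params$k, nrow(x$primary_groups$groups), nrow(x$secondary_groups$groups),
    nrow(x$modules), sum(x$modules$n_traits),
    sum(x$modules$is_epistatic %||% FALSE)))
  invisible(x)
}

#' One row per poeModule
#'
#' @param x A `poem_fit`.
#' @param ... Unused.
#' @return The module tibble (trait ids in a list column).
#' @method tidy poem_fit
#' @export
tidy.poem_fit <- function(x, ...) x$modules

#' One-row fit summary
#'
#' @param x A `poem_fit`.
#' @param ... Unused.
#' @return Tibble with group/module counts and the iteration number.
#' @method glance poem_fit
#' @export
glance.poem_fit <- function(x, ...) {
  tibble::tibble(
    k = x$params$k,
    n_primary_groups = nrow(x$primary_groups$groups),
    n_secondary_groups = nrow(x$secondary_groups$groups),
    n_modules = nrow(x$modules),
    n_module_traits = sum(x$modules$n_traits),
    n_epistatic = sum(x$modules$is_epistatic %||% logical(0)))
}

#' Hypergeometric overlap P-value
#'
#' One-sided upper-tail probability that two trait sets of sizes `n1` and
#' `n2`, drawn from `l` traits, share at least `overlap` traits.
#'
#' @param n1,n2 Group sizes.
#' @param overlap Observed intersection size.
#' @param l Total number of traits.
#' @return Probability.
#' @export
overlap_pvalue <- function(n1, n2, overlap, l) {
  if (any(overlap < 0) || any(overlap > pmin(n1, n2)) || any(pmax(n1, n2) > l)) {
    stop("inconsistent overlap counts", call. = FALSE)
  }
  stats::phyper(overlap - 1, n1, l - n1, n2, lower.tail = FALSE)
}

#' Build poeModules from primary and secondary groupings
#'
#' Every (primary group, secondary group) pair with distinct representative
#' variants is tested for trait overlap with the hypergeometric upper tail.
#' The two mirrored role assignments of the same unordered variant pair (for
#' additive effects the primary/secondary roles of a symmetric pair are
#' arbitrary) are consolidated into one module: trait set = union, overlap P
#' = the smaller of the two ordered tests, orientation taken from the more
#' significant one. Modules of exactly two traits must pass `cutoff_pairs`,
#' larger modules `cutoff_larger`.
#'
#' @param primary_groups,secondary_groups `poem_grouping` objects.
#' @param l Total number of traits in the dataset.
#' @param cutoff_pairs,cutoff_larger Overlap P cutoffs (1e-6 / 1e-3).
#' @param min_overlap Minimum module size (2).
#' @return Module tibble: `module_id`, `primary_variant`, `secondary_variant`,
#'   `n_traits`, `overlap_p`, `trait_ids` (list column).
#' @export
build_poemodules <- function(primary_groups, secondary_groups, l,
                             cutoff_pairs = 1e-6, cutoff_larger = 1e-3,
                             min_overlap = 2) {
  gp <- primary_groups$groups; gs <- secondary_groups$groups
  recs <- list()
  for (a in seq_len(nrow(gp))) {
    ta <- gp$trait_ids[[a]]
    for (b in seq_len(nrow(gs))) {
      if (gp$representative[a] == gs$representative[b]) next
      ov <- intersect(ta, gs$trait_ids[[b]])
      if (length(ov) == 0) next
      recs[[length(recs) + 1]] <- list(
        primary_variant = gp$representative[a],
        secondary_variant = gs$representative[b],
        p = overlap_pvalue(length(ta), length(gs$trait_ids[[b]]),
                           length(ov), l),
        traits = ov)
    }
  }
  if (!length(recs)) return(empty_modules())
  key <- vapply(recs, function(r)
    paste(sort(c(r$primary_variant, r$secondary_variant)), collapse = "|"),
    character(1))
  out <- lapply(split(recs, key), function(rr) {
    ps <- vapply(rr, `[[`, numeric(1), "p")
    best <- rr[[which.min(ps)]]
    list(primary_variant = best$primary_variant,
         secondary_variant = best$secondary_variant,
         overlap_p = min(ps),
         traits = sort(unique(unlist(lapply(rr, `[[`, "traits")))))
  })
  out <- unname(out)
  mods <- tibble::tibble(
    primary_variant = vapply(out, `[[`, character(1), "primary_variant"),
    secondary_variant = vapply(out, `[[`, character(1), "secondary_variant"),
    n_traits = vapply(out, function(o) length(o$traits), integer(1)),
    overlap_p = vapply(out, `[[`, numeric(1), "overlap_p"),
    trait_ids = lapply(out, `[[`, "traits"))
  mods <- mods[mods$n_traits >= min_overlap &
                 ifelse(mods$n_traits == 2,
                        mods$overlap_p < cutoff_pairs,
                        mods$overlap_p < cutoff_larger), , drop = FALSE]
  mods <- mods[order(mods$overlap_p, mods$primary_variant), , drop = FALSE]
  mods$module_id <- paste0("M", seq_len(nrow(mods)))
  dplyr::relocate(tibble::as_tibble(mods), "module_id")
}

empty_modules <- function() {
  tibble::tibble(module_id = character(), primary_variant = character(),
                 secondary_variant = character(), n_traits = integer(),
                 overlap_p = numeric(), trait_ids = list())
}

#' Drop poeModules nested within larger ones
#'
#' A module whose trait set is a strict subset of another module's trait set
#' is removed; among modules with identical trait sets only the one with the
#' smallest overlap P is kept.
#'
#' @param modules Module tibble from [build_poemodules()].
#' @return Filtered module tibble (module ids reassigned).
#' @export
remove_nested <- function(modules) {
  n <- nrow(modules)
  if (n <= 1) return(modules)
  sets <- modules$trait_ids
  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[i]) next
      si <- sets[[i]]; sj <- sets[[j]]
      if (all(si %in% sj)) {
        if (length(si) < length(sj)) drop[i] <- TRUE
        else if (setequal(si, sj)) {
          # identical sets: keep the more significant, tie to the first
          if (modules$overlap_p[i] > modules$overlap_p[j] ||
              (modules$overlap_p[i] == modules$overlap_p[j] && i > j)) {
            drop[i] <- TRUE
          }
        }
      }
    }
  }
  out <- modules[!drop, , drop = FALSE]
  out$module_id <- paste0("M", seq_len(nrow(out)))
  out
}

#' Two-locus interaction (epistasis) test
#'
#' Fits `y = mu + g1 b1 + g2 b2 + (g1*g2) b12 + e` by OLS and returns the
#' F-test P-value for `b12 != 0` on (1, n-4) degrees of freedom. A design in
#' which the interaction column is collinear with the main effects yields
#' P = 1 with `collinear = TRUE`.
#'
#' @param y Trait vector.
#' @param g1,g2 Genotype vectors coded -1/+1 (distinct variants).
#' @return List with `p_value`, `beta12`, `fstat`, `collinear`.
#' @export
epistasis_score <- function(y, g1, g2) {
  n <- length(y)
  stopifnot(length(g1) == n, length(g2) == n)
  X <- cbind(1, g1, g2, g1 * g2)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    return(list(p_value = 1, beta12 = NA_real_, fstat = NA_real_,
                collinear = TRUE))
  }
  coefs <- qr.coef(qrX, y)
  res_full <- y - X %*% coefs
  sse_full <- sum(res_full^2)
  X0 <- X[, 1:3, drop = FALSE]
  res_red <- qr.resid(qr(X0), y)
  sse_red <- sum(res_red^2)
  if (sse_full <= .Machine$double.eps * max(sse_red, 1)) {
    p <- if (sse_red - sse_full > .Machine$double.eps * max(sse_red, 1))
      .p_floor else 1
    return(list(p_value = p, beta12 = unname(coefs[4]), fstat = Inf,
                collinear = FALSE))
  }
  fstat <- (sse_red - sse_full) / (sse_full / (n - 4))
  fstat <- max(fstat, 0)
  list(p_value = max(stats::pf(fstat, 1, n - 4, lower.tail = FALSE), .p_floor),
       beta12 = unname(coefs[4]), fstat = fstat, collinear = FALSE)
}

#' Classify poeModules as epistatic or additive
#'
#' Computes the interaction test for every trait of every module against the
#' module's primary/secondary variant pair, applies Benjamini-Hochberg
#' correction pooled across all module traits, and flags a module epistatic
#' when any member trait has FDR q below `fdr_level`. The remaining modules
#' are the additive poeModules.
#'
#' @param modules Module tibble.
#' @param traits,genotypes Underlying matrices.
#' @param fdr_level FDR threshold (0.01).
#' @return Module tibble with `is_epistatic`, `min_epistasis_q` and a
#'   `epistasis` list column of per-trait tests.
#' @export
classify_epistatic <- function(modules, traits, genotypes, fdr_level = 0.01) {
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  if (nrow(modules) == 0) {
    modules$is_epistatic <- logical(0)
    modules$min_epistasis_q <- numeric(0)
    modules$epistasis <- list()
    return(modules)
  }
  tests <- purrr::map2_dfr(seq_len(nrow(modules)), modules$module_id,
    function(i, mid) {
      g1 <- genotypes$values[, modules$primary_variant[i]]
      g2 <- genotypes$values[, modules$secondary_variant[i]]
      purrr::map_dfr(modules$trait_ids[[i]], function(tr) {
        es <- epistasis_score(traits$values[, tr], g1, g2)
        tibble::tibble(module_id = mid, trait_id = tr,
                       p_value = es$p_value, beta12 = es$beta12,
                       collinear = es$collinear)
      })
    })
  tests$q_value <- stats::p.adjust(tests$p_value, method = "BH")
  by_mod <- tests |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(min_epistasis_q = min(.data$q_value),
                     is_epistatic = any(.data$q_value < fdr_level))
  modules |>
    dplyr::left_join(by_mod, by = "module_id") |>
    dplyr::mutate(epistasis = purrr::map(.data$module_id, function(mid) {
      tests[tests$module_id == mid, c("trait_id", "p_value", "q_value",
                                      "beta12", "collinear")]
    }))
}

#' Annotate poeModules as cis- or trans-acting
#'
#' A locus is cis for a trait when it lies on the trait gene's chromosome
#' within `cis_window_bp` of it. Each trait is classed cis-cis / cis-trans /
#' trans-trans by its module's two eQTLs; the module is trans-acting when the
#' trans-trans fraction among locatable traits exceeds `trans_fraction`,
#' cis-acting when below, and unannotated otherwise (no locatable traits, or
#' a fraction exactly at the threshold).
#'
#' @param modules Module tibble.
#' @param genotypes A [genotype_matrix()] with coordinates.
#' @param traits A [trait_matrix()] whose metadata holds gene locations.
#' @param cis_window_bp Cis window (10 Mbp).
#' @param trans_fraction Labelling threshold (0.66).
#' @return Module tibble with `cis_trans_label`, `frac_trans_trans` and a
#'   `cis_trans` list column of per-trait pair classes.
#' @export
classify_cis_trans <- function(modules, genotypes, traits,
                               cis_window_bp = 1e7, trans_fraction = 0.66) {
  genotypes <- as_genotype_matrix(genotypes)
  traits <- as_trait_matrix(traits)
  if (nrow(modules) == 0) {
    modules$cis_trans_label <- character(0)
    modules$frac_trans_trans <- numeric(0)
    modules$cis_trans <- list()
    return(modules)
  }
  vinfo <- genotypes$variants
  tinfo <- traits$traits
  locus_is_cis <- function(variant_id, gene_chrom, gene_pos) {
    i <- match(variant_id, vinfo$variant_id)
    !is.na(vinfo$chrom[i]) && !is.na(gene_chrom) &&
      vinfo$chrom[i] == gene_chrom &&
      abs(vinfo$pos_bp[i] - gene_pos) < cis_window_bp
  }
  per_mod <- purrr::map(seq_len(nrow(modules)), function(i) {
    purrr::map_dfr(modules$trait_ids[[i]], function(tr) {
      ti <- match(tr, tinfo$trait_id)
      gc <- tinfo$gene_chrom[ti]; gp <- tinfo$gene_pos_bp[ti]
      if (is.na(gc) || is.na(gp)) {
        return(tibble::tibble(trait_id = tr, pair_class = NA_character_))
      }
      c1 <- locus_is_cis(modules$primary_variant[i], gc, gp)
      c2 <- locus_is_cis(modules$secondary_variant[i], gc, gp)
      cls <- if (c1 && c2) "cis-cis" else if (c1 || c2) "cis-trans" else "trans-trans"
      tibble::tibble(trait_id = tr, pair_class = cls)
    })
  })
  frac <- vapply(per_mod, function(tb) {
    known <- tb$pair_class[!is.na(tb$pair_class)]
    if (!length(known)) NA_real_ else mean(known == "trans-trans")
  }, numeric(1))
  label <- dplyr::case_when(
    is.na(frac) ~ "unannotated",
    frac > trans_fraction ~ "trans-acting",
    frac < trans_fraction ~ "cis-acting",
    TRUE ~ "unannotated")
  modules$cis_trans_label <- label
  modules$frac_trans_trans <- frac
  modules$cis_trans <- per_mod
  modules
}

#' Permutation-based FDR for poeModules
#'
#' Reruns the full POEM pipeline on datasets in which the individual labels
#' of the trait matrix are randomly reshuffled relative to the genotypes, and
#' estimates the FDR as the ratio of the mean permuted module count (and
#' trait-in-module count) to the real count.
#'
#' @inheritParams poem
#' @param n_perm Number of permutations (paper-style default 100).
#' @param seed Integer seed; each permutation uses a derived substream.
#' @param ... Passed on to [poem()].
#' @return List with `fdr_modules`, `fdr_traits`, the real counts and the
#'   per-permutation count tibble. Ratios are NA when the real count is 0.
#' @export
permutation_fdr <- function(traits, genotypes, k = 6, n_perm = 100,
                            seed = 1, ...) {
  stopifnot(n_perm >= 1)
  traits <- as_trait_matrix(traits)
  genotypes <- as_genotype_matrix(genotypes)
  real <- poem(traits, genotypes, k = k, ...)
  real_modules <- nrow(real$modules)
  real_traits <- sum(real$modules$n_traits)
  n <- nrow(traits$values)
  perm_seeds <- derive_seeds(seed, n_perm)
  counts <- purrr::map_dfr(seq_len(n_perm), function(i) {
    set.seed(perm_seeds[i])
    perm <- sample.int(n)
    Yp <- traits
    Yp$values <- traits$values[perm, , drop = FALSE]
    rownames(Yp$values) <- rownames(traits$values)
    fit <- poem(Yp, genotypes, k = k, ...)
    tibble::tibble(perm = i, n_modules = nrow(fit$modules),
                   n_traits = sum(fit$modules$n_traits))
  })
  list(
    fdr_modules = if (real_modules > 0) mean(counts$n_modules) / real_modules else NA_real_,
    fdr_traits = if (real_traits > 0) mean(counts$n_traits) / real_traits else NA_real_,
    real_modules = real_modules, real_traits = real_traits,
    perm_counts = counts, fit = real)
}

#' Bipartite module-eQTL graph summary
#'
#' Builds the bipartite graph connecting each poeModule to its primary and
#' secondary eQTLs and labels every connected component: `singleton` (one
#' module with private eQTLs), `multifurcating` (several modules sharing
#' exactly one hub eQTL, all other eQTLs private), or `composite` (any richer
#' sharing pattern).
#'
#' @param modules Module tibble.
#' @return List with the `igraph` graph and a `components` tibble
#'   (`component`, `n_modules`, `structure`, `modules`).
#' @export
module_graph <- function(modules) {
  if (nrow(modules) == 0) {
    return(list(graph = igraph::make_empty_graph(),
                components = tibble::tibble(component = integer(),
                                            n_modules = integer(),
                                            structure = character(),
                                            modules = list())))
  }
  edges <- rbind(
    cbind(modules$module_id, paste0("eQTL:", modules$primary_variant)),
    cbind(modules$module_id, paste0("eQTL:", modules$secondary_variant)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$type <- grepl("^eQTL:", igraph::V(g)$name)
  comp <- igraph::components(g)
  rows <- purrr::map(seq_len(comp$no), function(ci) {
    vs <- names(comp$membership)[comp$membership == ci]
    mods <- vs[!grepl("^eQTL:", vs)]
    qtls <- vs[grepl("^eQTL:", vs)]
    degs <- igraph::degree(g, v = qtls)
    q <- length(mods)
    structure_label <-
      if (q == 1) "singleton"
      else if (sum(degs >= 2) == 1) "multifurcating"
      else "composite"
    tibble::tibble(component = ci, n_modules = q,
                   structure = structure_label, modules = list(mods))
  })
  list(graph = g, components = dplyr::bind_rows(rows))
}

#' Pair predictions from a POEM fit
#'
#' One row per trait residing in a poeModule: the predicted eQTL pair is the
#' module's (primary, secondary) representatives, and the per-trait P-values
#' are the trait's association P-values to those representatives in the final
#' primary and secondary association scans. The pair P (max of the two) is
#' the grouping cutoff at which the trait would enter both groups, so
#' sweeping it emulates sweeping the grouping significance cutoff.
#'
#' @param fit A `poem_fit`.
#' @return Tibble as in [map_rbsr()].
#' @export
poem_pairs <- function(fit) {
  stopifnot(inherits(fit, "poem_fit"))
  mods <- fit$modules
  if (nrow(mods) == 0) {
    return(tibble::tibble(trait_id = character(), primary_variant = character(),
                          secondary_variant = character(), primary_p = numeric(),
                          secondary_p = numeric(), pair_p = numeric()))
  }
  AP <- fit$primary_scan$scores
  AS <- fit$secondary_scan$scores
  # score each trait in its own orientation: consolidated modules contain
  # traits from both role assignments of the pair, and a trait's association
  # to a locus is only meaningful in the scan that was not conditioned on it
  pa <- tidy(fit$primary_groups)
  sa <- tidy(fit$secondary_groups)
  purrr::map_dfr(seq_len(nrow(mods)), function(i) {
    tr <- mods$trait_ids[[i]]
    v1 <- pa$representative[match(tr, pa$trait_id)]
    v2 <- sa$representative[match(tr, sa$trait_id)]
    tibble::tibble(
      trait_id = tr,
      primary_variant = v1, secondary_variant = v2,
      primary_p = 10^(-AP[cbind(tr, v1)]),
      secondary_p = 10^(-AS[cbind(tr, v2)]))
  }) |>
    dplyr::mutate(pair_p = pmax(.data$primary_p, .data$secondary_p)) |>
    dplyr::distinct(.data$trait_id, .keep_all = TRUE)
}

derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
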