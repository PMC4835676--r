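# ROC-based accuracy scoring of pairwise-effect recovery.
#
# A trait is predicted positive at a P-value cutoff when its predicted eQTL
# pair equals the planted pair (order-free identity) and its pair P-value is
# at or below the cutoff; the truth-positive class is the dual-effect traits.
# Sweeping the cutoff over the achieved pair P-values traces an empirical ROC
# curve. The accuracy score is the trapezoidal area under the achieved
# points, anchored at (0,0) and extended as a step function (horizontally at
# the final achieved TPR out to FPR = 1); the curve is never interpolated
# toward (1,1), so a method that names the true pair for every dual trait
# scores 1 while a method that never names it scores 0, and mid-range scores
# mostly reflect how many dual traits were recovered at all.

#' Confusion counts at one pair-P cutoff
#'
#' @param preds Pair predictions ([map_rbsr()] shape). Traits without a row
#'   are treated as predicted negative.
#' @param truth Truth tibble (`trait_id`, `class`) from a
#'   [simulate_collection()]; the positive class is `"dual"`.
#' @param pair Character vector of the two planted variant ids.
#' @param cutoff Pair P-value cutoff.
#' @param match_window_bp For real-coordinate panels, a predicted locus may
#'   match a planted locus within this window (0 = exact identity, the
#'   synthetic-benchmark default). Requires a `genotypes` attribute on
#'   `preds` when non-zero.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
classify_predictions <- function(preds, truth, pair, cutoff,
                                 match_window_bp = 0) {
  pos <- predicted_positive(preds, pair, match_window_bp)
  sig <- !is.na(preds$pair_p) & preds$pair_p <= cutoff
  hit <- preds$trait_id[pos & sig]
  is_dual <- truth$class == "dual"
  tp <- sum(truth$trait_id[is_dual] %in% hit)
  fp <- sum(truth$trait_id[!is_dual] %in% hit)
  tibble::tibble(tp = tp, fp = fp,
                 tn = sum(!is_dual) - fp, fn = sum(is_dual) - tp)
}

predicted_positive <- function(preds, pair, match_window_bp = 0) {
  stopifnot(length(pair) == 2)
  if (match_window_bp > 0) {
    gt <- attr(preds, "genotypes")
    if (is.null(gt)) stop("windowed matching needs a genotypes attribute",
                          call. = FALSE)
    vi <- gt$variants
    near <- function(a, b) {
      ia <- match(a, vi$variant_id); ib <- match(b, vi$variant_id)
      !is.na(ia) & !is.na(ib) & vi$chrom[ia] == vi$chrom[ib] &
        abs(vi$pos_bp[ia] - vi$pos_bp[ib]) <= match_window_bp
    }
    (near(preds$primary_variant, pair[1]) & near(preds$secondary_variant, pair[2])) |
      (near(preds$primary_variant, pair[2]) & near(preds$secondary_variant, pair[1]))
  } else {
    res <- (preds$primary_variant == pair[1] & preds$secondary_variant == pair[2]) |
      (preds$primary_variant == pair[2] & preds$secondary_variant == pair[1])
    res[is.na(res)] <- FALSE
    res
  }
}

#' ROC curve and accuracy score for pair predictions
#'
#' @inheritParams classify_predictions
#' @return A `poem_roc`: tibble of achieved `(fpr, tpr)` points (one per
#'   distinct pair P cutoff) plus an `accuracy` attribute; see [autoplot()].
#' @export
roc_accuracy <- function(preds, truth, pair, match_window_bp = 0) {
  if (!any(truth$class == "dual")) {
    stop("no dual-effect traits in the truth table: accuracy undefined",
         call. = FALSE)
  }
  npos <- sum(truth$class == "dual")
  nneg <- sum(truth$class != "dual")
  pos <- predicted_positive(preds, pair, match_window_bp)
  keep <- pos & !is.na(preds$pair_p)
  is_dual <- preds$trait_id %in% truth$trait_id[truth$class == "dual"]
  # only positive predictions ever contribute counts; sweep their pair P's
  pp <- preds$pair_p[keep]
  dual <- is_dual[keep]
  ord <- order(pp)
  pp <- pp[ord]; dual <- dual[ord]
  cuts <- unique(pp)
  cum_tp <- cumsum(dual); cum_fp <- cumsum(!dual)
  last <- findInterval(cuts, pp)
  pts <- tibble::tibble(
    cutoff = cuts,
    tpr = cum_tp[last] / npos,
    fpr = if (nneg > 0) cum_fp[last] / nneg else rep(0, length(cuts)))
  acc <- roc_area(pts$fpr, pts$tpr)
  structure(list(points = pts, accuracy = acc,
                 n_pos = npos, n_neg = nneg),
            class = "poem_roc")
}

# trapezoid over achieved points anchored at (0,0), step-extended to fpr = 1
roc_area <- function(fpr, tpr) {
  if (!length(fpr)) return(0)
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1)
  y <- c(0, tpr[o], tpr[o][length(o)])
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.poem_roc <- function(x, ...) {
  cat(sprintf("<poem_roc> accuracy = %.3f (%d achieved points, %d/%d pos/neg)\n",
              x$accuracy, nrow(x$points), x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy poem_roc
#' @export
tidy.poem_roc <- function(x, ...) x$points

#' @method glance poem_roc
#' @export
glance.poem_roc <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_points = nrow(x$points),
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Pooled ROC accuracy of a mapper over a dataset
#'
#' Runs a mapper on every collection, pools the pair predictions (and truth)
#' across collections, then computes one ROC. Collection-specific variant ids
#' are disambiguated internally so pooling never mixes loci across
#' collections.
#'
#' @param dataset A `poem_dataset` (list of collections).
#' @param mapper Function(traits, genotypes) returning pair predictions, e.g.
#'   [map_rbsr()], [map_pbsr()], or [poem_mapper()].
#' @return A `poem_roc`.
#' @export
dataset_roc <- function(dataset, mapper) {
  pooled <- pool_predictions(dataset, mapper)
  roc_accuracy(pooled$preds, pooled$truth, pooled$pair)
}

pool_predictions <- function(dataset, mapper) {
  parts <- purrr::imap(dataset, function(coll, i) {
    pr <- mapper(coll$traits, coll$genotypes)
    tag <- function(x) paste0("c", i, ":", x)
    list(
      preds = dplyr::mutate(pr,
        trait_id = tag(.data$trait_id),
        primary_variant = dplyr::if_else(
          .data$primary_variant %in% c(coll$v1, coll$v2),
          .data$primary_variant, tag(.data$primary_variant)),
        secondary_variant = dplyr::if_else(
          .data$secondary_variant %in% c(coll$v1, coll$v2),
          .data$secondary_variant, tag(.data$secondary_variant))),
      truth = dplyr::mutate(coll$truth, trait_id = tag(.data$trait_id)))
  })
  list(preds = dplyr::bind_rows(purrr::map(parts, "preds")),
       truth = dplyr::bind_rows(purrr::map(parts, "truth")),
       pair = c(dataset[[1]]$v1, dataset[[1]]$v2))
}

#' A POEM-based pair mapper for benchmarking
#'
#' Returns a mapper closure running POEM with `k` iterations and reporting
#' module-trait pair predictions via [poem_pairs()]. Sweeping the reported
#' pair P-values (each trait's association P to its two group
#' representatives) emulates tightening the grouping significance cutoff,
#' the natural ROC parameter for a grouping-based mapper.
#'
#' @param k Iterations.
#' @param ... Passed to [poem()] (e.g. `group_p`).
#' @return Function(traits, genotypes) -> pair predictions.
#' @export
poem_mapper <- function(k = 1, ...) {
  force(k)
  dots <- list(...)
  function(traits, genotypes) {
    fit <- do.call(poem, c(list(traits, genotypes, k = k), dots))
    poem_pairs(fit)
  }
}

#' Compare mappers on a synthetic dataset
#'
#' Computes each method's pooled ROC and accuracy score, then compares every
#' method pair with a paired t-test of specificity at matched sensitivity
#' levels (the union of achieved TPR values, with specificity linearly
#' interpolated along each curve).
#'
#' @param dataset A `poem_dataset`.
#' @param methods Named list of mapper functions.
#' @return List with `accuracy` (tibble: method, accuracy) , `roc` (named
#'   list of `poem_roc`) and `tests` (tibble of pairwise paired t-tests).
#' @export
compare_methods <- function(dataset, methods) {
  stopifnot(length(methods) >= 2, !is.null(names(methods)))
  roc <- purrr::map(methods, function(mp) dataset_roc(dataset, mp))
  acc <- tibble::tibble(method = names(methods),
                        accuracy = unname(purrr::map_dbl(roc, "accuracy")))
  nm <- names(methods)
  tests <- purrr::map_dfr(utils::combn(nm, 2, simplify = FALSE), function(pr) {
    a <- roc[[pr[1]]]; b <- roc[[pr[2]]]
    grid <- sort(unique(c(a$points$tpr, b$points$tpr)))
    grid <- grid[grid > 0]
    if (length(grid) < 2 || nrow(a$points) < 2 || nrow(b$points) < 2) {
      return(tibble::tibble(method_a = pr[1], method_b = pr[2],
                            statistic = NA_real_, p_value = NA_real_,
                            mean_spec_diff = NA_real_))
    }
    spec_at <- function(r, s) {
      # specificity achieved at sensitivity >= s (step interpolation)
      p <- r$points
      1 - vapply(s, function(si) {
        i <- which(p$tpr >= si)
        if (!length(i)) 1 else min(p$fpr[i])
      }, numeric(1))
    }
    d <- spec_at(a, grid) - spec_at(b, grid)
    if (stats::sd(d) == 0) {
      return(tibble::tibble(method_a = pr[1], method_b = pr[2],
                            statistic = 0, p_value = 1,
                            mean_spec_diff = mean(d)))
    }
    tt <- stats::t.test(d)
    tibble::tibble(method_a = pr[1], method_b = pr[2],
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   mean_spec_diff = mean(d))
  })
  list(accuracy = acc, roc = roc, tests = tests)
}
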