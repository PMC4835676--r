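# Readers and writers for the tabular formats.
#
# Genotype tables are variant-major (WebQTL convention): one row per variant
# with columns variant_id, chrom, pos_bp followed by one column per
# individual; coordinates are 1-based. Expression tables are trait-major:
# trait_id [gene_name stimulus] followed by individual columns. Gene
# locations come as BED (0-based half-open; converted to 1-based on read).

#' Read a genotype table
#'
#' @param path TSV with columns `variant_id`, `chrom`, `pos_bp`, then one
#'   column per individual. Calls are either numeric -1/+1 (`dialect =
#'   "numeric"`) or biallelic letters (`dialect = "letter"`) translated via
#'   `allele_map` (e.g. `c(B = -1, D = +1)` for a B6xD2 recombinant inbred
#'   panel). Unknown or heterozygous symbols are rejected with the offending
#'   cell named.
#' @param dialect `"numeric"` or `"letter"`.
#' @param allele_map Named vector mapping letters to -1/+1 (letter dialect).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("numeric", "letter"),
                           allele_map = c(B = -1, D = 1)) {
  dialect <- match.arg(dialect)
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("variant_id", "chrom", "pos_bp")
  if (!all(need %in% names(tb))) {
    stop("genotype table must have columns variant_id, chrom, pos_bp",
         call. = FALSE)
  }
  inds <- setdiff(names(tb), need)
  calls <- as.matrix(tb[, inds])
  if (dialect == "letter") {
    bad <- which(!(calls %in% names(allele_map)))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(calls))
      stop(sprintf("unmapped genotype symbol '%s' (variant '%s', individual '%s')",
                   calls[bad[1]], tb$variant_id[i[1]], inds[i[2]]),
           call. = FALSE)
    }
    num <- matrix(allele_map[calls], nrow(calls), ncol(calls))
  } else {
    suppressWarnings(num <- matrix(as.numeric(calls), nrow(calls), ncol(calls)))
    bad <- which(is.na(num) | !(num %in% c(-1, 1)))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(calls))
      stop(sprintf("invalid genotype call '%s' (variant '%s', individual '%s')",
                   calls[bad[1]], tb$variant_id[i[1]], inds[i[2]]),
           call. = FALSE)
    }
  }
  genotype_matrix(t(num), variant_ids = tb$variant_id, individual_ids = inds,
                  chrom = tb$chrom, pos_bp = as.numeric(tb$pos_bp))
}

#' Read an expression-trait table
#'
#' @param path TSV with columns `trait_id` (optionally `gene_name`,
#'   `stimulus`), then one column per individual. Trait ids follow the
#'   `gene@stimulus` convention when a gene is profiled under several
#'   stimulations.
#' @param individual_order Optional character vector (e.g. the genotype
#'   individual ids); columns are re-aligned to this order.
#' @return A [trait_matrix()].
#' @export
read_expression <- function(path, individual_order = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- intersect(c("trait_id", "gene_name", "stimulus"), names(tb))
  if (!"trait_id" %in% meta) stop("expression table needs a trait_id column",
                                  call. = FALSE)
  inds <- setdiff(names(tb), meta)
  vals <- as.matrix(tb[, inds])
  if (!is.numeric(vals)) stop("non-numeric expression values", call. = FALSE)
  if (!is.null(individual_order)) {
    miss <- setdiff(individual_order, inds)
    if (length(miss)) {
      stop("expression table lacks individuals: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    vals <- vals[, individual_order, drop = FALSE]
    inds <- individual_order
  }
  trait_matrix(t(vals), trait_ids = tb$trait_id, individual_ids = inds,
               gene_name = if ("gene_name" %in% meta) tb$gene_name,
               stimulus = if ("stimulus" %in% meta) tb$stimulus)
}

#' Read gene locations from a BED file
#'
#' BED is 0-based half-open; returned positions are the 1-based start. The
#' `name` field is matched against trait gene names.
#'
#' @param path BED file (chrom, start, end, name).
#' @return Tibble with `gene_name`, `gene_chrom`, `gene_pos_bp`.
#' @export
read_gene_locations <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          start = readr::col_double(),
                          end = readr::col_double(),
                          name = readr::col_character()))
  tibble::tibble(gene_name = tb$name, gene_chrom = tb$chrom,
                 gene_pos_bp = tb$start + 1)
}

#' Attach gene locations to a trait matrix
#'
#' @param traits A [trait_matrix()].
#' @param locations Tibble from [read_gene_locations()].
#' @return The trait matrix with per-trait gene coordinates filled in from
#'   the traits' `gene_name` (falling back to the trait id's `gene@stimulus`
#'   gene part).
#' @export
attach_gene_locations <- function(traits, locations) {
  traits <- as_trait_matrix(traits)
  genes <- traits$traits$gene_name
  genes[is.na(genes)] <- sub("@.*$", "", traits$traits$trait_id[is.na(genes)])
  i <- match(genes, locations$gene_name)
  traits$traits$gene_chrom <- locations$gene_chrom[i]
  traits$traits$gene_pos_bp <- locations$gene_pos_bp[i]
  traits
}

#' Stimulation-response traits from paired expression matrices
#'
#' The response of a gene to a stimulus is the difference between the
#' log-transformed expression after stimulation and at steady state.
#'
#' @param stimulated,steady Matrices (individuals x genes), aligned.
#' @param log_transform Apply `log2` before differencing (set `FALSE` when
#'   the inputs are already on a log scale).
#' @return Matrix of response traits.
#' @export
compute_response <- function(stimulated, steady, log_transform = FALSE) {
  stimulated <- as.matrix(stimulated); steady <- as.matrix(steady)
  stopifnot(identical(dim(stimulated), dim(steady)))
  if (log_transform) {
    stimulated <- log2(stimulated); steady <- log2(steady)
  }
  stimulated - steady
}

#' Write / read a grouping as TSV
#'
#' @param grouping A `poem_grouping`.
#' @param path Output path.
#' @export
write_grouping_tsv <- function(grouping, path) {
  readr::write_tsv(tidy(grouping), path)
  invisible(path)
}

#' Write pair predictions as TSV
#'
#' @param preds Pair-prediction tibble.
#' @param path Output path.
#' @export
write_pairs_tsv <- function(preds, path) {
  readr::write_tsv(preds, path)
  invisible(path)
}

#' Write the module table as TSV
#'
#' Trait ids are comma-separated; list diagnostics columns are dropped.
#'
#' @param modules Module tibble (or a `poem_fit`).
#' @param path Output path.
#' @export
write_modules_tsv <- function(modules, path) {
  if (inherits(modules, "poem_fit")) modules <- modules$modules
  flat <- modules |>
    dplyr::mutate(trait_ids = purrr::map_chr(.data$trait_ids, paste,
                                             collapse = ",")) |>
    dplyr::select(!dplyr::where(is.list))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Read a module table written by [write_modules_tsv()]
#'
#' @param path TSV path.
#' @return Module tibble with `trait_ids` as a list column.
#' @export
read_modules_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  tb$trait_ids <- strsplit(tb$trait_ids, ",", fixed = TRUE)
  tb
}

#' Export a POEM fit as JSON
#'
#' @param fit A `poem_fit`.
#' @param path Output path.
#' @export
write_poem_json <- function(fit, path) {
  stopifnot(inherits(fit, "poem_fit"))
  mods <- fit$modules
  mods$epistasis <- NULL
  mods$cis_trans <- NULL
  obj <- list(
    params = fit$params,
    primary_groups = tidy(fit$primary_groups),
    secondary_groups = tidy(fit$secondary_groups),
    modules = mods,
    iteration_trace = fit$iteration_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the module graph as an edge list TSV
#'
#' @param modules Module tibble (or `poem_fit`).
#' @param path Output path.
#' @export
write_module_graph_tsv <- function(modules, path) {
  if (inherits(modules, "poem_fit")) modules <- modules$modules
  g <- module_graph(modules)
  el <- igraph::as_edgelist(g$graph)
  readr::write_tsv(tibble::tibble(module = el[, 1], eqtl = el[, 2]), path)
  invisible(path)
}
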