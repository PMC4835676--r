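#' Construct a genotype matrix
#'
#' Binary genotypes for haploid individuals or homozygous recombinant inbred
#' strains, coded -1/+1. Rows are individuals, columns are variants. Variant
#' genomic coordinates are optional; when absent, variants are treated as
#' unlinked (no proximity structure), which is how the synthetic benchmark
#' collections are built.
#'
#' @param x Numeric matrix or data frame of -1/+1 calls, individuals in rows.
#' @param variant_ids Character vector of variant identifiers (defaults to
#'   column names or `V1..Vm`).
#' @param individual_ids Character vector of individual identifiers (defaults
#'   to row names or `I1..In`).
#' @param chrom Optional chromosome label per variant.
#' @param pos_bp Optional 1-based base-pair position per variant.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(x, variant_ids = NULL, individual_ids = NULL,
                            chrom = NULL, pos_bp = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(variant_ids)) {
    variant_ids <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(x) %||% paste0("I", seq_len(nrow(x)))
  }
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids", call. = FALSE)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids", call. = FALSE)
  if (length(variant_ids) != ncol(x)) stop("variant_ids length != ncol", call. = FALSE)
  if (length(individual_ids) != nrow(x)) stop("individual_ids length != nrow", call. = FALSE)
  bad <- which(!(x %in% c(-1, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop(sprintf("genotype must be -1 or +1; found %s at individual '%s', variant '%s'",
                 format(x[bad[1]]), individual_ids[i[1]], variant_ids[i[2]]),
         call. = FALSE)
  }
  if (!is.null(pos_bp) && any(pos_bp < 0, na.rm = TRUE)) {
    stop("positions must be non-negative", call. = FALSE)
  }
  dimnames(x) <- list(individual_ids, variant_ids)
  structure(
    list(values = x,
         variants = tibble::tibble(
           variant_id = as.character(variant_ids),
           chrom = if (is.null(chrom)) NA_character_ else as.character(chrom),
           pos_bp = if (is.null(pos_bp)) NA_real_ else as.numeric(pos_bp))),
    class = "genotype_matrix")
}

#' Construct a trait matrix
#'
#' Expression traits across the same individuals as a [genotype_matrix()].
#' An expression trait is one gene's transcriptional response under one
#' stimulus. Optional gene locations enable cis/trans annotation.
#'
#' @param x Numeric matrix or data frame of measurements, individuals in rows.
#' @param trait_ids,individual_ids Identifiers (defaults from dimnames).
#' @param gene_name,stimulus Optional per-trait labels.
#' @param gene_chrom,gene_pos_bp Optional per-trait gene location.
#' @return A `trait_matrix` object.
#' @export
trait_matrix <- function(x, trait_ids = NULL, individual_ids = NULL,
                         gene_name = NULL, stimulus = NULL,
                         gene_chrom = NULL, gene_pos_bp = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(trait_ids)) trait_ids <- colnames(x) %||% paste0("T", seq_len(ncol(x)))
  if (is.null(individual_ids)) individual_ids <- rownames(x) %||% paste0("I", seq_len(nrow(x)))
  if (anyDuplicated(trait_ids)) stop("duplicate trait ids", call. = FALSE)
  if (length(trait_ids) != ncol(x)) stop("trait_ids length != ncol", call. = FALSE)
  if (anyNA(x)) stop("trait matrix contains missing values", call. = FALSE)
  dimnames(x) <- list(individual_ids, trait_ids)
  structure(
    list(values = x,
         traits = tibble::tibble(
           trait_id = as.character(trait_ids),
           gene_name = if (is.null(gene_name)) NA_character_ else as.character(gene_name),
           stimulus = if (is.null(stimulus)) NA_character_ else as.character(stimulus),
           gene_chrom = if (is.null(gene_chrom)) NA_character_ else as.character(gene_chrom),
           gene_pos_bp = if (is.null(gene_pos_bp)) NA_real_ else as.numeric(gene_pos_bp))),
    class = "trait_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$variants$chrom))) cat("  with genomic coordinates\n")
  invisible(x)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d individuals x %d traits\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
dim.trait_matrix <- function(x) dim(x$values)

# Coerce permissively: plain matrices / data frames are accepted anywhere a
# container is expected, so the scan functions compose with base workflows.
as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) x else genotype_matrix(x)
}

as_trait_matrix <- function(x) {
  if (inherits(x, "trait_matrix")) x else trait_matrix(x)
}

check_aligned <- function(traits, genotypes) {
  ti <- rownames(traits$values); gi <- rownames(genotypes$values)
  if (nrow(traits$values) != nrow(genotypes$values)) {
    stop("trait and genotype matrices cover different numbers of individuals",
         call. = FALSE)
  }
  if (!identical(ti, gi)) {
    stop("individual ids of traits and genotypes do not match (reorder first)",
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
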