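#' Construct a CellExpression object
#'
#' The central container of the pipeline: a sparse non-negative integer
#' count matrix (genes in rows, cells in columns) together with per-cell
#' annotations and, optionally, genomic positions for the genes (needed by
#' the copy-number smoother).
#'
#' @param counts sparse or dense matrix of non-negative integer counts,
#'   genes x cells. Row names are taken as gene ids when `gene_ids` is NULL.
#' @param cell_meta data.frame with one row per cell. Must contain
#'   `cell_id` (unique), `sample_id` and `dataset_id`; recognised optional
#'   columns are `cancer_type`, `tissue` (one of `"tumour"`, `"normal"`),
#'   `cell_type` and `malignancy` (one of `"malignant"`, `"non_malignant"`,
#'   `"unassigned"`).
#' @param gene_ids character vector of unique gene identifiers.
#' @param gene_symbols character vector of gene symbols (defaults to
#'   `gene_ids`). Gene-set matching is done on symbols, case-sensitively.
#' @param gene_positions optional data.frame with columns `gene_symbol`,
#'   `chrom`, `start` (1-based).
#'
#' @return an object of class `CellExpression`: a list with elements
#'   `counts` (dgCMatrix), `gene_ids`, `gene_symbols`, `gene_positions`,
#'   `cell_meta`.
#' @export
cell_expression <- function(counts, cell_meta, gene_ids = NULL,
                            gene_symbols = NULL, gene_positions = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) stop("gene_ids required (or rownames on counts)")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length != nrow(counts)")
  if (is.null(gene_symbols)) gene_symbols <- gene_ids
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != nrow(counts))
    stop("gene_symbols length != nrow(counts)")

  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  for (col in c("cell_id", "sample_id", "dataset_id")) {
    if (!col %in% names(cell_meta)) stop("cell_meta lacks column ", col)
    if (anyNA(cell_meta[[col]])) stop("cell_meta column ", col, " has NAs")
  }
  if (anyDuplicated(cell_meta$cell_id)) stop("duplicate cell_id in cell_meta")
  if (nrow(cell_meta) != ncol(counts)) stop("cell_meta rows != ncol(counts)")
  if ("tissue" %in% names(cell_meta) &&
      !all(cell_meta$tissue %in% c("tumour", "normal")))
    stop("tissue must be 'tumour' or 'normal'")
  if ("malignancy" %in% names(cell_meta) &&
      !all(cell_meta$malignancy %in%
           c("malignant", "non_malignant", "unassigned")))
    stop("malignancy must be malignant/non_malignant/unassigned")
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_meta$cell_id
  rownames(cell_meta) <- NULL

  if (!is.null(gene_positions)) {
    gene_positions <- as.data.frame(gene_positions, stringsAsFactors = FALSE)
    need <- c("gene_symbol", "chrom", "start")
    if (!all(need %in% names(gene_positions)))
      stop("gene_positions needs columns: ", paste(need, collapse = ", "))
    gene_positions$start <- as.integer(gene_positions$start)
  }

  structure(
    list(counts = counts, gene_ids = gene_ids, gene_symbols = gene_symbols,
         gene_positions = gene_positions, cell_meta = cell_meta),
    class = "CellExpression")
}

#' @export
print.CellExpression <- function(x, ...) {
  cat(sprintf("CellExpression: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  datasets: %s\n",
              paste(unique(x$cell_meta$dataset_id), collapse = ", ")))
  cat(sprintf("  samples: %d\n", length(unique(x$cell_meta$sample_id))))
  if (!is.null(x$gene_positions))
    cat(sprintf("  gene positions: %d genes\n", nrow(x$gene_positions)))
  invisible(x)
}

#' @export
dim.CellExpression <- function(x) dim(x$counts)

#' Subset a CellExpression by cells and/or genes
#'
#' @param x CellExpression.
#' @param cells logical/integer/character index into cells.
#' @param genes logical/integer/character (gene ids) index into genes.
#' @return the subsetted CellExpression.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CellExpression"))
  counts <- x$counts
  meta <- x$cell_meta
  gi <- seq_len(nrow(counts))
  if (!is.null(genes)) {
    gi <- if (is.character(genes)) match(genes, x$gene_ids) else
      seq_len(nrow(counts))[genes]
    if (anyNA(gi)) stop("unknown gene ids in subset")
  }
  ci <- seq_len(ncol(counts))
  if (!is.null(cells)) {
    ci <- if (is.character(cells)) match(cells, meta$cell_id) else
      seq_len(ncol(counts))[cells]
    if (anyNA(ci)) stop("unknown cell ids in subset")
  }
  cell_expression(counts[gi, ci, drop = FALSE], meta[ci, , drop = FALSE],
                  gene_ids = x$gene_ids[gi],
                  gene_symbols = x$gene_symbols[gi],
                  gene_positions = x$gene_positions)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene symbols; must be non-empty, made
#'   unique preserving order.
#' @param category one of `"pathway"`, `"regulon"`, `"hallmark"`,
#'   `"signature"`, `"mmp"`.
#' @param regulator transcription-factor name, for regulon sets.
#' @return object of class `GeneSet`.
#' @export
gene_set <- function(name, genes, category = "pathway", regulator = NULL) {
  category <- match.arg(category,
                        c("pathway", "regulon", "hallmark", "signature", "mmp"))
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), category = category,
                 genes = genes, regulator = regulator),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' (%s%s): %d genes\n", x$name, x$category,
              if (!is.null(x$regulator)) paste0(", regulator ", x$regulator)
              else "", length(x$genes)))
  invisible(x)
}

# coerce a collection argument into a named list of GeneSet
as_gene_set_list <- function(sets) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "GeneSet")))
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Construct a score matrix (units x gene sets)
#'
#' A thin wrapper around a numeric matrix whose rows are scoring units
#' (cells or samples) and whose columns are gene-set names; both dimensions
#' must be fully labelled.
#'
#' @param values numeric matrix with rownames (units) and colnames (sets).
#' @return a `ScoreMatrix` (numeric matrix subclass).
#' @export
score_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("score matrix must have unit and set labels")
  if (anyNA(values)) stop("score matrix must not contain NA")
  class(values) <- c("ScoreMatrix", class(values))
  values
}
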