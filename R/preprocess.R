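#' QC configuration
#'
#' Thresholds follow the common atlas conventions: cells need at least 200
#' detected genes and 500 UMIs; at most 10% mitochondrial reads (per-library
#' overrides up to 40% allowed); datasets are downsampled to at most
#' 100,000 cells; samples with fewer than 20 cells are excluded from
#' per-sample analyses.
#'
#' @param min_genes minimum detected genes per cell.
#' @param min_umi minimum UMI count per cell.
#' @param max_mito_fraction default mitochondrial-read cap.
#' @param mito_overrides named numeric vector (names = sample ids) of
#'   per-library caps; each must be <= 0.40.
#' @param max_cells_per_dataset downsampling cap per dataset.
#' @param min_cells_per_sample minimum cells for a sample to enter
#'   per-sample stages (NMF, pseudo-bulk).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_genes = 200L, min_umi = 500L,
                      max_mito_fraction = 0.10, mito_overrides = NULL,
                      max_cells_per_dataset = 100000L,
                      min_cells_per_sample = 20L,
                      mito_prefix = "MT-") {
  stopifnot(min_genes > 0, min_umi > 0, max_mito_fraction > 0,
            max_cells_per_dataset > 0, min_cells_per_sample > 0)
  if (!is.null(mito_overrides) && any(mito_overrides > 0.40))
    stop("per-library mitochondrial override must be <= 0.40")
  structure(list(min_genes = as.integer(min_genes),
                 min_umi = as.integer(min_umi),
                 max_mito_fraction = max_mito_fraction,
                 mito_overrides = mito_overrides,
                 max_cells_per_dataset = as.integer(max_cells_per_dataset),
                 min_cells_per_sample = as.integer(min_cells_per_sample),
                 mito_prefix = mito_prefix), class = "qc_config")
}

#' Quality-control filter
#'
#' Removes cells below the detected-gene or UMI thresholds or above the
#' mitochondrial cap (per-library overrides honoured), then downsamples
#' each dataset uniformly without replacement to the configured cap. The
#' retained-cell report is attached as attribute `"qc_report"`.
#'
#' @param x CellExpression.
#' @param cfg a [qc_config()].
#' @param seed seed for the downsampling draw.
#' @return filtered CellExpression with a `qc_report` attribute
#'   (data.frame: one row per sample with cells before/after).
#' @export
qc_filter <- function(x, cfg = qc_config(), seed = 1L) {
  stopifnot(inherits(x, "CellExpression"))
  counts <- x$counts
  detected <- Matrix::colSums(counts > 0)
  umi <- Matrix::colSums(counts)
  mito <- startsWith(x$gene_symbols, cfg$mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1) else
    rep(0, ncol(counts))
  cap <- rep(cfg$max_mito_fraction, ncol(counts))
  if (!is.null(cfg$mito_overrides)) {
    ov <- cfg$mito_overrides[x$cell_meta$sample_id]
    cap <- ifelse(is.na(ov), cap, ov)
  }
  keep <- detected >= cfg$min_genes & umi >= cfg$min_umi & mito_frac <= cap
  if (!any(keep)) stop("QC removed all cells")

  # seeded uniform downsampling per dataset
  set.seed(seed)
  ds <- x$cell_meta$dataset_id
  keep_idx <- which(keep)
  final <- logical(ncol(counts))
  for (d in unique(ds)) {
    idx <- keep_idx[ds[keep_idx] == d]
    if (length(idx) > cfg$max_cells_per_dataset)
      idx <- sort(sample(idx, cfg$max_cells_per_dataset))
    final[idx] <- TRUE
  }
  report <- stats::aggregate(
    list(cells_before = rep(1L, ncol(counts)), cells_after = as.integer(final)),
    by = list(sample_id = x$cell_meta$sample_id), FUN = sum)
  out <- subset_cells(x, cells = final)
  attr(out, "qc_report") <- report[order(report$sample_id), ]
  out
}

#' Log-normalize counts
#'
#' `value = log(1 + scale * count / cell_total)` — natural log, default
#' scale 1e4 (the standard library-size normalization of single-cell
#' toolkits).
#'
#' @param x CellExpression or a counts matrix (genes x cells).
#' @param scale scale factor.
#' @return sparse dgCMatrix of normalized values (genes x cells), rownames
#'   = gene symbols.
#' @export
lognormalize <- function(x, scale = 1e4) {
  counts <- if (inherits(x, "CellExpression")) x$counts else
    methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  sym <- if (inherits(x, "CellExpression")) x$gene_symbols else
    rownames(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) stop("zero-total cell encountered (run QC first)")
  norm <- counts %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- list(sym, colnames(counts))
  methods::as(norm, "generalMatrix")
}

#' Keep the top metabolic genes by mean expression
#'
#' Intersects the matrix genes with the metabolic list, then keeps the
#' `top_n` genes with highest mean normalized expression (all, if fewer
#' are present). Ties at the cutoff are broken lexicographically (smaller
#' symbol wins).
#'
#' @param x normalized matrix (genes x cells) with gene symbols as
#'   rownames.
#' @param metabolic_genes a [gene_set()] or character vector.
#' @param top_n number of genes to retain (default 500).
#' @return the reduced matrix.
#' @export
select_metabolic <- function(x, metabolic_genes, top_n = 500L) {
  stopifnot(top_n >= 1)
  genes <- if (inherits(metabolic_genes, "GeneSet")) metabolic_genes$genes
           else as.character(metabolic_genes)
  present <- rownames(x) %in% genes
  if (!any(present)) stop("no metabolic genes present in matrix")
  xm <- x[present, , drop = FALSE]
  means <- Matrix::rowMeans(xm)
  ord <- order(-means, rownames(xm))
  xm[ord[seq_len(min(top_n, nrow(xm)))], , drop = FALSE]
}

#' Scale per gene across cells and clip negatives
#'
#' Gene-wise z-score across cells (population standard deviation, i.e.
#' divisor n) followed by setting negative values to zero, yielding the
#' non-negative matrix consumed by NMF. Zero-variance genes become all-zero
#' rows.
#'
#' @param x reduced matrix (genes x cells), sparse or dense.
#' @return dense non-negative matrix, same dimnames.
#' @export
scale_and_clip <- function(x) {
  if (ncol(x) < 2) stop("need at least 2 cells to scale")
  m <- as.matrix(x)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  z[z < 0] <- 0
  z
}
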