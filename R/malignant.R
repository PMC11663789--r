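#' Lightweight per-cell copy-number profiles
#'
#' A simplified stand-in for HMM-based CNV callers: log-normalized
#' expression, reference-cell mean subtracted per gene, then a sliding
#' window mean over genomically ordered genes (window truncated at
#' chromosome bounds — no cross-chromosome smoothing), per-cell
#' median-centred, and clamped to +/- `clamp`.
#'
#' @param x CellExpression with `gene_positions`.
#' @param reference_cells character vector of cell ids used as the
#'   copy-number-neutral reference.
#' @param window odd window size in genes (default 101).
#' @param clamp symmetric clamp applied to the smoothed values (default 3).
#' @return matrix of smoothed values, genomically ordered genes x cells,
#'   with attributes `window` and `gene_order`.
#' @export
infer_cnv_lite <- function(x, reference_cells, window = 101L, clamp = 3) {
  stopifnot(inherits(x, "CellExpression"))
  if (is.null(x$gene_positions)) stop("gene positions required")
  if (length(reference_cells) == 0) stop("reference set is empty")
  ref_idx <- match(reference_cells, x$cell_meta$cell_id)
  if (anyNA(ref_idx)) stop("unknown reference cell ids")

  pos <- x$gene_positions
  gi <- match(x$gene_symbols, pos$gene_symbol)
  positioned <- which(!is.na(gi))
  if (!length(positioned)) stop("no positioned genes")
  chrom <- pos$chrom[gi[positioned]]
  start <- pos$start[gi[positioned]]
  ord <- positioned[order(chrom, start)]
  chrom_ord <- pos$chrom[gi[ord]]

  norm <- lognormalize(x)
  rel <- as.matrix(norm[ord, , drop = FALSE])
  rel <- rel - rowMeans(rel[, ref_idx, drop = FALSE])

  half <- (window - 1) %/% 2
  out <- matrix(0, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  for (ch in unique(chrom_ord)) {
    rows <- which(chrom_ord == ch)
    g <- length(rows)
    cs <- apply(rel[rows, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(g) - half, 1L)
    hi <- pmin(seq_len(g) + half, g)
    out[rows, ] <- (cs[hi + 1L, , drop = FALSE] -
                      cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  out <- sweep(out, 2, apply(out, 2, stats::median))
  out[out > clamp] <- clamp
  out[out < -clamp] <- -clamp
  attr(out, "window") <- as.integer(window)
  attr(out, "gene_order") <- x$gene_symbols[ord]
  out
}

#' CNV score per cell
#'
#' Quadratic sum of the smoothed copy-number values; high scores indicate
#' chromosomal aberration typical of malignant cells.
#'
#' @param p profile matrix from [infer_cnv_lite()] (genes x cells).
#' @return named non-negative numeric vector, one score per cell.
#' @export
cnv_score <- function(p) {
  if (any(!is.finite(p))) stop("profile must be finite")
  Matrix::colSums(p^2)
}

#' Iterative malignant/non-malignant classification of epithelial cells
#'
#' Each cell gets a malignant score (mean normalized expression of the top
#' `top_n` upregulated genes) and a non-malignant score (top `top_n`
#' downregulated genes) from a signed tumour-vs-normal DE list; 2-means in
#' the 2-D score space assigns putative labels (the cluster with higher
#' mean malignant score is malignant); each iteration recomputes DE
#' between the putative groups by rank-sum test, rebuilds scores and
#' re-clusters, until the fraction of labels changed versus the previous
#' round drops below `stop_rate`.
#'
#' @param x CellExpression restricted to epithelial cells.
#' @param initial_de list with character elements `up` (higher in tumour)
#'   and `down` (higher in normal).
#' @param top_n genes per score (default 50).
#' @param stop_rate convergence threshold on the between-round label-change
#'   fraction (default 0.001).
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising.
#' @param seed seed for k-means restarts.
#' @return a `MalignancyCall` list: `labels` (named, `"malignant"` /
#'   `"non_malignant"`), `malignant_score`, `nonmalignant_score`,
#'   `n_iterations`, `final_misclassification_rate`, `converged`.
#' @export
iterative_malignancy <- function(x, initial_de, top_n = 50L,
                                 stop_rate = 0.001, max_iter = 20L,
                                 seed = 1L) {
  stopifnot(inherits(x, "CellExpression"))
  if (!all(c("up", "down") %in% names(initial_de)))
    stop("initial_de must have elements 'up' and 'down'")
  norm <- lognormalize(x)
  syms <- rownames(norm)
  set.seed(seed)

  score_pair <- function(up, down) {
    up <- utils::head(up[up %in% syms], top_n)
    down <- utils::head(down[down %in% syms], top_n)
    if (length(up) == 0 || length(down) == 0)
      stop("DE gene lists do not overlap the matrix")
    cbind(mal = Matrix::colMeans(norm[up, , drop = FALSE]),
          non = Matrix::colMeans(norm[down, , drop = FALSE]))
  }
  cluster_scores <- function(sc) {
    if (stats::sd(sc[, "mal"]) == 0 && stats::sd(sc[, "non"]) == 0)
      stop("degenerate input: all scores identical")
    # raw score space: the axes' natural scales carry the group separation
    sep <- sc[, "mal"] - sc[, "non"]
    centers <- sc[c(which.max(sep), which.min(sep)), , drop = FALSE]
    if (any(duplicated(centers))) stop("degenerate input: no score spread")
    km <- suppressWarnings(stats::kmeans(sc, centers = centers,
                                         iter.max = 50))
    cl_mal <- which.max(tapply(sc[, "mal"], km$cluster, mean))
    ifelse(km$cluster == cl_mal, "malignant", "non_malignant")
  }

  sc <- score_pair(initial_de$up, initial_de$down)
  labels <- cluster_scores(sc)
  rate <- NA_real_
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (length(unique(labels)) < 2) {
      # one-cluster fixed point: nothing left to reclassify
      rate <- 0
      converged <- TRUE
      break
    }
    de <- differential(norm, labels, mode = "gene")
    de_m <- de[de$group == "malignant", ]
    de_m <- de_m[order(-de_m$log2fc), ]
    up <- de_m$feature[de_m$log2fc > 0]
    down <- rev(de_m$feature)[rev(de_m$log2fc) < 0]
    sc <- score_pair(up, down)
    new_labels <- cluster_scores(sc)
    rate <- mean(new_labels != labels)
    labels <- new_labels
    if (rate < stop_rate) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    labels = stats::setNames(labels, x$cell_meta$cell_id),
    malignant_score = stats::setNames(sc[, "mal"], x$cell_meta$cell_id),
    nonmalignant_score = stats::setNames(sc[, "non"], x$cell_meta$cell_id),
    n_iterations = iter,
    final_misclassification_rate = rate,
    converged = converged), class = "MalignancyCall")
}

#' @export
print.MalignancyCall <- function(x, ...) {
  cat(sprintf(
    "MalignancyCall: %d cells (%d malignant), %d iterations, final rate %.4g%s\n",
    length(x$labels), sum(x$labels == "malignant"), x$n_iterations,
    x$final_misclassification_rate,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Tumour-vs-normal DE list from pseudo-bulk profiles
#'
#' Builds the signed gene list that seeds [iterative_malignancy()]: a
#' rank-sum test between tumour-sample and normal-sample pseudo-bulk
#' profiles of the candidate epithelial cells, genes ordered by fold
#' change.
#'
#' @param x CellExpression containing tumour and normal tissue cells.
#' @param cell_types cell types treated as epithelial candidates.
#' @return list with `up` and `down` character vectors.
#' @export
tumour_normal_de <- function(x, cell_types = c("malignant", "epithelial")) {
  stopifnot(inherits(x, "CellExpression"))
  sel <- x$cell_meta$cell_type %in% cell_types
  if (!any(sel)) stop("no candidate epithelial cells")
  sub <- subset_cells(x, cells = sel)
  pb <- build_pseudobulk(sub, min_cells = 1L, group_by = "sample_id")
  tissue <- sub$cell_meta$tissue[match(pb$meta$sample_id,
                                       sub$cell_meta$sample_id)]
  de <- differential(t(pb$matrix), tissue, mode = "gene",
                     fdr_threshold = 1.1, pct_threshold = 0)
  de <- de[de$group == "tumour", ]
  de <- de[order(-de$log2fc), ]
  list(up = de$feature[de$log2fc > 0],
       down = rev(de$feature[de$log2fc < 0]))
}

#' Assign CD4+/CD8+ labels to T cells
#'
#' CD3 is the mean normalized expression of CD3D/CD3E/CD3G, CD8 the mean
#' of CD8A/CD8B. Cells with CD3 > 0, CD4 > 0 and CD8 = 0 are CD4+; cells
#' with CD3 > 0, CD4 = 0 and CD8 > 0 are CD8+; all others unassigned.
#'
#' @param x CellExpression restricted to T cells.
#' @return named character vector per cell in
#'   `{"CD4", "CD8", "unassigned"}`.
#' @export
assign_t_subsets <- function(x) {
  stopifnot(inherits(x, "CellExpression"))
  norm <- lognormalize(x)
  syms <- rownames(norm)
  cd3_genes <- intersect(c("CD3D", "CD3E", "CD3G"), syms)
  cd8_genes <- intersect(c("CD8A", "CD8B"), syms)
  if (!length(cd3_genes) || !"CD4" %in% syms || !length(cd8_genes))
    stop("CD3/CD4/CD8 marker genes absent")
  cd3 <- Matrix::colMeans(norm[cd3_genes, , drop = FALSE])
  cd4 <- as.vector(norm["CD4", ])
  cd8 <- Matrix::colMeans(norm[cd8_genes, , drop = FALSE])
  lab <- rep("unassigned", ncol(norm))
  lab[cd3 > 0 & cd4 > 0 & cd8 == 0] <- "CD4"
  lab[cd3 > 0 & cd4 == 0 & cd8 > 0] <- "CD8"
  stats::setNames(lab, x$cell_meta$cell_id)
}
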