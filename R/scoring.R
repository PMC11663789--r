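#' AUCell-style gene-set activity scores for single cells
#'
#' Per cell, genes are ranked by descending expression (ties broken by one
#' seeded random permutation fixed for the whole run). The score of a set
#' is the area under its recovery curve within the top
#' `ceiling(top_fraction * n_genes)` ranks, normalized by the maximal
#' achievable area, so scores lie in \[0, 1\]: 1 when the set occupies the
#' very top of the ranking, 0 when no set gene enters the window.
#'
#' @param x normalized expression matrix (genes x cells) with gene symbols
#'   as rownames.
#' @param sets list of [gene_set()] objects (or a single one).
#' @param top_fraction fraction of the ranking used as the scoring window
#'   (default 0.05, the tool-default top 5%).
#' @param seed seed for the tie-breaking permutation.
#' @return [score_matrix()], cells x sets.
#' @export
aucell_score <- function(x, sets, top_fraction = 0.05, seed = 1L) {
  stopifnot(top_fraction > 0, top_fraction <= 0.5)
  sets <- as_gene_set_list(sets)
  genes <- rownames(x)
  if (is.null(genes)) stop("matrix must carry gene symbols as rownames")
  G <- length(genes)
  w <- ceiling(top_fraction * G)
  set.seed(seed)
  tie_perm <- sample.int(G)

  set_idx <- lapply(sets, function(s) which(genes %in% s$genes))
  empty <- vapply(set_idx, length, integer(1)) == 0L
  if (any(empty))
    warning("gene sets with no genes in matrix scored 0: ",
            paste(names(sets)[empty], collapse = ", "))
  maxsum <- vapply(set_idx, function(idx) {
    s <- min(length(idx), w)
    w * s - s * (s - 1) / 2
  }, numeric(1))

  n_cells <- ncol(x)
  out <- matrix(0, n_cells, length(sets),
                dimnames = list(colnames(x), names(sets)))
  dense <- as.matrix(x)
  for (ci in seq_len(n_cells)) {
    expr <- dense[, ci]
    ord <- order(-expr, tie_perm)
    rk <- integer(G)
    rk[ord] <- seq_len(G)
    for (si in seq_along(set_idx)) {
      idx <- set_idx[[si]]
      if (!length(idx)) next
      rs <- rk[idx]
      rs <- rs[rs <= w]
      out[ci, si] <- sum(w - rs + 1) / maxsum[si]
    }
  }
  score_matrix(out)
}

#' Rank-based gene-set scores for pseudo-bulk samples
#'
#' A light-weight GSVA stand-in: per sample, genes are rank-transformed
#' within the sample and the score is the standardized difference between
#' the mean rank of the set genes and the overall mean rank
#' (`(mean_rank_set - (G+1)/2) / (sd_ranks / sqrt(m))`). The statistic is
#' signed and anti-symmetric under rank reversal; its sign and ordering,
#' not exact values, are the contract.
#'
#' @param pb sample x gene matrix (rownames = samples, colnames = genes).
#' @param sets list of [gene_set()] objects.
#' @return [score_matrix()], samples x sets.
#' @export
pseudobulk_score <- function(pb, sets) {
  if (nrow(pb) < 2) stop("need at least 2 samples")
  sets <- as_gene_set_list(sets)
  pb <- as.matrix(pb)
  G <- ncol(pb)
  rk <- t(apply(pb, 1, rank))
  set_idx <- lapply(sets, function(s) which(colnames(pb) %in% s$genes))
  empty <- vapply(set_idx, length, integer(1)) == 0L
  if (any(empty))
    warning("gene sets with no genes in matrix scored 0: ",
            paste(names(sets)[empty], collapse = ", "))
  out <- matrix(0, nrow(pb), length(sets),
                dimnames = list(rownames(pb), names(sets)))
  for (si in seq_along(set_idx)) {
    idx <- set_idx[[si]]
    if (!length(idx)) next
    m <- length(idx)
    for (r in seq_len(nrow(pb))) {
      sd_r <- stats::sd(rk[r, ])
      if (sd_r == 0) next
      out[r, si] <- (mean(rk[r, idx]) - (G + 1) / 2) / (sd_r / sqrt(m))
    }
  }
  score_matrix(out)
}

#' Differential features by Wilcoxon rank-sum, one-vs-rest
#'
#' For every group with at least 3 units, each feature is tested against
#' all remaining units with a Wilcoxon rank-sum test; p-values are BH
#' adjusted per contrast. A feature is significant when `|log2FC|` exceeds
#' the mode threshold (0.1 for genes, 0.01 for sets/pathways), FDR < 0.01,
#' and — in gene mode — the feature is detected in more than 10% of cells
#' in either population.
#'
#' @param x feature x unit matrix. Gene mode expects log-normalized
#'   expression (fold changes are computed on the de-logged scale); set
#'   mode expects a transposed score matrix (`t(scores)`).
#' @param group_labels vector of group labels per unit.
#' @param mode `"gene"` or `"set"`.
#' @param log2fc_threshold,fdr_threshold,pct_threshold significance gates;
#'   `log2fc_threshold = NULL` picks the mode default.
#' @return data.frame with columns `group`, `feature`, `log2fc`, `p`,
#'   `fdr`, `pct_group1`, `pct_group2`, `significant`.
#' @export
differential <- function(x, group_labels, mode = c("gene", "set"),
                         log2fc_threshold = NULL, fdr_threshold = 0.01,
                         pct_threshold = 0.10) {
  mode <- match.arg(mode)
  if (is.null(log2fc_threshold))
    log2fc_threshold <- if (mode == "gene") 0.1 else 0.01
  group_labels <- as.character(group_labels)
  stopifnot(ncol(x) == length(group_labels))
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) stop("need at least two groups")
  eps <- 1e-9
  feats <- rownames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(x)))
  res <- list()
  for (g in groups) {
    idx1 <- which(group_labels == g)
    idx2 <- which(group_labels != g)
    if (length(idx1) < 3) {
      warning("group '", g, "' has fewer than 3 units; skipped")
      next
    }
    if (mode == "gene") {
      m1 <- Matrix::rowMeans(expm1_sparse(x[, idx1, drop = FALSE]))
      m2 <- Matrix::rowMeans(expm1_sparse(x[, idx2, drop = FALSE]))
    } else {
      # scores are non-negative for AUC-type inputs; signed scores are
      # clamped at zero so the ratio-based fold change stays defined
      m1 <- pmax(Matrix::rowMeans(x[, idx1, drop = FALSE]), 0)
      m2 <- pmax(Matrix::rowMeans(x[, idx2, drop = FALSE]), 0)
    }
    l2fc <- log2((m1 + eps) / (m2 + eps))
    pct1 <- Matrix::rowMeans(x[, idx1, drop = FALSE] > 0)
    pct2 <- Matrix::rowMeans(x[, idx2, drop = FALSE] > 0)
    p <- wilcox_rows(x, idx1, idx2)
    fdr <- stats::p.adjust(p, "BH")
    sig <- abs(l2fc) > log2fc_threshold & fdr < fdr_threshold
    if (mode == "gene") sig <- sig & (pct1 > pct_threshold | pct2 > pct_threshold)
    res[[g]] <- data.frame(group = g, feature = feats, log2fc = l2fc,
                           p = p, fdr = fdr, pct_group1 = pct1,
                           pct_group2 = pct2, significant = sig,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no group had enough units")
  do.call(rbind, res)
}

#' Cell-to-cell metabolic similarity
#'
#' PCA on the metabolic expression profile, then the Spearman correlation
#' of each pair of cells' first `n_pcs` principal-component coordinates.
#' Component signs are fixed (largest-magnitude loading positive) so the
#' result is invariant under gene reordering of the input.
#'
#' @param x normalized metabolic matrix (genes x cells).
#' @param n_pcs number of principal components (default 30).
#' @return symmetric cells x cells similarity matrix with unit diagonal.
#' @export
metabolic_similarity <- function(x, n_pcs = 30L) {
  n_cells <- ncol(x)
  if (n_cells < n_pcs + 1)
    stop("need more cells (", n_cells, ") than components (", n_pcs, ")")
  pc <- stats::prcomp(t(as.matrix(x)), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  # sign convention: per PC, the largest-|loading| gene loads positively
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  s <- stats::cor(t(scores), method = "spearman")
  diag(s) <- 1
  dimnames(s) <- list(colnames(x), colnames(x))
  s
}

#' Lineage predictability from metabolic gene expression
#'
#' Per dataset: samples are split randomly into two equal halves
#' (seeded); up to `n_subsample` cells are drawn from each half (a cap,
#' not a quota); an L1-regularized logistic model per lineage
#' (one-vs-rest, 10-fold cross-validated penalty) is trained on metabolic
#' genes of the first half and its AUC evaluated on the held-out half.
#'
#' @param x CellExpression with `cell_type` metadata.
#' @param metabolic_genes [gene_set()] or character vector.
#' @param n_subsample per-half cell cap (default 10000).
#' @param seed RNG seed for the split and subsampling.
#' @param nfolds cross-validation folds for the penalty (default 10).
#' @return data.frame: `dataset`, `lineage`, `auc`, `n_train`, `n_test`.
#' @export
lineage_auc <- function(x, metabolic_genes, n_subsample = 10000L, seed = 1L,
                        nfolds = 10L) {
  stopifnot(inherits(x, "CellExpression"))
  genes <- if (inherits(metabolic_genes, "GeneSet")) metabolic_genes$genes
           else as.character(metabolic_genes)
  set.seed(seed)
  meta <- x$cell_meta
  norm <- lognormalize(x)
  keep_genes <- rownames(norm) %in% genes
  if (!any(keep_genes)) stop("no metabolic genes present")
  norm <- norm[keep_genes, , drop = FALSE]
  out <- list()
  for (d in unique(meta$dataset_id)) {
    cells_d <- which(meta$dataset_id == d)
    samp <- unique(meta$sample_id[cells_d])
    if (length(samp) < 2) stop("dataset ", d, " has fewer than 2 samples")
    samp <- sample(samp)
    train_samp <- samp[seq_len(floor(length(samp) / 2))]
    tr <- cells_d[meta$sample_id[cells_d] %in% train_samp]
    te <- setdiff(cells_d, tr)
    if (length(tr) > n_subsample) tr <- sort(sample(tr, n_subsample))
    if (length(te) > n_subsample) te <- sort(sample(te, n_subsample))
    Xtr <- t(as.matrix(norm[, tr, drop = FALSE]))
    Xte <- t(as.matrix(norm[, te, drop = FALSE]))
    for (lin in sort(unique(meta$cell_type[cells_d]))) {
      ytr <- meta$cell_type[tr] == lin
      yte <- meta$cell_type[te] == lin
      if (!any(ytr) || all(ytr) || !any(yte) || all(yte)) {
        warning("lineage '", lin, "' absent from a half of dataset ", d,
                "; skipped")
        next
      }
      cv <- glmnet::cv.glmnet(Xtr, factor(ytr), family = "binomial",
                              alpha = 1, nfolds = nfolds,
                              type.measure = "auc")
      pred <- as.vector(stats::predict(cv, Xte, s = "lambda.min"))
      out[[length(out) + 1]] <- data.frame(
        dataset = d, lineage = lin, auc = rank_auc(pred, yte),
        n_train = length(tr), n_test = length(te),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
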