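#' Cell-type-specific pseudo-bulk profiles
#'
#' Mean log-normalized expression per (sample, cell type) group; groups
#' below `min_cells` are omitted (reported via `message()`). The 20-cell
#' default reuses the per-sample cell threshold of the NMF stage.
#'
#' @param x CellExpression with cell types assigned.
#' @param min_cells minimal group size (default 20).
#' @param group_by `"sample_cell_type"` (default) or `"sample_id"` for
#'   plain per-sample pseudo-bulk.
#' @param norm optional precomputed normalized matrix (genes x cells).
#' @return list with `matrix` (groups x genes) and `meta` (data.frame:
#'   `key`, `sample_id`, `cell_type`, `n_cells`).
#' @export
build_pseudobulk <- function(x, min_cells = 20L,
                             group_by = c("sample_cell_type", "sample_id"),
                             norm = NULL) {
  stopifnot(inherits(x, "CellExpression"))
  group_by <- match.arg(group_by)
  if (is.null(norm)) norm <- lognormalize(x)
  meta <- x$cell_meta
  key <- if (group_by == "sample_cell_type")
    paste(meta$sample_id, meta$cell_type, sep = ":") else meta$sample_id
  tab <- table(key)
  keep_keys <- names(tab)[tab >= min_cells]
  dropped <- setdiff(names(tab), keep_keys)
  if (length(dropped))
    message(length(dropped), " groups below ", min_cells, " cells omitted: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (!length(keep_keys)) stop("no group passes the cell threshold")
  keep_keys <- sort(keep_keys)
  mat <- matrix(0, length(keep_keys), nrow(norm),
                dimnames = list(keep_keys, rownames(norm)))
  for (i in seq_along(keep_keys)) {
    cells <- which(key == keep_keys[i])
    mat[i, ] <- Matrix::rowMeans(norm[, cells, drop = FALSE])
  }
  meta_out <- data.frame(
    key = keep_keys,
    sample_id = vapply(keep_keys, function(k)
      meta$sample_id[key == k][1], character(1)),
    cell_type = if (group_by == "sample_cell_type")
      vapply(keep_keys, function(k) meta$cell_type[key == k][1],
             character(1)) else NA_character_,
    n_cells = as.integer(tab[keep_keys]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(matrix = mat, meta = meta_out)
}

#' Consensus clustering with resampling
#'
#' Per iteration, `ceiling(resample * n)` items are drawn without
#' replacement and clustered by average-linkage hierarchical clustering on
#' the 1 - Pearson correlation distance; the consensus matrix is the
#' ratio of co-clustering to co-sampling counts. The optimal k over
#' `k_range` minimizes the proportion of ambiguous consensus values (PAC,
#' fraction of off-diagonal entries in `(pac_lower, pac_upper)`); final
#' labels come from clustering the consensus matrix at that k.
#'
#' @param m item x feature matrix.
#' @param k_range candidate cluster numbers.
#' @param n_iter resampling iterations (default 1000).
#' @param resample resampling fraction (default 0.8).
#' @param seed RNG seed.
#' @param pac_lower,pac_upper PAC ambiguity bounds (default 0.1, 0.9).
#' @return `ConsensusResult` list: `consensus` (items x items, for the
#'   chosen k), `k`, `labels`, `pac` (named by k), `n_iterations`,
#'   `resample_fraction`, `consensus_by_k`.
#' @export
consensus_cluster <- function(m, k_range, n_iter = 1000L, resample = 0.8,
                              seed = 1L, pac_lower = 0.1, pac_upper = 0.9) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (max(k_range) > n) stop("k_range exceeds item count")
  if (n < 2 * max(k_range))
    stop("need at least 2*max(k_range) items")
  set.seed(seed)
  n_sub <- ceiling(resample * n)
  ks <- sort(unique(as.integer(k_range)))
  co_sampled <- matrix(0, n, n)
  co_cluster <- array(0, dim = c(n, n, length(ks)))
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, n_sub))
    sub <- m[idx, , drop = FALSE]
    d <- stats::as.dist(1 - stats::cor(t(sub)))
    if (anyNA(d)) d[is.na(d)] <- 1
    hc <- stats::hclust(d, method = "average")
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    for (ki in seq_along(ks)) {
      cl <- stats::cutree(hc, k = ks[ki])
      same <- outer(cl, cl, "==") * 1
      co_cluster[idx, idx, ki] <- co_cluster[idx, idx, ki] + same
    }
  }
  consensus_by_k <- list()
  pac <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    cons <- co_cluster[, , ki] / pmax(co_sampled, 1)
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(m), rownames(m))
    consensus_by_k[[ki]] <- cons
    off <- cons[upper.tri(cons)]
    pac[ki] <- mean(off > pac_lower & off < pac_upper)
  }
  names(pac) <- ks
  best <- ks[which.min(pac)]
  cons <- consensus_by_k[[which.min(pac)]]
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = best)
  names(consensus_by_k) <- ks
  structure(list(consensus = cons, k = best, labels = labels, pac = pac,
                 n_iterations = as.integer(n_iter),
                 resample_fraction = resample,
                 consensus_by_k = consensus_by_k),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf(
    "ConsensusResult: k = %d over %d items (%d iterations, resample %.2f)\n",
    x$k, nrow(x$consensus), x$n_iterations, x$resample_fraction))
  invisible(x)
}

#' Derive per-cluster gene signatures from pseudo-bulk profiles
#'
#' Runs [differential()] in gene mode, one cluster versus the rest, and
#' returns each cluster's significantly upregulated genes as a
#' [gene_set()]. Clusters with fewer than 3 members are skipped.
#'
#' @param pb result of [build_pseudobulk()] (or a groups x genes matrix).
#' @param labels cluster id per pseudo-bulk row.
#' @param prefix signature name prefix (default `"C"`).
#' @return named list of [gene_set()] objects (possibly with empty sets
#'   dropped).
#' @export
derive_subtype_signature <- function(pb, labels, prefix = "C") {
  mat <- if (is.list(pb)) pb$matrix else as.matrix(pb)
  stopifnot(nrow(mat) == length(labels))
  tab <- table(labels)
  if (sum(tab >= 3) < 2) stop("need at least 2 clusters with >= 3 members")
  de <- differential(t(mat), as.character(labels), mode = "gene")
  sets <- list()
  for (g in unique(de$group)) {
    sub <- de[de$group == g & de$significant & de$log2fc > 0, ]
    if (!nrow(sub)) next
    nm <- paste0(prefix, g)
    sets[[nm]] <- gene_set(nm, sub$feature, category = "signature")
  }
  sets
}
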