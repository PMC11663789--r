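#' Correlation screen between two score matrices
#'
#' For every (set in `scores_a`, set in `scores_b`) pair: Pearson and
#' Spearman correlation per tumour (across the units of that tumour),
#' mean Pearson r per dataset, a one-sided t-test that the per-tumour
#' coefficients differ from zero in the direction of their mean, and BH
#' adjustment over pairs (Pearson and Spearman separately, within
#' dataset). A pair is significant when both adjusted p-values are below
#' `alpha` and `|mean r|` exceeds `r_threshold`; with `top_k` set, only
#' the `top_k` pairs by `|mean r|` per (dataset, set_a) are retained among
#' the significant ones.
#'
#' Used with `r_threshold = 0.4` for regulon screens, 0.1 for signature
#' correlations and 0.3 for drug-response covariates.
#'
#' @param scores_a,scores_b [score_matrix()]-like matrices with identical
#'   row sets (units).
#' @param tumour,dataset per-unit tumour and dataset labels.
#' @param r_threshold threshold on `|mean Pearson r|`.
#' @param top_k optional cap per (dataset, set_a).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_tumours minimal usable tumours per pair (default 3).
#' @return data.frame of correlation records (one row per dataset x pair)
#'   with columns `dataset_id`, `set_a`, `set_b`, `n_tumours`,
#'   `mean_pearson_r`, `p_pearson_adj`, `p_spearman_adj`, `significant`.
#' @export
score_correlation <- function(scores_a, scores_b, tumour, dataset,
                              r_threshold = 0.4, top_k = NULL,
                              alpha = 0.05, min_tumours = 3L) {
  stopifnot(nrow(scores_a) == nrow(scores_b),
            nrow(scores_a) == length(tumour),
            length(tumour) == length(dataset))
  rows <- list()
  for (ds in unique(dataset)) {
    units_ds <- which(dataset == ds)
    tums <- unique(tumour[units_ds])
    recs <- list()
    for (a in colnames(scores_a)) for (b in colnames(scores_b)) {
      rp <- rs <- numeric(0)
      for (tm in tums) {
        u <- units_ds[tumour[units_ds] == tm]
        if (length(u) < 3) next
        va <- scores_a[u, a]; vb <- scores_b[u, b]
        if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
          warning("zero-variance score in tumour ", tm, " for pair ",
                  a, "/", b, "; tumour dropped")
          next
        }
        rp <- c(rp, stats::cor(va, vb))
        rs <- c(rs, stats::cor(va, vb, method = "spearman"))
      }
      if (length(rp) < min_tumours) next
      recs[[length(recs) + 1]] <- data.frame(
        dataset_id = ds, set_a = a, set_b = b, n_tumours = length(rp),
        mean_pearson_r = mean(rp),
        p_pearson = one_sided_t_p(rp), p_spearman = one_sided_t_p(rs),
        stringsAsFactors = FALSE)
    }
    if (!length(recs)) next
    df <- do.call(rbind, recs)
    df$p_pearson_adj <- stats::p.adjust(df$p_pearson, "BH")
    df$p_spearman_adj <- stats::p.adjust(df$p_spearman, "BH")
    df$significant <- df$p_pearson_adj < alpha & df$p_spearman_adj < alpha &
      abs(df$mean_pearson_r) > r_threshold
    if (!is.null(top_k)) {
      for (a in unique(df$set_a)) {
        sel <- which(df$set_a == a & df$significant)
        if (length(sel) > top_k) {
          drop <- sel[order(-abs(df$mean_pearson_r[sel]))][-seq_len(top_k)]
          df$significant[drop] <- FALSE
        }
      }
    }
    df$p_pearson <- df$p_spearman <- NULL
    rows[[length(rows) + 1]] <- df
  }
  if (!length(rows))
    return(data.frame(dataset_id = character(), set_a = character(),
                      set_b = character(), n_tumours = integer(),
                      mean_pearson_r = numeric(), p_pearson_adj = numeric(),
                      p_spearman_adj = numeric(), significant = logical()))
  do.call(rbind, rows)
}

#' Co-occurrence network of MMPs across tumours
#'
#' Scores are min-max normalized per MMP within each dataset (raw
#' AUC-type scores rarely exceed 0.5); the per-tumour fraction of cells
#' scoring above `score_threshold` is computed (over the cells of the
#' MMP's own cell type, when `mmp_cell_type` is given), z-scaled within
#' dataset, and Pearson-correlated across tumours for every MMP pair.
#' Only positive correlations with p below `p_cut` become edges;
#' same-cell-type pairs and self-pairs are excluded, and edges are
#' undirected.
#'
#' @param scores cells x MMP score matrix.
#' @param tumour,dataset,cell_type per-cell labels.
#' @param mmp_cell_type optional named vector mapping each MMP column to
#'   its cell type.
#' @param score_threshold per-cell activity cutoff (default 0.5).
#' @param p_cut correlation p-value cutoff (default 1e-5).
#' @param min_tumours minimal tumour count (default 5).
#' @return data.frame of edges: `mmp_a`, `mmp_b`, `pearson_r`, `p_value`.
#' @export
cooccurrence <- function(scores, tumour, dataset, cell_type = NULL,
                         mmp_cell_type = NULL, score_threshold = 0.5,
                         p_cut = 1e-5, min_tumours = 5L) {
  stopifnot(nrow(scores) == length(tumour))
  tums <- sort(unique(tumour))
  if (length(tums) < min_tumours)
    stop("need at least ", min_tumours, " tumours")
  # min-max per MMP within dataset
  norm <- scores
  for (ds in unique(dataset)) {
    u <- dataset == ds
    rng <- apply(scores[u, , drop = FALSE], 2, range)
    span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
    norm[u, ] <- sweep(sweep(scores[u, , drop = FALSE], 2, rng[1, ]),
                       2, span, "/")
  }
  frac <- matrix(NA_real_, length(tums), ncol(scores),
                 dimnames = list(tums, colnames(scores)))
  for (tm in tums) {
    u <- which(tumour == tm)
    for (m in colnames(scores)) {
      um <- u
      if (!is.null(mmp_cell_type) && !is.null(cell_type))
        um <- u[cell_type[u] == mmp_cell_type[[m]]]
      if (length(um))
        frac[tm, m] <- mean(norm[um, m] > score_threshold)
    }
  }
  tum_ds <- vapply(tums, function(tm)
    as.character(dataset[tumour == tm][1]), character(1))
  for (ds in unique(tum_ds)) {
    r <- tum_ds == ds
    frac[r, ] <- scale(frac[r, , drop = FALSE])
  }
  keep <- apply(frac, 2, function(v) sum(is.finite(v)) >= min_tumours &&
                  stats::sd(v, na.rm = TRUE) > 0)
  if (any(!keep))
    warning("MMPs with zero variance across tumours excluded: ",
            paste(colnames(frac)[!keep], collapse = ", "))
  frac <- frac[, keep, drop = FALSE]
  mm <- colnames(frac)
  edges <- list()
  for (i in seq_along(mm)) for (j in seq_along(mm)) {
    if (j <= i) next
    if (!is.null(mmp_cell_type) &&
        identical(mmp_cell_type[[mm[i]]], mmp_cell_type[[mm[j]]])) next
    ok <- is.finite(frac[, i]) & is.finite(frac[, j])
    if (sum(ok) < min_tumours) next
    ct <- stats::cor.test(frac[ok, i], frac[ok, j])
    if (ct$estimate > 0 && ct$p.value < p_cut)
      edges[[length(edges) + 1]] <- data.frame(
        mmp_a = mm[i], mmp_b = mm[j], pearson_r = unname(ct$estimate),
        p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(data.frame(mmp_a = character(), mmp_b = character(),
                      pearson_r = numeric(), p_value = numeric()))
  do.call(rbind, edges)
}

#' Proportion of variance in a pathway score explained by a clinical metric
#'
#' Fits `score ~ metric` by least squares (categorical metrics enter as
#' factors) and reports the adjusted R-squared as the PVE together with
#' the F-test p-value.
#'
#' @param score numeric vector of per-individual pathway scores.
#' @param metric numeric or categorical covariate of the same length.
#' @return list with `pve` and `p`.
#' @export
pve <- function(score, metric) {
  stopifnot(length(score) == length(metric))
  ok <- is.finite(score) & !is.na(metric)
  score <- score[ok]; metric <- metric[ok]
  if (length(score) < 5) stop("need at least 5 individuals")
  if (length(unique(metric)) < 2) stop("constant metric")
  if (!is.numeric(metric)) metric <- factor(metric)
  fit <- stats::lm(score ~ metric)
  a <- stats::anova(fit)
  list(pve = summary(fit)$adj.r.squared, p = a[["Pr(>F)"]][1])
}

#' PVE screen over several metrics with BH adjustment
#'
#' @param score numeric vector of per-individual scores.
#' @param metrics data.frame of covariates (columns = metrics).
#' @return data.frame: `metric`, `pve`, `p`, `p_adj`; constant metrics are
#'   skipped.
#' @export
pve_screen <- function(score, metrics) {
  rows <- list()
  for (m in names(metrics)) {
    v <- metrics[[m]]
    if (length(unique(v[!is.na(v)])) < 2) next
    r <- pve(score, v)
    rows[[length(rows) + 1]] <- data.frame(metric = m, pve = r$pve, p = r$p,
                                           stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(metric = character(), pve = numeric(),
                                       p = numeric(), p_adj = numeric()))
  df <- do.call(rbind, rows)
  df$p_adj <- stats::p.adjust(df$p, "BH")
  df
}

#' Spearman correlation of two log2 fold-change vectors
#'
#' Computed over the genes present with finite values in both vectors;
#' errors below 10 shared genes.
#'
#' @param fc_a,fc_b named numeric vectors of per-gene log2 fold changes.
#' @return the Spearman correlation coefficient.
#' @export
fc_correlation <- function(fc_a, fc_b) {
  shared <- intersect(names(fc_a), names(fc_b))
  a <- fc_a[shared]; b <- fc_b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) stop("fewer than 10 shared genes with finite values")
  stats::cor(a[ok], b[ok], method = "spearman")
}
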