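# Non-negative matrix factorization with deterministic NNDSVD
# initialization and multiplicative Frobenius updates. Deterministic given
# the input, so results are reproducible per (sample, K) without relying on
# random restarts.

nndsvd_init <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      mp <- nup * nvp; mn <- nun * nvn
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(sv$d[j] * mp) / nup * up
        H[j, ] <- sqrt(sv$d[j] * mp) / nvp * vp
      } else if (mn > 0) {
        W[, j] <- sqrt(sv$d[j] * mn) / nun * un
        H[j, ] <- sqrt(sv$d[j] * mn) / nvn * vn
      }
    }
  }
  # 'nndsvda' variant: replace zeros with the matrix mean so multiplicative
  # updates are not frozen at zero
  a <- mean(A)
  W[W <= 0] <- a
  H[H <= 0] <- a
  list(W = W, H = H)
}

nmf_fit <- function(A, k, max_iter = 500L, tol = 1e-4) {
  stopifnot(all(A >= 0), k >= 1, k < min(dim(A)))
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  eps <- 1e-10
  prev_loss <- Inf
  converged <- FALSE
  # HALS coordinate descent: each factor column updated in closed form
  for (it in seq_len(max_iter)) {
    HHt <- tcrossprod(H); AHt <- A %*% t(H)
    for (j in seq_len(k)) {
      num <- AHt[, j] - W %*% HHt[, j] + W[, j] * HHt[j, j]
      W[, j] <- pmax(num / max(HHt[j, j], eps), 0)
    }
    WtW <- crossprod(W); WtA <- crossprod(W, A)
    for (j in seq_len(k)) {
      num <- WtA[j, ] - WtW[j, ] %*% H + WtW[j, j] * H[j, ]
      H[j, ] <- pmax(num / max(WtW[j, j], eps), 0)
    }
    if (it %% 10 == 0 || it == max_iter) {
      loss <- norm(A - W %*% H, "F")
      if (is.finite(prev_loss) &&
          abs(prev_loss - loss) <= tol * max(prev_loss, eps)) {
        converged <- TRUE
        break
      }
      prev_loss <- loss
    }
  }
  list(W = W, H = H, converged = converged)
}

#' Per-sample NMF expression programs
#'
#' Runs one NMF decomposition per rank in `k_values` on each sample's
#' non-negative (scaled, clipped) metabolic expression matrix and
#' summarizes every factor by its top `top_genes` coefficient genes. With
#' the default rank schedule 4:9 each sample yields
#' `sum(4:9) = 39` programs. Samples with fewer than `min_cells` cells are
#' skipped (with a message); non-converged factorizations are flagged but
#' their factors still emitted.
#'
#' @param mats named list of non-negative matrices (genes x cells), one
#'   per sample, e.g. the output of [scale_and_clip()].
#' @param k_values NMF ranks (default 4:9).
#' @param seed kept for interface stability; the solver is deterministic.
#' @param min_cells per-sample cell threshold (default 20).
#' @param top_genes genes summarizing each factor (default 30).
#' @param cancer_types optional named vector (sample id -> cancer type)
#'   attached to each program for downstream abundance assessment.
#' @param max_iter,tol solver controls.
#' @return list of `NMFProgram` records: `id`, `sample_id`, `k`,
#'   `factor_index`, `genes` (ordered by coefficient, decreasing),
#'   `coefficients`, `converged`, `cancer_type`.
#' @export
nmf_programs <- function(mats, k_values = 4:9, seed = 1L, min_cells = 20L,
                         top_genes = 30L, cancer_types = NULL,
                         max_iter = 500L, tol = 1e-4) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  programs <- list()
  for (sid in names(mats)) {
    A <- as.matrix(mats[[sid]])
    if (ncol(A) < min_cells) {
      message("sample ", sid, " has ", ncol(A), " cells (< ", min_cells,
              "); skipped")
      next
    }
    if (nrow(A) < top_genes) stop("sample ", sid, " has fewer than ",
                                  top_genes, " genes")
    if (is.null(rownames(A))) stop("matrices must carry gene rownames")
    for (k in k_values) {
      fit <- nmf_fit(A, k, max_iter = max_iter, tol = tol)
      for (f in seq_len(k)) {
        coefs <- fit$W[, f]
        ord <- order(-coefs, rownames(A))[seq_len(top_genes)]
        programs[[length(programs) + 1]] <- structure(list(
          id = sprintf("%s.K%d.F%d", sid, k, f),
          sample_id = sid, k = as.integer(k), factor_index = as.integer(f),
          genes = rownames(A)[ord],
          coefficients = unname(coefs[ord]),
          converged = fit$converged,
          cancer_type = if (!is.null(cancer_types))
            unname(cancer_types[sid]) else NA_character_),
          class = "NMFProgram")
      }
    }
  }
  names(programs) <- vapply(programs, `[[`, character(1), "id")
  programs
}

# overlap (shared gene count) between two programs' gene lists
overlap_matrix <- function(gene_lists) {
  n <- length(gene_lists)
  O <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    O[i, j] <- O[j, i] <- length(intersect(gene_lists[[i]], gene_lists[[j]]))
  }
  O
}

#' Filter NMF programs to the robust set
#'
#' Three criteria, applied in order:
#' 1. within-sample robustness: at least `within_overlap` (70%) gene
#'    overlap with a program of a *different* rank from the same sample
#'    (inclusive, i.e. >= 21/30 genes);
#' 2. cross-tumour robustness: at least `cross_overlap` (20%) gene overlap
#'    with a program from another tumour (>= 6/30);
#' 3. within-tumour non-redundancy: programs surviving 1-2 are sorted in
#'    descending order of their maximal cross-tumour overlap, selected top
#'    down, and any unselected program sharing *more than*
#'    `redundancy_overlap` (20%, i.e. >= 7/30) genes with an
#'    already-selected same-tumour program is dropped.
#'
#' "At least" thresholds are inclusive and "more than" strict, matching
#' the distinct phrasings of the published rules.
#'
#' @param programs list of `NMFProgram`s from [nmf_programs()].
#' @param within_overlap,cross_overlap,redundancy_overlap fractional
#'   thresholds (of the 30-gene program size).
#' @return the surviving programs, in input order.
#' @export
robust_filter <- function(programs, within_overlap = 0.7,
                          cross_overlap = 0.2, redundancy_overlap = 0.2) {
  if (!length(programs)) return(programs)
  genes <- lapply(programs, `[[`, "genes")
  size <- length(genes[[1]])
  samp <- vapply(programs, `[[`, character(1), "sample_id")
  kval <- vapply(programs, `[[`, integer(1), "k")
  O <- overlap_matrix(genes)
  thr_within <- ceiling(within_overlap * size)
  thr_cross <- ceiling(cross_overlap * size)

  same_sample <- outer(samp, samp, "==")
  diff_k <- outer(kval, kval, "!=")
  crit1 <- vapply(seq_along(programs), function(i)
    any(O[i, ] >= thr_within & same_sample[i, ] & diff_k[i, ]), logical(1))
  crit2 <- vapply(seq_along(programs), function(i)
    any(O[i, ] >= thr_cross & !same_sample[i, ]), logical(1))
  pass12 <- which(crit1 & crit2)
  if (!length(pass12)) return(programs[0])

  # criterion 3 among survivors, per tumour
  max_cross <- vapply(pass12, function(i) {
    others <- pass12[samp[pass12] != samp[i]]
    if (!length(others)) 0L else max(O[i, others])
  }, integer(1))
  ids <- names(programs)[pass12]
  ord <- pass12[order(-max_cross, ids)]
  selected <- integer(0)
  for (i in ord) {
    same <- selected[samp[selected] == samp[i]]
    if (length(same) && any(O[i, same] > redundancy_overlap * size)) next
    selected <- c(selected, i)
  }
  programs[sort(selected)]
}

# recompute an MMP's 30-gene list as the genes occurring in most member
# programs; ties broken by higher summed coefficient rank (a gene ranked
# first in a member contributes `size`, last contributes 1), then by
# lexicographic symbol order
mmp_consensus_genes <- function(members, size = 30L) {
  all_genes <- unlist(lapply(members, `[[`, "genes"))
  occ <- table(all_genes)
  weight <- numeric(length(occ))
  names(weight) <- names(occ)
  for (m in members) {
    w <- rev(seq_along(m$genes))
    weight[m$genes] <- weight[m$genes] + w
  }
  g <- names(occ)
  ord <- order(-as.integer(occ), -weight[g], g)
  g[ord][seq_len(min(size, length(g)))]
}

#' Cluster robust programs into metabolic meta-programs
#'
#' Greedy founder-extension clustering: programs are sorted in descending
#' order by their number of "similar" programs (other-tumour programs with
#' more than `min_overlap` gene overlap); the top program founds a cluster
#' whose MMP gene list starts as its 30 genes; the unclustered program
#' with the highest overlap with the current MMP list is added repeatedly,
#' the list being recomputed each time as the 30 genes with the most
#' occurrences across members; extension stops when no remaining program
#' overlaps the list by more than `min_overlap`. New founders are
#' attempted while some candidate still has at least `min_similar` similar
#' programs; clusters with fewer than `min_members` members are discarded
#' at the end.
#'
#' @param robust list of robust `NMFProgram`s ([robust_filter()] output).
#' @param min_overlap fractional overlap threshold (default 0.2, strict).
#' @param min_members minimal cluster size kept (default 10).
#' @param min_similar minimal similar-program count to found a cluster
#'   (default 5).
#' @return list of `MMP` objects (`mmp_id`, `genes`, `members`,
#'   `member_programs`, `tumours`, `annotation`), with the unclustered
#'   programs in attribute `"unassigned"`.
#' @export
cluster_mmps <- function(robust, min_overlap = 0.2, min_members = 10L,
                         min_similar = 5L) {
  if (!length(robust)) return(structure(list(), unassigned = robust))
  genes <- lapply(robust, `[[`, "genes")
  size <- length(genes[[1]])
  thr <- min_overlap * size  # "more than 20%": strict
  samp <- vapply(robust, `[[`, character(1), "sample_id")
  ids <- names(robust)
  O <- overlap_matrix(genes)
  other <- outer(samp, samp, "!=")

  remaining <- seq_along(robust)
  clusters <- list()
  repeat {
    if (!length(remaining)) break
    n_similar <- vapply(remaining, function(i) {
      js <- remaining[other[i, remaining]]
      sum(O[i, js] > thr)
    }, integer(1))
    if (max(n_similar) < min_similar) break
    # founder tie-break: earliest sample id, then id (k, factor index)
    cand <- remaining[n_similar == max(n_similar)]
    founder <- cand[order(samp[cand], ids[cand])][1]
    members <- founder
    mmp_genes <- genes[[founder]]
    pool <- setdiff(remaining, founder)
    while (length(pool)) {
      ov <- vapply(pool, function(i)
        length(intersect(genes[[i]], mmp_genes)), integer(1))
      if (max(ov) <= thr) break
      nxt <- pool[ov == max(ov)]
      nxt <- nxt[order(samp[nxt], ids[nxt])][1]
      members <- c(members, nxt)
      mmp_genes <- mmp_consensus_genes(robust[members], size = size)
      pool <- setdiff(pool, nxt)
    }
    clusters[[length(clusters) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  keep <- clusters[vapply(clusters, length, integer(1)) >= min_members]
  mmps <- lapply(seq_along(keep), function(ci) {
    members <- keep[[ci]]
    structure(list(
      mmp_id = sprintf("MMP%d", ci),
      genes = mmp_consensus_genes(robust[members]),
      members = ids[members],
      member_programs = robust[members],
      tumours = unique(samp[members]),
      annotation = NULL), class = "MMP")
  })
  names(mmps) <- vapply(mmps, `[[`, character(1), "mmp_id")
  structure(mmps,
            unassigned = robust[setdiff(seq_along(robust),
                                        unlist(keep))])
}

#' @export
print.MMP <- function(x, ...) {
  cat(sprintf("%s: %d member programs over %d tumours%s\n", x$mmp_id,
              length(x$members), length(x$tumours),
              if (!is.null(x$annotation))
                paste0(" [", x$annotation$pathway, "]") else ""))
  invisible(x)
}

#' Annotate an MMP by pathway enrichment
#'
#' Hypergeometric over-representation of the 30 MMP genes in each pathway
#' against the metabolic gene universe, BH adjusted; the top pathway with
#' adjusted p < `alpha` becomes the annotation, otherwise
#' `"unannotated"`.
#'
#' @param m an `MMP`.
#' @param pathways list of [gene_set()] objects.
#' @param background character vector, the metabolic gene universe (must
#'   contain all MMP genes).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the MMP with `annotation` set
#'   (`list(pathway, p_adj)`; pathway `"unannotated"` if nothing passes).
#' @export
annotate_mmp <- function(m, pathways, background, alpha = 0.05) {
  pathways <- as_gene_set_list(pathways)
  if (!length(pathways)) stop("empty pathway collection")
  if (!all(m$genes %in% background))
    stop("background must contain all MMP genes")
  N <- length(unique(background))
  k <- length(m$genes)
  p <- vapply(pathways, function(pw) {
    pw_bg <- intersect(pw$genes, background)
    ov <- length(intersect(m$genes, pw_bg))
    stats::phyper(ov - 1, length(pw_bg), N - length(pw_bg), k,
                  lower.tail = FALSE)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, "BH")
  best <- order(p_adj, names(pathways))[1]
  m$annotation <- if (p_adj[best] < alpha)
    list(pathway = names(pathways)[best], p_adj = unname(p_adj[best]))
  else list(pathway = "unannotated", p_adj = unname(p_adj[best]))
  m
}

#' MMP abundance per cancer type
#'
#' For each (MMP, cancer type): `observed` is the number of member
#' programs from that cancer type; `expected = N_MMP * N_cancer /
#' N_robust`; `abundance = log2((observed + 1) / (expected + 1))`; the
#' hypergeometric upper-tail p (drawing a cancer type's robust programs
#' from the pooled robust set) is Bonferroni-corrected over all pairs.
#' Categories are assigned in order: high (`observed > 10` or
#' `abundance > 1`; `high_significant` when additionally the adjusted p
#' < 0.05), medium (`2 <= observed <= 10` or `0 < abundance <= 1`), low
#' (`observed == 1` and `-1.5 < abundance <= 0`), else absent.
#'
#' @param mmps list of `MMP` objects.
#' @param program_cancer_types named character vector mapping every robust
#'   program id to its cancer type.
#' @return data.frame of abundance records.
#' @export
abundance <- function(mmps, program_cancer_types) {
  n_robust <- length(program_cancer_types)
  if (n_robust == 0) stop("N_robust = 0")
  cancers <- sort(unique(program_cancer_types))
  n_cancer <- table(program_cancer_types)
  n_pairs <- length(mmps) * length(cancers)
  rows <- list()
  for (m in mmps) {
    n_mmp <- length(m$members)
    member_ct <- program_cancer_types[m$members]
    for (ct in cancers) {
      obs <- sum(member_ct == ct)
      nc <- as.integer(n_cancer[[ct]])
      expd <- n_mmp * nc / n_robust
      ab <- log2((obs + 1) / (expd + 1))
      p <- stats::phyper(obs - 1, n_mmp, n_robust - n_mmp, nc,
                         lower.tail = FALSE)
      p_bonf <- min(1, p * n_pairs)
      category <- if (obs > 10 || ab > 1) {
        if (p_bonf < 0.05) "high_significant" else "high"
      } else if ((obs >= 2 && obs <= 10) || (ab > 0 && ab <= 1)) {
        "medium"
      } else if (obs == 1 && ab > -1.5 && ab <= 0) {
        "low"
      } else "absent"
      rows[[length(rows) + 1]] <- data.frame(
        cancer_type = ct, mmp_id = m$mmp_id, observed = obs,
        expected = expd, abundance = ab, p_bonferroni = p_bonf,
        category = category, n_mmp_total = n_mmp, n_cancer_total = nc,
        n_robust_total = n_robust, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Jaccard similarity between robust programs
#'
#' @param robust list of `NMFProgram`s.
#' @return symmetric matrix of Jaccard indices of the 30-gene lists.
#' @export
program_jaccard <- function(robust) {
  genes <- lapply(robust, `[[`, "genes")
  n <- length(genes)
  J <- matrix(1, n, n, dimnames = list(names(robust), names(robust)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ov <- length(intersect(genes[[i]], genes[[j]]))
    J[i, j] <- J[j, i] <- ov / (length(genes[[i]]) + length(genes[[j]]) - ov)
  }
  J
}

#' End-to-end MMP discovery from a CellExpression
#'
#' Convenience wrapper chaining the per-sample preprocessing
#' ([lognormalize()], [select_metabolic()], [scale_and_clip()]) with
#' [nmf_programs()], [robust_filter()] and [cluster_mmps()] for one cell
#' type of the tumour samples.
#'
#' @param x CellExpression.
#' @param metabolic_genes [gene_set()] or character vector.
#' @param cell_type cell type analysed (default `"malignant"`; matched
#'   against the `malignancy` column when `use_malignancy` is TRUE,
#'   otherwise `cell_type`).
#' @param use_malignancy select cells by the `malignancy` metadata column.
#' @param k_values,seed,min_cells,top_n_genes,max_iter,tol passed through.
#' @param pathways optional pathway collection for annotation.
#' @return list: `programs`, `robust`, `mmps`, `abundance` (NULL unless
#'   cancer types present), `jaccard`.
#' @export
discover_mmps <- function(x, metabolic_genes, cell_type = "malignant",
                          use_malignancy = FALSE, k_values = 4:9, seed = 1L,
                          min_cells = 20L, top_n_genes = 500L,
                          max_iter = 500L, tol = 1e-4, pathways = NULL) {
  stopifnot(inherits(x, "CellExpression"))
  meta <- x$cell_meta
  sel <- meta$tissue == "tumour" &
    (if (use_malignancy) meta$malignancy == "malignant"
     else meta$cell_type == cell_type)
  if (!any(sel)) stop("no cells of the requested type in tumour samples")
  sub <- subset_cells(x, cells = sel)
  samples <- sort(unique(sub$cell_meta$sample_id))
  mats <- list()
  for (sid in samples) {
    cells <- sub$cell_meta$sample_id == sid
    if (sum(cells) < min_cells) {
      message("sample ", sid, " has ", sum(cells), " cells (< ", min_cells,
              "); excluded")
      next
    }
    s <- subset_cells(sub, cells = cells)
    norm <- lognormalize(s)
    red <- select_metabolic(norm, metabolic_genes, top_n = top_n_genes)
    mats[[sid]] <- scale_and_clip(red)
  }
  if (!length(mats)) stop("no sample passed the cell threshold")
  ct_map <- vapply(names(mats), function(sid) {
    unique(sub$cell_meta$cancer_type[sub$cell_meta$sample_id == sid])[1]
  }, character(1))
  programs <- nmf_programs(mats, k_values = k_values, seed = seed,
                           min_cells = min_cells, cancer_types = ct_map,
                           max_iter = max_iter, tol = tol)
  robust <- robust_filter(programs)
  mmps <- cluster_mmps(robust)
  metab_universe <- if (inherits(metabolic_genes, "GeneSet"))
    metabolic_genes$genes else as.character(metabolic_genes)
  if (!is.null(pathways) && length(mmps))
    mmps[] <- lapply(mmps, annotate_mmp, pathways = pathways,
                     background = metab_universe)
  ab <- NULL
  if (length(mmps) && length(robust) && !anyNA(
        vapply(robust, `[[`, character(1), "cancer_type"))) {
    pct <- vapply(robust, `[[`, character(1), "cancer_type")
    ab <- abundance(mmps, pct)
  }
  list(programs = programs, robust = robust, mmps = mmps, abundance = ab,
       jaccard = if (length(robust)) program_jaccard(robust) else NULL)
}
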