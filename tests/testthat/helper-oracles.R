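# Independent brute-force oracles. These re-implement the stated rules
# from first principles (loops, enumeration, exact tail sums) and are kept
# deliberately separate from the package's vectorized/greedy code paths.

# recovery-curve AUC by exhaustive enumeration: walk the ranking position
# by position, record the cumulative number of set genes recovered, and
# normalize by the best achievable curve
brute_aucell <- function(expr, tie_perm, set_genes, top_fraction) {
  G <- length(expr)
  w <- ceiling(top_fraction * G)
  ord <- order(-expr, tie_perm)
  ranked_genes <- names(expr)[ord]
  rec <- numeric(w)
  hits <- 0
  for (r in seq_len(w)) {
    if (ranked_genes[r] %in% set_genes) hits <- hits + 1
    rec[r] <- hits
  }
  s <- min(sum(names(expr) %in% set_genes), w)
  if (s == 0) return(0)
  best <- pmin(seq_len(w), s)
  sum(rec) / sum(best)
}

# exact hypergeometric upper tail P(X >= q) by direct summation of the
# probability mass (choose-based, no phyper)
brute_hyper_upper <- function(q, n_white, n_black, n_draw) {
  hi <- min(n_white, n_draw)
  if (q > hi) return(0)
  tot <- choose(n_white + n_black, n_draw)
  sum(vapply(q:hi, function(i)
    choose(n_white, i) * choose(n_black, n_draw - i), numeric(1))) / tot
}

# robust-program filter re-implemented rule by rule with explicit loops
brute_robust_filter <- function(programs, within = 0.7, cross = 0.2,
                                redundancy = 0.2) {
  n <- length(programs)
  if (n == 0) return(programs)
  size <- length(programs[[1]]$genes)
  ov <- function(i, j)
    length(intersect(programs[[i]]$genes, programs[[j]]$genes))
  p1 <- logical(n); p2 <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- programs[[i]]$sample_id == programs[[j]]$sample_id
      if (same && programs[[i]]$k != programs[[j]]$k &&
          ov(i, j) / size >= within) p1[i] <- TRUE
      if (!same && ov(i, j) / size >= cross) p2[i] <- TRUE
    }
  }
  surv <- which(p1 & p2)
  if (!length(surv)) return(programs[0])
  maxcross <- vapply(surv, function(i) {
    best <- 0
    for (j in surv)
      if (programs[[j]]$sample_id != programs[[i]]$sample_id)
        best <- max(best, ov(i, j))
    best
  }, numeric(1))
  ids <- names(programs)[surv]
  order_idx <- surv[order(-maxcross, ids)]
  chosen <- integer(0)
  for (i in order_idx) {
    clash <- FALSE
    for (j in chosen)
      if (programs[[j]]$sample_id == programs[[i]]$sample_id &&
          ov(i, j) / size > redundancy) clash <- TRUE
    if (!clash) chosen <- c(chosen, i)
  }
  programs[sort(chosen)]
}

# abundance records recomputed from the printed formulas with direct
# arithmetic and the explicit category decision ladder
brute_abundance <- function(mmps, program_cancer_types) {
  n_robust <- length(program_cancer_types)
  cancers <- sort(unique(program_cancer_types))
  n_pairs <- length(mmps) * length(cancers)
  out <- list()
  for (m in mmps) for (ct in cancers) {
    obs <- 0
    for (id in m$members) if (program_cancer_types[[id]] == ct) obs <- obs + 1
    n_mmp <- length(m$members)
    nc <- sum(program_cancer_types == ct)
    expd <- n_mmp * nc / n_robust
    ab <- log2((obs + 1) / (expd + 1))
    p <- brute_hyper_upper(obs, n_mmp, n_robust - n_mmp, nc)
    p_bonf <- min(1, p * n_pairs)
    cat_ <- "absent"
    if (obs > 10 || ab > 1) {
      cat_ <- if (p_bonf < 0.05) "high_significant" else "high"
    } else if ((obs >= 2 && obs <= 10) || (ab > 0 && ab <= 1)) {
      cat_ <- "medium"
    } else if (obs == 1 && ab > -1.5 && ab <= 0) {
      cat_ <- "low"
    }
    out[[length(out) + 1]] <- data.frame(
      cancer_type = ct, mmp_id = m$mmp_id, observed = obs, expected = expd,
      abundance = ab, p_bonferroni = p_bonf, category = cat_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random small program instances for the filter/abundance property checks
random_program_instance <- function(seed, n_programs = NULL) {
  set.seed(seed)
  if (is.null(n_programs)) n_programs <- sample(5:30, 1)
  gene_pool <- sprintf("g%03d", 1:60)  # small pool forces overlaps
  samples <- sprintf("S%d", 1:sample(2:5, 1))
  progs <- vector("list", n_programs)
  for (i in seq_len(n_programs)) {
    sid <- sample(samples, 1)
    progs[[i]] <- structure(list(
      id = sprintf("p%02d", i), sample_id = sid,
      k = sample(4:9, 1), factor_index = sample(1:9, 1),
      genes = sample(gene_pool, 30),
      coefficients = sort(stats::runif(30), decreasing = TRUE),
      converged = TRUE,
      cancer_type = sample(c("CT1", "CT2", "CT3"), 1)),
      class = "NMFProgram")
  }
  names(progs) <- vapply(progs, `[[`, character(1), "id")
  progs
}

# mid-rank ("textbook", tie-corrected) Spearman via Pearson on average
# ranks, computed with an explicit rank assignment loop
brute_spearman <- function(a, b) {
  midrank <- function(v) {
    sv <- sort(v)
    vapply(v, function(x) mean(which(sv == x)), numeric(1))
  }
  ra <- midrank(a); rb <- midrank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
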