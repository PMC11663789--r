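# internal statistical helpers

# expm1 on a sparse matrix without densifying
expm1_sparse <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
    x@x <- expm1(x@x)
    x
  } else expm1(x)
}

# Wilcoxon rank-sum p-values for every row of `m`, group 1 columns `idx1`
# vs group 2 columns `idx2`. Normal approximation with tie correction and
# continuity correction (the regime this pipeline runs in has dozens to
# hundreds of cells per group).
wilcox_rows <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  sub <- as.matrix(m[, c(idx1, idx2), drop = FALSE])
  apply(sub, 1, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tt <- table(v)
    tie_adj <- sum(tt^3 - tt)
    s2 <- n1 * n2 / 12 * ((N + 1) - tie_adj / (N * (N - 1)))
    if (s2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(s2)
    2 * stats::pnorm(-abs(z))
  })
}

# mean of a one-sided t-test that values differ from 0 in the direction of
# their mean; returns 1 when degenerate
one_sided_t_p <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 2 || stats::sd(v) == 0) {
    if (n >= 1 && all(v != 0) && length(unique(sign(v))) == 1) return(0)
    return(1)
  }
  tstat <- mean(v) / (stats::sd(v) / sqrt(n))
  if (mean(v) >= 0) stats::pt(tstat, n - 1, lower.tail = FALSE)
  else stats::pt(tstat, n - 1, lower.tail = TRUE)
}

# rank-based AUC of scores for a binary truth vector
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
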