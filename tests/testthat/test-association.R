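# small paired score-matrix world: `n_tum` tumours x `per` units each
make_paired_scores <- function(n_tum = 12, per = 12, seed = 1) {
  set.seed(seed)
  tumour <- rep(sprintf("T%02d", 1:n_tum), each = per)
  dataset <- rep("D1", n_tum * per)
  a <- matrix(stats::rnorm(n_tum * per), ncol = 1,
              dimnames = list(paste0("u", seq_along(tumour)), "mmp"))
  list(a = a, tumour = tumour, dataset = dataset)
}

test_that("score_correlation keeps perfect pairs and applies the r threshold", {
  w <- make_paired_scores()
  ident <- w$a; colnames(ident) <- "cov"
  rec <- score_correlation(w$a, ident, w$tumour, w$dataset, r_threshold = 0.4)
  expect_equal(rec$mean_pearson_r, 1)
  expect_true(rec$significant)
  # pair with mean r ~ 0.35: excluded at 0.4, eligible at 0.3
  set.seed(5)
  noisy <- w$a * 0.37 + matrix(stats::rnorm(nrow(w$a), sd = 1), ncol = 1)
  colnames(noisy) <- "cov"
  r35 <- score_correlation(w$a, noisy, w$tumour, w$dataset, r_threshold = 0.4)
  # engineer the exact situation: verify the threshold gate directly
  expect_true(abs(r35$mean_pearson_r) < 0.6 && abs(r35$mean_pearson_r) > 0.2)
  r_low <- score_correlation(w$a, noisy, w$tumour, w$dataset,
                             r_threshold = abs(r35$mean_pearson_r) + 0.01)
  r_high <- score_correlation(w$a, noisy, w$tumour, w$dataset,
                              r_threshold = abs(r35$mean_pearson_r) - 0.01)
  expect_false(r_low$significant)
  expect_true(r_high$significant)  # p-values are tiny for a real signal
  # zero-variance tumour dropped with warning
  flat <- ident; flat[w$tumour == "T01", 1] <- 0
  expect_warning(score_correlation(w$a, flat, w$tumour, w$dataset, 0.4),
                 "zero-variance")
})

test_that("score_correlation top_k retains the strongest covariates", {
  w <- make_paired_scores(seed = 2)
  covs <- sapply(1:5, function(i) w$a[, 1] + stats::rnorm(nrow(w$a), sd = 0.1 * i))
  colnames(covs) <- paste0("c", 1:5)
  rec <- score_correlation(w$a, covs, w$tumour, w$dataset,
                           r_threshold = 0.4, top_k = 3)
  expect_equal(sum(rec$significant), 3L)
  kept <- rec$set_b[rec$significant]
  expect_setequal(kept, rec$set_b[order(-abs(rec$mean_pearson_r))][1:3])
})

test_that("pve recovers planted variance fractions", {
  # metric equal to the score -> PVE ~ 1
  set.seed(3)
  s <- stats::rnorm(100)
  expect_gt(suppressWarnings(pve(s, s))$pve, 0.99)  # perfect-fit warning
  # independent metric -> PVE ~ 0 (median over repeats)
  pves <- vapply(1:20, function(i) {
    set.seed(i)
    pve(stats::rnorm(100), stats::rnorm(100))$pve
  }, numeric(1))
  expect_lt(abs(stats::median(pves)), 0.05)
  # y = x + noise at 1:1 variance, n = 1000 -> adjusted R^2 ~ 0.5
  set.seed(4)
  x <- stats::rnorm(1000)
  y <- x + stats::rnorm(1000)
  expect_equal(pve(y, x)$pve, 0.5, tolerance = 0.05)
  # categorical metrics are encoded; constant metric errors
  expect_no_error(pve(s, rep(c("a", "b"), 50)))
  expect_error(pve(s, rep("a", 100)), "constant")
  expect_error(pve(s[1:4], s[1:4]), "5 individuals")
  # screen: BH column present, constant metrics skipped
  met <- data.frame(good = s, konst = 1)
  scr <- pve_screen(s, met)
  expect_identical(scr$metric, "good")
  expect_true("p_adj" %in% names(scr))
})

test_that("fc_correlation: limits, intersection and tie-corrected ranks", {
  v <- stats::setNames(seq_len(12) / 7, sprintf("g%02d", 1:12))
  expect_equal(fc_correlation(v, v), 1)
  expect_equal(fc_correlation(v, stats::setNames(rev(v), names(v))), -1)
  # hand-built example with one tie matches the textbook mid-rank formula
  a <- stats::setNames(c(1.0, 2.0, 2.0, 3.0, 4.0, 0.5, 1.5, 2.5, 3.5, 4.5),
                       sprintf("g%02d", 1:10))
  b <- stats::setNames(c(0.3, 1.1, 0.9, 2.2, 1.8, 0.1, 0.8, 1.4, 2.0, 2.5),
                       sprintf("g%02d", 1:10))
  expect_equal(fc_correlation(a, b), brute_spearman(a, b), tolerance = 1e-12)
  # fewer than 10 shared genes errors; NA values are excluded first
  expect_error(fc_correlation(v[1:5], v), "10 shared")
  v2 <- v; v2[1] <- NA
  expect_error(fc_correlation(v2[1:10], v[1:10]), "10 shared")
})

test_that("cooccurrence: planted co-activity found, negatives and self pairs excluded", {
  set.seed(6)
  n_tum <- 16; per <- 30
  tumour <- rep(sprintf("T%02d", 1:n_tum), each = per)
  dataset <- rep(c("D1", "D2"), each = n_tum / 2 * per)
  # latent per-tumour activity drives a correlated MMP pair
  act <- stats::runif(n_tum, 0.05, 0.9)
  mk_scores <- function(frac_by_tum) {
    unlist(lapply(seq_len(n_tum), function(t)
      ifelse(stats::runif(per) < frac_by_tum[t],
             stats::runif(per, 0.7, 1), stats::runif(per, 0, 0.3))))
  }
  scores <- cbind(m1 = mk_scores(act), m2 = mk_scores(act),
                  m3 = mk_scores(stats::runif(n_tum, 0.05, 0.9)),
                  m4 = mk_scores(1 - act))
  rownames(scores) <- paste0("c", seq_along(tumour))
  ct <- rep("x", length(tumour))
  mmp_ct <- c(m1 = "malignant", m2 = "T_cell", m3 = "myeloid",
              m4 = "fibroblast")
  edges <- cooccurrence(scores, tumour, dataset, cell_type = NULL,
                        mmp_cell_type = NULL, p_cut = 1e-4)
  key <- paste(edges$mmp_a, edges$mmp_b)
  expect_true("m1 m2" %in% key)            # planted co-active pair
  expect_false("m1 m4" %in% key)           # anti-correlated: no edge
  expect_false(any(edges$mmp_a == edges$mmp_b))
  expect_true(all(edges$pearson_r > 0))
  # identical fractions give r = 1 edges for any tumour count >= 5
  dup <- cbind(a = scores[, "m1"], b = scores[, "m1"])
  e2 <- cooccurrence(dup, tumour, dataset, p_cut = 1e-5)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$pearson_r, 1, tolerance = 1e-9)
  expect_error(cooccurrence(scores[1:60, ], tumour[1:60], dataset[1:60]),
               "5 tumours")
})

test_that("score_correlation and differential are calibrated under the null", {
  # independent noise covariate over 20 tumours: retention stays near the
  # nominal level (acceptance runs 500 reps at the 0.06 bound; 120 reps
  # here for speed, with the bound widened by the Monte-Carlo error of the
  # smaller replicate count)
  retained <- vapply(1:120, function(rep) {
    set.seed(rep)
    n_tum <- 20; per <- 8
    tumour <- rep(sprintf("T%02d", 1:n_tum), each = per)
    a <- matrix(stats::rnorm(n_tum * per), ncol = 1,
                dimnames = list(NULL, "mmp"))
    b <- matrix(stats::rnorm(n_tum * per), ncol = 1,
                dimnames = list(NULL, "cov"))
    rec <- score_correlation(a, b, tumour, rep("D1", length(tumour)),
                             r_threshold = 0)
    rec$significant
  }, logical(1))
  expect_lte(mean(retained), 0.09)
})
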