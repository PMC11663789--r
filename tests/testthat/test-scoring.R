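test_that("aucell_score matches exhaustive recovery-curve enumeration", {
  # sweep all matrices with <= 20 genes: random expression, random sets
  set.seed(42)
  for (rep in 1:40) {
    G <- sample(6:20, 1)
    n_cells <- sample(1:4, 1)
    m <- matrix(stats::rexp(G * n_cells), G, n_cells,
                dimnames = list(sprintf("g%02d", 1:G),
                                sprintf("c%d", 1:n_cells)))
    if (rep %% 3 == 0) m[sample(length(m), G)] <- 0  # ties via zeros
    set_genes <- sample(rownames(m), sample(1:G, 1))
    tf <- sample(c(0.2, 0.3, 0.5), 1)
    got <- suppressWarnings(
      aucell_score(m, gene_set("s", set_genes), top_fraction = tf,
                   seed = 7))
    set.seed(7)
    tie_perm <- sample.int(G)
    for (ci in seq_len(n_cells)) {
      want <- brute_aucell(stats::setNames(m[, ci], rownames(m)),
                           tie_perm, set_genes, tf)
      expect_equal(unname(got[ci, "s"]), want, tolerance = 1e-12)
    }
  }
})

test_that("aucell_score hits its extremes and warns on absent sets", {
  m <- matrix(20:1, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "c1"))
  # set = the k top-ranked genes, k <= window -> score 1
  top <- aucell_score(m, gene_set("top", c("g01", "g02")),
                      top_fraction = 0.25, seed = 1)
  expect_equal(unname(top[1, 1]), 1)
  # set entirely outside the window -> 0
  out <- aucell_score(m, gene_set("tail", c("g19", "g20")),
                      top_fraction = 0.25, seed = 1)
  expect_equal(unname(out[1, 1]), 0)
  expect_warning(
    zero <- aucell_score(m, gene_set("none", "absent"), seed = 1),
    "no genes")
  expect_equal(unname(zero[1, 1]), 0)
  expect_true(all(top >= 0 & top <= 1))
})

test_that("pseudobulk_score: sign semantics, null mean, anti-symmetry", {
  set.seed(9)
  G <- 200
  pb <- matrix(stats::rnorm(3 * G), 3, G,
               dimnames = list(c("s1", "s2", "s3"), sprintf("g%03d", 1:G)))
  idx <- order(pb["s1", ], decreasing = TRUE)[1:10]
  topset <- gene_set("top", colnames(pb)[idx])
  sc <- pseudobulk_score(pb, topset)
  # uniformly top-ranked set genes give that sample the maximal score of
  # any sample and any same-size set
  expect_equal(unname(which.max(sc[, "top"])), 1L)
  # anti-symmetric under rank reversal of a sample
  rev_pb <- pb; rev_pb["s1", ] <- -pb["s1", ]
  sc_rev <- pseudobulk_score(rev_pb, topset)
  expect_equal(sc_rev["s1", "top"], -sc["s1", "top"], tolerance = 1e-10)
  # permutation null: mean score over random sets ~ 0
  set.seed(10)
  null_scores <- replicate(1000, {
    s <- gene_set("r", sample(colnames(pb), 10))
    pseudobulk_score(pb, s)["s1", 1]
  })
  expect_lt(abs(mean(null_scores)), 0.05)
  expect_error(pseudobulk_score(pb[1, , drop = FALSE], topset), "2 samples")
})

test_that("differential applies the printed significance gates", {
  set.seed(11)
  g <- 60; n <- 200
  m <- matrix(stats::rpois(g * n, 2), g, n,
              dimnames = list(sprintf("g%02d", 1:g), NULL))
  grp <- rep(c("a", "b"), each = n / 2)
  # planted 2-fold gene expressed in half of group-a cells
  m[1, grp == "a"][seq_len(n / 4) * 2] <- m[1, grp == "a"][seq_len(n / 4) * 2] + 8L
  norm <- log1p(m / rep(colSums(m), each = g) * 1e4)
  de <- differential(norm, grp, mode = "gene")
  de_a <- de[de$group == "a", ]
  expect_true(de_a$significant[de_a$feature == "g01"])
  # null features: none significant
  expect_lte(sum(de_a$significant), 1L)
  # the significance flag is exactly the conjunction of the three gates;
  # in particular a gene with log2FC 0.05 and FDR 1e-6 cannot be flagged
  expect_identical(de_a$significant,
                   abs(de_a$log2fc) > 0.1 & de_a$fdr < 0.01 &
                     (de_a$pct_group1 > 0.1 | de_a$pct_group2 > 0.1))
  sets <- matrix(stats::rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("s", 1:5), NULL))
  sets[1, 16:30] <- sets[1, 16:30] + 0.03
  de_s <- differential(sets, rep(c("x", "y"), each = 15), mode = "set")
  expect_true(all(c("log2fc", "fdr", "significant") %in% names(de_s)))
  expect_warning(differential(norm, c(rep("a", 2), rep("b", n - 2))),
                 "fewer than 3")
})

test_that("differential is calibrated on permuted labels", {
  set.seed(13)
  g <- 500; n <- 500
  m <- matrix(stats::rpois(g * n, 3), g, n,
              dimnames = list(sprintf("g%03d", 1:g), NULL))
  norm <- log1p(m / rep(colSums(m), each = g) * 1e4)
  grp <- sample(rep(c("a", "b"), each = n / 2))  # labels carry no signal
  de <- differential(norm, grp, mode = "gene")
  expect_equal(sum(de$significant), 0L)
})

test_that("differential p-values are uniform on a continuous null", {
  # group sizes large enough that the tie-corrected normal approximation
  # of the rank-sum p-value is accurate at KS resolution
  set.seed(17)
  scores <- matrix(stats::rnorm(2000 * 300), 2000, 300,
                   dimnames = list(sprintf("f%04d", 1:2000), NULL))
  de <- differential(scores, rep(c("a", "b"), each = 150), mode = "set")
  p <- de$p[de$group == "a"]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("metabolic_similarity separates planted states and is gene-order invariant", {
  set.seed(19)
  g <- 80; n <- 60
  m <- matrix(stats::rnorm(g * n), g, n,
              dimnames = list(sprintf("g%02d", 1:g), sprintf("c%02d", 1:n)))
  m[1:30, 1:30] <- m[1:30, 1:30] + 2        # state A
  m[31:60, 31:60] <- m[31:60, 31:60] + 2    # state B
  s <- metabolic_similarity(m, n_pcs = 10)
  expect_equal(unname(diag(s)), rep(1, n))
  expect_equal(s, t(s))
  within <- c(s[1:30, 1:30][upper.tri(s[1:30, 1:30])],
              s[31:60, 31:60][upper.tri(s[31:60, 31:60])])
  between <- s[1:30, 31:60]
  expect_gt(mean(within), mean(between))
  # invariance under gene reordering
  perm <- sample(g)
  s2 <- metabolic_similarity(m[perm, ], n_pcs = 10)
  expect_equal(s, s2, tolerance = 1e-8)
  expect_error(metabolic_similarity(m[, 1:9], n_pcs = 10), "components")
})

test_that("lineage_auc: separable marker gives 1, shuffled labels give 0.5", {
  set.seed(23)
  g <- 60; n <- 800
  counts <- matrix(stats::rpois(g * n, 3), g, n,
                   dimnames = list(sprintf("g%02d", 1:g), NULL))
  type <- rep(c("A", "B"), each = n / 2)
  counts[1, type == "A"] <- counts[1, type == "A"] + 25L  # exclusive marker
  meta <- data.frame(
    cell_id = sprintf("c%03d", 1:n),
    sample_id = rep(sprintf("s%d", 1:4), length.out = n),
    dataset_id = "D1", cancer_type = "CT1", tissue = "tumour",
    cell_type = type, stringsAsFactors = FALSE)
  x <- cell_expression(counts, meta)
  res <- lineage_auc(x, rownames(counts), seed = 3, nfolds = 5)
  expect_equal(res$auc[res$lineage == "A"], 1.0, tolerance = 1e-6)
  # shuffled labels -> AUC ~ 0.5
  meta2 <- meta; set.seed(29); meta2$cell_type <- sample(type)
  x2 <- cell_expression(counts, meta2)
  res2 <- lineage_auc(x2, rownames(counts), seed = 3, nfolds = 5)
  expect_lt(max(abs(res2$auc - 0.5)), 0.06)
  # n_subsample is a cap, not a quota
  res3 <- lineage_auc(x, rownames(counts), n_subsample = 10000, seed = 3,
                      nfolds = 5)
  expect_equal(res3$n_train[1], n / 2)
})
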