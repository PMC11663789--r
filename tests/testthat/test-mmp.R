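test_that("nmf_programs: K schedule, program size, planted block recovery", {
  # two disjoint 30-gene blocks active in disjoint cell halves
  set.seed(31)
  g <- 80; n <- 60
  A <- matrix(stats::runif(g * n, 0, 0.05), g, n,
              dimnames = list(sprintf("g%02d", 1:g), sprintf("c%02d", 1:n)))
  A[1:30, 1:30] <- A[1:30, 1:30] + 2
  A[31:60, 31:60] <- A[31:60, 31:60] + 2
  progs <- nmf_programs(list(S1 = A), k_values = 2, seed = 1, min_cells = 20)
  expect_length(progs, 2)
  lists <- lapply(progs, `[[`, "genes")
  expect_setequal(sort(lists[[1]]), sprintf("g%02d",
    if (lists[[1]][1] %in% sprintf("g%02d", 1:30)) 1:30 else 31:60))
  expect_setequal(sort(unlist(lists)), sprintf("g%02d", 1:60))
  # coefficients sorted non-increasing
  for (p in progs) expect_true(all(diff(p$coefficients) <= 1e-12))
  # default K schedule gives exactly 39 programs of exactly 30 genes
  set.seed(33)
  B <- matrix(stats::rexp(100 * 40), 100, 40,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  p39 <- nmf_programs(list(S1 = B), seed = 1)
  expect_length(p39, 39)
  expect_true(all(vapply(p39, function(p) length(p$genes), 1L) == 30L))
  expect_true(all(vapply(p39, `[[`, integer(1), "k") %in% 4:9))
  # sample below the cell threshold is skipped with a message
  expect_message(
    none <- nmf_programs(list(S2 = B[, 1:10]), k_values = 2, seed = 1),
    "skipped")
  expect_length(none, 0)
})

test_that("robust_filter agrees with the brute-force oracle on random instances", {
  for (seed in 1:100) {
    progs <- random_program_instance(seed)
    got <- robust_filter(progs)
    want <- brute_robust_filter(progs)
    expect_identical(names(got), names(want))
  }
})

test_that("robust_filter boundary cases follow the printed thresholds", {
  mk <- function(id, sample, k, genes) {
    structure(list(id = id, sample_id = sample, k = as.integer(k),
                   factor_index = 1L, genes = genes,
                   coefficients = rev(seq_along(genes)) / 30,
                   converged = TRUE, cancer_type = "CT1"),
              class = "NMFProgram")
  }
  pool <- sprintf("x%03d", 1:200)
  base <- pool[1:30]
  # p1: 21/30 with different-K same-sample partner, 6/30 with other tumour
  p1 <- mk("p1", "S1", 4, base)
  partner <- mk("p2", "S1", 5, c(base[1:21], pool[101:109]))
  other <- mk("p3", "S2", 4, c(base[1:6], pool[121:144]))
  other_partner <- mk("p4", "S2", 5, c(base[1:6], pool[121:144]))
  progs <- list(p1 = p1, p2 = partner, p3 = other, p4 = other_partner)
  kept <- robust_filter(progs)
  expect_true("p1" %in% names(kept))   # 21/30 and 6/30: both inclusive
  # 20/30 within-sample overlap fails criterion 1
  partner20 <- mk("p2", "S1", 5, c(base[1:20], pool[101:110]))
  kept2 <- robust_filter(list(p1 = p1, p2 = partner20, p3 = other,
                              p4 = other_partner))
  expect_false("p1" %in% names(kept2))
  # program overlapping nothing anywhere is removed
  lone <- mk("p5", "S3", 4, pool[171:200])
  expect_false("p5" %in% names(robust_filter(c(progs, list(p5 = lone)))))
  # criterion 3: of two same-tumour programs sharing 7 genes, the one with
  # higher cross-tumour overlap survives
  a1 <- mk("a1", "S1", 4, base)
  a1b <- mk("a1b", "S1", 5, base)                      # cross-K partner
  a2 <- mk("a2", "S1", 6, c(base[1:7], pool[31:53]))   # shares 7 with a1
  a2b <- mk("a2b", "S1", 7, c(base[1:7], pool[31:53]))
  b1 <- mk("b1", "S2", 4, base)                        # 30/30 with a1
  b1b <- mk("b1b", "S2", 5, base)
  b2 <- mk("b2", "S2", 6, c(base[1:7], pool[31:43], pool[61:70]))  # 17/30 w a2
  b2b <- mk("b2b", "S2", 7, c(base[1:7], pool[31:43], pool[61:70]))
  kept3 <- robust_filter(list(a1 = a1, a1b = a1b, a2 = a2, a2b = a2b,
                              b1 = b1, b1b = b1b, b2 = b2, b2b = b2b))
  expect_true("a1" %in% names(kept3))
  expect_false("a2" %in% names(kept3))  # lower cross-tumour overlap, shares 7
})

test_that("cluster_mmps handles the degenerate and boundary cases", {
  mk <- function(id, sample, genes) {
    structure(list(id = id, sample_id = sample, k = 4L, factor_index = 1L,
                   genes = genes, coefficients = rev(seq_along(genes)) / 30,
                   converged = TRUE, cancer_type = "CT1"),
              class = "NMFProgram")
  }
  shared <- sprintf("g%03d", 1:30)
  # 12 identical programs from 12 tumours -> one MMP with 12 members
  twelve <- lapply(1:12, function(i)
    mk(sprintf("p%02d", i), sprintf("T%02d", i), shared))
  names(twelve) <- vapply(twelve, `[[`, character(1), "id")
  mm <- cluster_mmps(twelve)
  expect_length(mm, 1)
  expect_length(mm[[1]]$members, 12)
  expect_setequal(mm[[1]]$genes, shared)
  expect_length(mm[[1]]$tumours, 12)
  # 9 identical programs -> candidate cluster below min_members: dropped
  nine <- twelve[1:9]
  expect_length(cluster_mmps(nine), 0)
  expect_length(attr(cluster_mmps(nine), "unassigned"), 9)
  # empty input -> empty output
  expect_length(cluster_mmps(list()), 0)
})

test_that("full planted recovery at reduced scale keeps members >= floor", {
  # reuses the mid-size cohort: every planted module present as a cluster
  coh <- mmp_cohort()
  res <- discover_mmps(coh$expression,
                       metabolic_gene_set(coh$truth), seed = 1)
  truthmods <- lapply(coh$truth$programs, `[[`, "genes")
  mm <- cluster_mmps(res$robust, min_members = 4)
  expect_gte(length(mm), 6)
  matched <- vapply(mm, function(m)
    max(vapply(truthmods, function(g) length(intersect(g, m$genes)),
               integer(1))) >= 21, logical(1))
  expect_gte(sum(matched), 0.8 * length(mm))
  # every reported MMP spans >= 2 tumours and respects the member floor
  for (m in mm) {
    expect_gte(length(m$members), 4)
    expect_gte(length(m$tumours), 2)
    expect_length(m$genes, 30)
  }
  # member conservation: per-MMP observed sums over cancer types equal
  # the member count
  pct <- vapply(res$robust, `[[`, character(1), "cancer_type")
  ab <- abundance(mm, pct)
  for (m in mm)
    expect_equal(sum(ab$observed[ab$mmp_id == m$mmp_id]),
                 length(m$members))
})

test_that("annotate_mmp: hypergeometric enrichment against the universe", {
  bg <- sprintf("g%04d", 1:1500)
  m <- structure(list(mmp_id = "MMP1", genes = bg[1:30],
                      members = as.character(1:10), member_programs = NULL,
                      tumours = as.character(1:10), annotation = NULL),
                 class = "MMP")
  # all 30 genes inside one 40-gene pathway -> that pathway, minimal p
  paths <- list(gene_set("hit", bg[1:40]),
                gene_set("miss", bg[1000:1080]))
  ann <- annotate_mmp(m, paths, bg)
  expect_identical(ann$annotation$pathway, "hit")
  # overlap 5, set 30, pathway 50, background 1500: p equals the exact
  # tail summation (here with a single pathway, BH leaves p unchanged)
  p5 <- list(gene_set("p5", c(bg[1:5], bg[100:144])))
  ann5 <- annotate_mmp(m, p5, bg)
  want <- brute_hyper_upper(5, 50, 1450, 30)
  expect_equal(ann5$annotation$p_adj, want, tolerance = 1e-12)
  # zero overlap everywhere -> unannotated
  far <- list(gene_set("far", bg[1400:1450]))
  expect_identical(annotate_mmp(m, far, bg)$annotation$pathway,
                   "unannotated")
  expect_error(annotate_mmp(m, list(), bg), "empty")
  expect_error(annotate_mmp(m, paths, bg[100:1500]), "background")
})

test_that("abundance matches direct arithmetic and the brute-force oracle", {
  # printed example: N_MMP = 12, N_cancer = 39, N_robust = 390, observed 4
  pct <- c(rep("CTA", 39), rep("CTB", 351))
  names(pct) <- sprintf("p%03d", 1:390)
  members <- c(sprintf("p%03d", 1:4),        # 4 observed in CTA
               sprintf("p%03d", 40:47))      # 8 in CTB
  m <- structure(list(mmp_id = "MMP1", genes = sprintf("g%d", 1:30),
                      members = members, member_programs = NULL,
                      tumours = as.character(1:12), annotation = NULL),
                 class = "MMP")
  ab <- abundance(list(m), pct)
  rec <- ab[ab$cancer_type == "CTA", ]
  expect_equal(rec$expected, 1.2)
  expect_equal(rec$abundance, log2(5 / 2.2), tolerance = 1e-12)
  expect_equal(rec$abundance, 1.1844, tolerance = 1e-4)
  expect_identical(substr(rec$category, 1, 4), "high")
  expect_equal(rec$n_mmp_total, 12L)
  expect_equal(rec$n_cancer_total, 39L)
  expect_equal(rec$n_robust_total, 390L)
  # rule fall-through: observed 0 with expected ~0 -> absent
  empty_ct <- c(pct, q1 = "CTC")
  ab2 <- abundance(list(m), empty_ct)
  expect_identical(ab2$category[ab2$cancer_type == "CTC"], "absent")
  # oracle agreement on random instances
  for (seed in 101:130) {
    progs <- random_program_instance(seed, n_programs = 25)
    pmap <- vapply(progs, `[[`, character(1), "cancer_type")
    mmp <- structure(list(mmp_id = "M", genes = sprintf("g%d", 1:30),
                          members = sample(names(progs), 12),
                          member_programs = NULL, tumours = "t",
                          annotation = NULL), class = "MMP")
    got <- abundance(list(mmp), pmap)
    want <- brute_abundance(list(mmp), pmap)
    expect_equal(got$observed, want$observed)
    expect_equal(got$expected, want$expected, tolerance = 1e-12)
    expect_equal(got$abundance, want$abundance, tolerance = 1e-12)
    expect_equal(got$p_bonferroni, want$p_bonferroni, tolerance = 1e-9)
    expect_identical(got$category, want$category)
  }
  expect_error(abundance(list(m), character(0)), "N_robust")
})
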