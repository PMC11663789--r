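# fixtures are generated in code; expensive ones are memoized so multiple
# test files can share a single computation

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# tiny deterministic CellExpression from a dense matrix
toy_expression <- function(counts, sample_id = "S1", dataset_id = "D1",
                           tissue = "tumour", cell_type = "epithelial",
                           gene_symbols = NULL, gene_positions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (!is.null(gene_symbols)) rownames(counts) <- gene_symbols
  n <- ncol(counts)
  meta <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n), dataset_id = rep_len(dataset_id, n),
    cancer_type = "CT1", tissue = rep_len(tissue, n),
    cell_type = rep_len(cell_type, n), stringsAsFactors = FALSE)
  cell_expression(counts, meta, gene_positions = gene_positions)
}

# small multi-sample cohort shared across unit tests
small_cohort <- function() fixture("small_cohort", {
  cfg <- synthetic_config(seed = 101, n_datasets = 1,
                          tumours_per_dataset = 4, normals_per_dataset = 2,
                          cells_per_sample = 200, n_genes = 1000)
  generate_cohort(cfg)
})

# mid-size cohort for reduced-scale MMP recovery: 8 planted programs, each
# active in 6 of 8 tumours, so the per-tumour program load stays within the
# capacity of the K <= 9 factorization schedule
mmp_cohort <- function() fixture("mmp_cohort", {
  progs <- default_program_catalogue(n_tumours = 8, n_active_tumours = 6)[1:8]
  cfg <- synthetic_config(seed = 303, n_datasets = 1,
                          tumours_per_dataset = 8, normals_per_dataset = 1,
                          cells_per_sample = 250, programs = progs)
  generate_cohort(cfg)
})

# cohort for the malignancy tests (also used by acceptance criterion 5)
malignancy_cohort <- function() fixture("malignancy_cohort", {
  cfg <- synthetic_config(seed = 5, n_datasets = 1, tumours_per_dataset = 6,
                          normals_per_dataset = 3, cells_per_sample = 300)
  generate_cohort(cfg)
})

malignancy_call <- function() fixture("malignancy_call", {
  coh <- malignancy_cohort()
  de <- suppressWarnings(tumour_normal_de(coh$expression))
  epi <- subset_cells(coh$expression,
    cells = coh$expression$cell_meta$cell_type %in%
      c("malignant", "epithelial"))
  list(call = iterative_malignancy(epi, de, seed = 1), epi = epi)
})

# the full default cohort and MMP discovery run (acceptance criterion 2)
acceptance_mmp_run <- function() fixture("acceptance_mmp_run", {
  cfg <- synthetic_config(seed = 20260910L)
  coh <- generate_cohort(cfg)
  res <- discover_mmps(coh$expression, metabolic_gene_set(coh$truth),
                       seed = 1, pathways = default_pathway_catalogue(cfg))
  list(cfg = cfg, coh = coh, res = res)
})
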