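#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale pan-cancer cohort: 2 datasets (one cancer
#' type each), 11 tumour + 2 normal samples per dataset, 500 cells per
#' sample, 2000 genes (half flagged metabolic) plus 13 mitochondrial genes,
#' 7 cell lineages, per-tumour CNV segments on malignant cells, and a
#' planted catalogue of subpopulation-restricted metabolic programs
#' (see [default_program_catalogue()]).
#'
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param n_datasets number of datasets (each gets one cancer type).
#' @param tumours_per_dataset,normals_per_dataset samples per dataset.
#' @param cells_per_sample cells drawn per sample.
#' @param n_genes number of (non-mitochondrial) genes.
#' @param metabolic_fraction fraction of genes flagged metabolic (the first
#'   `floor(metabolic_fraction * n_genes)` genes).
#' @param n_chromosomes chromosomes genes are laid out on, contiguously.
#' @param cell_types data.frame with columns `name`, `freq` (tumour-sample
#'   frequency; in normal samples the malignant mass is reassigned to
#'   epithelial), `marker_size`, `marker_log2fc`.
#' @param programs list of planted program specs as returned by
#'   [default_program_catalogue()]; may be empty.
#' @param cnv_segments_per_tumour number of CNV segments per tumour (0
#'   disables CNV).
#' @param cnv_factors multiplicative rate factors cycled over segments.
#' @param cnv_chrom_pool chromosomes eligible for CNV segments (kept away
#'   from the metabolic genes by default so planted programs and CNV signal
#'   stay orthogonal).
#' @param cnv_span_genes genes per CNV segment (from the chromosome start).
#' @param library_meanlog,library_sdlog log-normal library-size parameters.
#' @param dataset_libsize_shift multiplicative library-size factor applied
#'   per dataset index (dataset d gets `shift^(d-1)`).
#' @param n_mito,mito_fraction mitochondrial gene count and expected
#'   baseline mitochondrial fraction of each library.
#' @param dispersion negative-binomial size parameter (shared over genes).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_datasets = 2L,
                             tumours_per_dataset = 11L,
                             normals_per_dataset = 2L,
                             cells_per_sample = 500L,
                             n_genes = 2000L,
                             metabolic_fraction = 0.5,
                             n_chromosomes = 10L,
                             cell_types = default_cell_type_catalogue(),
                             programs = default_program_catalogue(
                               n_tumours = n_datasets * tumours_per_dataset),
                             cnv_segments_per_tumour = 2L,
                             cnv_factors = c(1.6, 0.6),
                             cnv_chrom_pool = NULL,
                             cnv_span_genes = 120L,
                             library_meanlog = log(3000),
                             library_sdlog = 0.35,
                             dataset_libsize_shift = 1.2,
                             n_mito = 13L,
                             mito_fraction = 0.05,
                             dispersion = 10) {
  stopifnot(n_datasets >= 1, tumours_per_dataset >= 1,
            cells_per_sample >= 1, n_genes >= 100,
            metabolic_fraction > 0, metabolic_fraction <= 1,
            mito_fraction > 0, mito_fraction < 1, dispersion > 0,
            all(cnv_factors > 0))
  for (p in programs) {
    stopifnot(all(p$active_fraction > 0), all(p$active_fraction < 1),
              p$log2_effect > 0, length(p$genes) >= 1)
  }
  if (is.null(cnv_chrom_pool)) {
    first_free <- ceiling(metabolic_fraction * n_chromosomes) + 1
    cnv_chrom_pool <- paste0("chr", seq(min(first_free + 1, n_chromosomes),
                                        n_chromosomes))
  }
  structure(list(
    seed = as.integer(seed), n_datasets = as.integer(n_datasets),
    tumours_per_dataset = as.integer(tumours_per_dataset),
    normals_per_dataset = as.integer(normals_per_dataset),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes), metabolic_fraction = metabolic_fraction,
    n_chromosomes = as.integer(n_chromosomes), cell_types = cell_types,
    programs = programs,
    cnv_segments_per_tumour = as.integer(cnv_segments_per_tumour),
    cnv_factors = cnv_factors, cnv_chrom_pool = cnv_chrom_pool,
    cnv_span_genes = as.integer(cnv_span_genes),
    library_meanlog = library_meanlog, library_sdlog = library_sdlog,
    dataset_libsize_shift = dataset_libsize_shift,
    n_mito = as.integer(n_mito), mito_fraction = mito_fraction,
    dispersion = dispersion), class = "synthetic_config")
}

#' Default cell-lineage catalogue for the generator
#'
#' Seven lineages with tumour-sample frequencies; malignant cells dominate
#' tumour samples so per-sample factorization sees a few hundred malignant
#' cells. Marker modules are disjoint blocks of non-metabolic genes.
#'
#' @return data.frame with columns `name`, `freq`, `marker_size`,
#'   `marker_log2fc`.
#' @export
default_cell_type_catalogue <- function() {
  data.frame(
    name = c("malignant", "epithelial", "T_cell", "B_cell", "myeloid",
             "fibroblast", "endothelial"),
    freq = c(0.70, 0.06, 0.08, 0.04, 0.05, 0.04, 0.03),
    marker_size = 25L,
    marker_log2fc = 2,
    stringsAsFactors = FALSE)
}

#' Planted metabolic program catalogue
#'
#' One disjoint 30-gene module per malignant-cell metabolic meta-program of
#' the reference inventory (15 in total, covering DNA synthesis, steroid
#' metabolism, OXPHOS, glycolysis, the citric-acid cycle, transport, amino
#' acid metabolism and several less canonical processes). Each module is
#' active in exactly 12 of `n_tumours` tumours (assignment balanced so no
#' tumour carries more than `ceiling(15 * 12 / n_tumours)` programs), in a
#' per-tumour active-cell fraction drawn uniformly from 0.1-0.3, with a
#' log2 effect of 2 on the module genes. Active-tumour counts and the
#' fraction range are chosen so that, after robust filtering, each
#' meta-program can retain the minimal 10 member programs.
#'
#' @param n_tumours number of tumour samples in the cohort.
#' @param n_active_tumours tumours each program is active in (default 12,
#'   capped at `n_tumours` for small test cohorts).
#' @return list of program specs: `name`, `genes`, `target_cell_type`,
#'   `active_fraction`, `log2_effect`, `active_tumours`.
#' @export
default_program_catalogue <- function(n_tumours = 22L,
                                      n_active_tumours = min(12L, n_tumours)) {
  stopifnot(n_active_tumours <= n_tumours)
  names15 <- c("DNA_synthesis", "Steroid_metabolism", "OXPHOS", "Glycolysis",
               "CAC", "Transport", "Amino_acid_metabolism",
               "Folate_metabolism", "Sulphur_metabolism",
               "Fatty_acid_metabolism", "Glutamine_metabolism",
               "Nucleotide_salvage", "Pentose_phosphate",
               "Redox_homeostasis", "Lipid_storage")
  n_prog <- length(names15)
  tumour_ids <- sprintf("T%02d", seq_len(n_tumours))
  # balanced incidence: each program takes the currently least-loaded tumours
  load <- stats::setNames(integer(n_tumours), tumour_ids)
  programs <- vector("list", n_prog)
  for (p in seq_len(n_prog)) {
    ord <- order(load, names(load))
    active <- sort(names(load)[ord[seq_len(n_active_tumours)]])
    load[active] <- load[active] + 1L
    genes <- sprintf("G%04d", ((p - 1) * 30 + 1):(p * 30))
    programs[[p]] <- list(name = names15[p], genes = genes,
                          target_cell_type = "malignant",
                          active_fraction = c(0.10, 0.30), log2_effect = 2,
                          active_tumours = active)
  }
  names(programs) <- names15
  programs
}

#' Synthetic metabolic pathway catalogue
#'
#' One pathway gene set per planted program: the 30 module genes plus 10
#' filler metabolic genes, for testing hypergeometric MMP annotation.
#'
#' @param config a [synthetic_config()].
#' @return named list of [gene_set()] objects (category `"pathway"`).
#' @export
default_pathway_catalogue <- function(config = synthetic_config()) {
  programs <- config$programs
  n_module_genes <- length(programs) * 30L
  out <- vector("list", length(programs))
  for (p in seq_along(programs)) {
    filler <- sprintf("G%04d",
                      (n_module_genes + (p - 1) * 10 + 1):
                      (n_module_genes + p * 10))
    out[[p]] <- gene_set(programs[[p]]$name,
                         c(programs[[p]]$genes, filler),
                         category = "pathway")
  }
  names(out) <- names(programs)
  out
}

# internal: gene table shared by generator and truth
synthetic_gene_table <- function(config) {
  g <- config$n_genes
  symbols <- sprintf("G%04d", seq_len(g))
  per_chrom <- ceiling(g / config$n_chromosomes)
  chrom <- paste0("chr", (seq_len(g) - 1) %/% per_chrom + 1)
  start <- ((seq_len(g) - 1) %% per_chrom) * 100000L + 1L
  if (config$n_mito > 0) {
    symbols <- c(symbols, paste0("MT-", seq_len(config$n_mito)))
    chrom <- c(chrom, rep("chrM", config$n_mito))
    start <- c(start, seq_len(config$n_mito) * 1000L)
  }
  n_metab <- floor(config$metabolic_fraction * g)
  data.frame(gene_symbol = symbols, chrom = chrom, start = as.integer(start),
             metabolic = c(seq_len(g) <= n_metab,
                           rep(FALSE, config$n_mito)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-dataset tumour/normal cohort
#'
#' Counts are negative binomial with mean `library_size` times the
#' softmax-normalized per-cell gene rates. Rates multiply in: cell-type
#' marker effects, planted program effects (only in Bernoulli-selected
#' active cells of the target type, in the program's active tumours), and
#' CNV segment factors in malignant cells. Malignant cells appear only in
#' tumour samples; in normal samples their frequency mass goes to
#' epithelial cells.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression` (a [cell_expression()]) and
#'   `truth` (cell table, program-activity matrix, CNV segment table,
#'   planted program list, metabolic gene vector).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- synthetic_gene_table(config)
  n_all <- nrow(genes)
  sym <- genes$gene_symbol

  for (p in config$programs)
    if (!all(p$genes %in% sym))
      stop("config error: program '", p$name, "' references unknown genes")

  # baseline log-rates; planted module genes drawn from an upper stratum so
  # they survive the mean-expression metabolic gene selection
  base_log <- stats::rnorm(n_all, 0, 0.9)
  module_genes <- unique(unlist(lapply(config$programs, `[[`, "genes")))
  base_log[match(module_genes, sym)] <-
    stats::rnorm(length(module_genes), 0.8, 0.4)
  base <- exp(base_log)
  mito_idx <- which(genes$chrom == "chrM")
  if (length(mito_idx)) {
    f <- config$mito_fraction
    base[mito_idx] <- f / (1 - f) * sum(base[-mito_idx]) / length(mito_idx)
  }

  # marker modules: disjoint blocks of non-metabolic, non-mito genes; one
  # extra block is a normal-epithelial differentiation module that
  # malignant cells lack (tumours lose differentiation programs), giving
  # the tumour-vs-normal DE a genuine down-regulated arm
  ct <- config$cell_types
  nonmet <- which(!genes$metabolic & genes$chrom != "chrM")
  epi_diff_size <- 25L
  need <- sum(ct$marker_size) + epi_diff_size
  if (need > length(nonmet)) stop("not enough non-metabolic genes for markers")
  # markers are scattered across the genome (as real lineage markers are),
  # so cell-type identity does not mimic a CNV segment under window
  # smoothing
  scatter <- nonmet[unique(round(seq(1, length(nonmet), length.out = need)))]
  stopifnot(length(scatter) == need)
  marker_idx <- split(scatter,
                      rep(seq_len(nrow(ct) + 1L),
                          c(ct$marker_size, epi_diff_size)))
  names(marker_idx) <- c(ct$name, ".epi_diff")

  # sample sheet
  n_t <- config$n_datasets * config$tumours_per_dataset
  n_n <- config$n_datasets * config$normals_per_dataset
  samples <- data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_t)),
                  sprintf("N%02d", seq_len(n_n))),
    dataset_id = c(sprintf("DS%d", rep(seq_len(config$n_datasets),
                                       each = config$tumours_per_dataset)),
                   sprintf("DS%d", rep(seq_len(config$n_datasets),
                                       each = config$normals_per_dataset))),
    tissue = c(rep("tumour", n_t), rep("normal", n_n)),
    stringsAsFactors = FALSE)
  samples$cancer_type <- sub("DS", "CT", samples$dataset_id)

  # CNV segments per tumour
  cnv <- NULL
  if (config$cnv_segments_per_tumour > 0) {
    rows <- list()
    for (s in which(samples$tissue == "tumour")) {
      chroms <- sample(config$cnv_chrom_pool,
                       min(config$cnv_segments_per_tumour,
                           length(config$cnv_chrom_pool)))
      for (k in seq_along(chroms)) {
        gidx <- which(genes$chrom == chroms[k])
        gidx <- gidx[seq_len(min(config$cnv_span_genes, length(gidx)))]
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = samples$sample_id[s], chrom = chroms[k],
          start = min(genes$start[gidx]), end = max(genes$start[gidx]),
          factor = config$cnv_factors[(k - 1) %% length(config$cnv_factors) + 1],
          stringsAsFactors = FALSE)
      }
    }
    cnv <- do.call(rbind, rows)
  }

  prog_names <- vapply(config$programs, `[[`, character(1), "name")
  counts_list <- vector("list", nrow(samples))
  meta_list <- vector("list", nrow(samples))
  activity_list <- vector("list", nrow(samples))
  theta <- config$dispersion

  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    d_idx <- as.integer(sub("DS", "", samples$dataset_id[s]))
    n_cells <- config$cells_per_sample
    freq <- ct$freq
    type_names <- ct$name
    if (samples$tissue[s] == "normal" && "malignant" %in% type_names) {
      epi <- match("epithelial", type_names)
      mal <- match("malignant", type_names)
      freq[epi] <- freq[epi] + freq[mal]
      freq[mal] <- 0
    }
    types <- sample(type_names, n_cells, replace = TRUE,
                    prob = freq / sum(freq))
    R <- matrix(base, n_all, n_cells)
    for (t in unique(types)) {
      cols <- which(types == t)
      R[marker_idx[[t]], cols] <-
        R[marker_idx[[t]], cols, drop = FALSE] *
        2^ct$marker_log2fc[match(t, ct$name)]
      if (t == "malignant")  # malignant cells keep the epithelial identity
        R[marker_idx[["epithelial"]], cols] <-
          R[marker_idx[["epithelial"]], cols, drop = FALSE] *
          2^ct$marker_log2fc[match("epithelial", ct$name)]
      if (t == "epithelial" && "malignant" %in% ct$name) {
        eff <- 2^ct$marker_log2fc[match("epithelial", ct$name)]
        R[marker_idx[[".epi_diff"]], cols] <-
          R[marker_idx[[".epi_diff"]], cols, drop = FALSE] * eff
      }
    }
    act <- matrix(0L, n_cells, length(config$programs),
                  dimnames = list(NULL, prog_names))
    for (p in seq_along(config$programs)) {
      pr <- config$programs[[p]]
      if (!sid %in% pr$active_tumours) next
      target <- which(types == pr$target_cell_type)
      if (!length(target)) next
      fr <- if (length(pr$active_fraction) == 2)
        stats::runif(1, pr$active_fraction[1], pr$active_fraction[2])
      else pr$active_fraction
      on <- target[stats::runif(length(target)) < fr]
      if (!length(on)) next
      act[on, p] <- 1L
      gi <- match(pr$genes, sym)
      R[gi, on] <- R[gi, on, drop = FALSE] * 2^pr$log2_effect
    }
    if (!is.null(cnv)) {
      seg <- cnv[cnv$sample_id == sid, , drop = FALSE]
      mal_cols <- which(types == "malignant")
      if (nrow(seg) && length(mal_cols)) {
        for (r in seq_len(nrow(seg))) {
          gi <- which(genes$chrom == seg$chrom[r] &
                      genes$start >= seg$start[r] & genes$start <= seg$end[r])
          R[gi, mal_cols] <- R[gi, mal_cols, drop = FALSE] * seg$factor[r]
        }
      }
    }
    P <- sweep(R, 2, colSums(R), "/")
    lib <- stats::rlnorm(n_cells, config$library_meanlog,
                         config$library_sdlog) *
      config$dataset_libsize_shift^(d_idx - 1)
    mu <- sweep(P, 2, lib, "*")
    cnts <- stats::rnbinom(length(mu), size = theta, mu = as.vector(mu))
    cm <- matrix(cnts, n_all, n_cells)
    counts_list[[s]] <- methods::as(Matrix::Matrix(cm, sparse = TRUE),
                                    "generalMatrix")
    meta_list[[s]] <- data.frame(
      cell_id = sprintf("%s_c%04d", sid, seq_len(n_cells)),
      sample_id = sid, dataset_id = samples$dataset_id[s],
      cancer_type = samples$cancer_type[s], tissue = samples$tissue[s],
      cell_type = types,
      malignancy = ifelse(types == "malignant", "malignant",
                          "non_malignant"),
      stringsAsFactors = FALSE)
    activity_list[[s]] <- act
  }

  counts <- do.call(cbind, counts_list)
  meta <- do.call(rbind, meta_list)
  activity <- do.call(rbind, activity_list)
  rownames(activity) <- meta$cell_id
  positions <- genes[, c("gene_symbol", "chrom", "start")]
  expr <- cell_expression(counts, meta, gene_ids = sym,
                          gene_symbols = sym, gene_positions = positions)
  truth <- list(
    cells = meta[, c("cell_id", "sample_id", "dataset_id", "cancer_type",
                     "tissue", "cell_type")],
    program_activity = activity,
    cnv_segments = cnv,
    programs = config$programs,
    metabolic_genes = sym[genes$metabolic])
  truth$cells$malignant <- meta$cell_type == "malignant"
  list(expression = expr, truth = truth)
}

#' Metabolic gene universe of a synthetic cohort
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @return a [gene_set()] with the cohort's metabolic genes.
#' @export
metabolic_gene_set <- function(truth) {
  gene_set("metabolic_genes", truth$metabolic_genes, category = "pathway")
}
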