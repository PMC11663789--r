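#' Read a 10x-style MTX triplet into a CellExpression
#'
#' Expects the common 10x dialect: a Matrix Market coordinate integer file,
#' a features TSV with 1-3 columns (id / id+symbol / id+symbol+type) and a
#' barcodes TSV with one barcode per line. Cell metadata is joined on
#' `cell_id`; cells absent from the metadata table are dropped (the count is
#' reported via `message()`).
#'
#' @param matrix_path path to matrix.mtx.
#' @param features_path path to features.tsv.
#' @param barcodes_path path to barcodes.tsv.
#' @param meta_path path to a cell-metadata TSV keyed by `cell_id`.
#' @param positions_path optional gene-position TSV
#'   (`gene_symbol`, `chrom`, `start`).
#' @return a [cell_expression()] object.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path, meta_path,
                        positions_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m))
    stop("format error: features rows (", nrow(feats),
         ") != matrix rows (", nrow(m), ")")
  if (length(barcodes) != ncol(m))
    stop("format error: barcodes rows (", length(barcodes),
         ") != matrix columns (", ncol(m), ")")
  if (anyDuplicated(barcodes))
    stop("integrity error: duplicate barcodes")
  gene_ids <- as.character(feats[[1]])
  gene_symbols <- if (ncol(feats) >= 2) as.character(feats[[2]]) else gene_ids

  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(meta)) stop("metadata must be keyed by cell_id")
  keep <- barcodes %in% meta$cell_id
  if (any(!keep))
    message(sum(!keep), " cells absent from metadata were dropped")
  if (!any(keep)) stop("no barcodes present in metadata")
  m <- m[, keep, drop = FALSE]
  barcodes <- barcodes[keep]
  meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]

  positions <- NULL
  if (!is.null(positions_path)) positions <- read_gene_positions(positions_path)
  cell_expression(m, meta, gene_ids = gene_ids, gene_symbols = gene_symbols,
                  gene_positions = positions)
}

#' Write a CellExpression as MTX + TSV files
#'
#' Inverse of [read_counts()]. Entries are written in canonical
#' column-major order so that two writes of the same object are
#' byte-identical.
#'
#' @param x CellExpression.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "CellExpression"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  m <- methods::as(x$counts, "TsparseMatrix")
  ord <- order(m@j, m@i)
  con <- file(mp, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                     as.integer(m@x[ord])), con)
  close(con)
  fp <- file.path(dir, "features.tsv")
  utils::write.table(data.frame(x$gene_ids, x$gene_symbols),
                     fp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bp <- file.path(dir, "barcodes.tsv")
  writeLines(x$cell_meta$cell_id, bp)
  cp <- file.path(dir, "cell_meta.tsv")
  utils::write.table(x$cell_meta, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(mp, fp, bp, cp)
  if (!is.null(x$gene_positions)) {
    pp <- file.path(dir, "gene_positions.tsv")
    utils::write.table(x$gene_positions, pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' Read a gene-position table
#'
#' @param path TSV with columns `gene_symbol`, `chrom`, `start`.
#' @return data.frame.
#' @export
read_gene_positions <- function(path) {
  pos <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "chrom", "start")
  if (!all(need %in% names(pos)))
    stop("gene position table needs columns: ", paste(need, collapse = ", "))
  pos$start <- as.integer(pos$start)
  pos
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' The description field carries the set category as written by
#' [write_gene_sets()] (`category` or `regulon:TFNAME`); unknown
#' descriptions default to category `"pathway"`. Regulon sets with fewer
#' than `min_regulon_targets` genes are excluded — the target-count filter
#' applies to regulons only.
#'
#' @param gmt_path path to the GMT file.
#' @param min_regulon_targets minimum number of target genes for a regulon
#'   to be kept (default 5, boundary inclusive).
#' @return named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(gmt_path, min_regulon_targets = 5L) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line has fewer than 3 tab-separated fields: ",
           substr(ln, 1, 40))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning("gene set '", f[1], "' has no genes; skipped")
      next
    }
    desc <- f[2]
    regulator <- NULL
    category <- "pathway"
    if (grepl("^regulon(:|$)", desc)) {
      category <- "regulon"
      if (grepl(":", desc, fixed = TRUE))
        regulator <- sub("^regulon:", "", desc)
    } else if (desc %in% c("pathway", "hallmark", "signature", "mmp")) {
      category <- desc
    }
    if (category == "regulon" && length(genes) < min_regulon_targets) next
    sets[[f[1]]] <- gene_set(f[1], genes, category = category,
                             regulator = regulator)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  sets <- as_gene_set_list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (s$category == "regulon" && !is.null(s$regulator))
      paste0("regulon:", s$regulator) else s$category
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a record table deterministically
#'
#' Rows are sorted by all columns left to right (the leftmost column is the
#' primary key), numeric columns are serialized at fixed precision, and the
#' column order is preserved, so two writes of equal records are
#' byte-identical. A `.json` extension selects JSON output, anything else
#' TSV.
#'
#' @param records data.frame (or list of homogeneous records).
#' @param path output path ending in `.tsv` or `.json`.
#' @param digits significant digits for numeric columns (default 8).
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path, digits = 8L) {
  if (!is.data.frame(records)) records <- do.call(rbind.data.frame, records)
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    ord <- do.call(order, unname(as.list(df)))
    df <- df[ord, , drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
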