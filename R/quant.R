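# Multimapper filtering, UMI-deduplicated quantification, and the 10X-style
# MTX output trio. One sparse barcode-by-gene matrix per species; an entry
# is the number of distinct (barcode, gene, UMI) triples.

#' Multimapper keep-rule for one read's alignments within one species
#'
#' A read with a single alignment is kept as is. A multimapper is kept only
#' if exactly one of its alignments is exonic (that alignment wins);
#' otherwise (no exonic, or exons of two genes at once) the read is
#' discarded from quantification.
#'
#' @param alignments_of_read data.frame of one read's alignment records,
#'   carrying a `feature` column.
#' @return the kept alignment row (one-row data.frame) or `NULL`.
#' @export
filter_multimapper <- function(alignments_of_read) {
  stopifnot(nrow(alignments_of_read) >= 1L,
            length(unique(alignments_of_read$read_id)) == 1L)
  if (nrow(alignments_of_read) == 1L) return(alignments_of_read)
  ex <- which(as.character(alignments_of_read$feature) == "exonic")
  if (length(ex) == 1L) alignments_of_read[ex, , drop = FALSE] else NULL
}

# Vectorized form: apply the keep-rule per read over a whole alignment
# table. Returns the kept rows.
.filter_multimappers <- function(aln) {
  dt <- data.table::as.data.table(aln)
  dt[, `:=`(.n = .N, .nex = sum(as.character(feature) == "exonic")),
     by = read_id]
  kept <- dt[.n == 1L | (.nex == 1L & as.character(feature) == "exonic")]
  kept[, c(".n", ".nex") := NULL]
  as.data.frame(kept)
}

#' Build a UMI-deduplicated spot-by-gene count matrix
#'
#' Counts distinct (barcode, gene, UMI) triples; duplicate molecules (same
#' triple) collapse to one count, so adding a duplicate read never changes
#' the matrix. Exact UMI collapse only - no mismatch-tolerant merging.
#'
#' @param assignments data.frame with `barcode`, `umi`, `gene_id`,
#'   `feature` columns (one row per kept read).
#' @param species "host" or "graft", stored on the matrix.
#' @param barcodes,genes optional fixed universes (column/row order); by
#'   default the sorted observed values.
#' @param gene_names optional named vector gene_id -> display symbol.
#' @param include_intronic if `TRUE`, intronic reads count toward their
#'   gene body's gene; default counts exonic reads only (the standard
#'   Visium convention).
#' @return object of class `SpotMatrix`: `counts` (dgCMatrix, genes x
#'   barcodes), `barcodes`, `genes`, `gene_names`, `species`.
#' @export
build_spot_matrix <- function(assignments, species, barcodes = NULL,
                              genes = NULL, gene_names = NULL,
                              include_intronic = FALSE) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    assignments <- data.frame(barcode = character(0), umi = character(0),
                              gene_id = character(0),
                              feature = character(0))
  }
  feat <- as.character(assignments$feature)
  keep <- feat == "exonic" & !is.na(assignments$gene_id)
  if (include_intronic) {
    keep <- keep | (feat == "intronic" & !is.na(assignments$gene_id))
  }
  a <- assignments[keep, c("barcode", "umi", "gene_id")]
  a <- unique(a)
  if (is.null(barcodes)) barcodes <- sort(unique(a$barcode))
  if (is.null(genes)) genes <- sort(unique(a$gene_id))
  .check(all(a$barcode %in% barcodes), "assignment barcode outside universe")
  .check(all(a$gene_id %in% genes), "assignment gene outside universe")
  counts <- Matrix::sparseMatrix(
    i = match(a$gene_id, genes),
    j = match(a$barcode, barcodes),
    x = rep(1L, nrow(a)),
    dims = c(length(genes), length(barcodes)),
    dimnames = list(genes, barcodes))
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(gene_names)) gene_names <- stats::setNames(genes, genes)
  structure(list(counts = counts, barcodes = barcodes, genes = genes,
                 gene_names = gene_names[genes], species = species),
            class = "SpotMatrix")
}

#' @export
print.SpotMatrix <- function(x, ...) {
  cat(sprintf("SpotMatrix (%s): %d genes x %d barcodes, %d nonzero, %d UMIs\n",
              x$species, length(x$genes), length(x$barcodes),
              Matrix::nnzero(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write a spot matrix as a 10X-style MTX trio
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, genes as rows),
#' `barcodes.tsv` and `features.tsv` (gene_id, gene_name,
#' "Gene Expression") into `out_dir`.
#'
#' @param m a `SpotMatrix`.
#' @param out_dir output directory (created if needed).
#' @export
write_spot_matrix <- function(m, out_dir) {
  stopifnot(inherits(m, "SpotMatrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .check(dir.exists(out_dir), "cannot create output directory %s", out_dir)
  Matrix::writeMM(m$counts, file.path(out_dir, "matrix.mtx"))
  writeLines(m$barcodes, file.path(out_dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(m$genes, unname(m$gene_names), "Gene Expression"),
    file.path(out_dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}

#' Read a spot matrix written by [write_spot_matrix()]
#'
#' @param dir directory holding matrix.mtx, barcodes.tsv, features.tsv.
#' @param species species label for the returned object.
#' @return a `SpotMatrix`.
#' @export
read_spot_matrix <- function(dir, species = "host") {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  fpath <- file.path(dir, "features.tsv")
  feats <- if (file.size(fpath) > 0L) {
    utils::read.table(fpath, sep = "\t", colClasses = "character")
  } else data.frame(V1 = character(0), V2 = character(0))
  dimnames(counts) <- list(feats$V1, barcodes)
  structure(list(counts = counts, barcodes = barcodes, genes = feats$V1,
                 gene_names = stats::setNames(feats$V2, feats$V1),
                 species = species), class = "SpotMatrix")
}

#' Library-size normalize and log-transform a spot matrix
#'
#' Per-spot counts are scaled to `scale` total (spots with zero counts stay
#' zero) and transformed with log1p; the convention used by the spatial
#' ligand-receptor tests.
#'
#' @param m a `SpotMatrix`.
#' @param scale target per-spot total (default 1e4).
#' @return dense-ish dgCMatrix of normalized expression, genes x barcodes.
#' @export
normalize_expression <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "SpotMatrix"))
  libsize <- Matrix::colSums(m$counts)
  sf <- ifelse(libsize > 0, scale / libsize, 0)
  norm <- m$counts %*% Matrix::Diagonal(x = sf)
  dimnames(norm) <- dimnames(m$counts)
  methods::as(log1p(norm), "CsparseMatrix")
}
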