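# GTF-backed feature annotation. An alignment locus is labeled exonic,
# intronic, pseudogene, or intergenic, with a deterministic precedence:
# exon of a non-pseudogene gene > intron of a non-pseudogene gene > any
# overlap with a pseudogene-biotype gene > intergenic. Pseudogene hits rank
# below intergenic evidence in downstream rescue because pseudogenes are
# homology traps: an exonic alignment in the other species should override
# them.

.FEATURE_LEVELS <- c("exonic", "intronic", "pseudogene", "intergenic")

#' Build an interval index over genes and exons from a GTF
#'
#' GTF coordinates (1-based, inclusive) are kept in `GRanges` form
#' internally. Genes whose biotype contains the substring "pseudogene" are
#' indexed separately. Both Ensembl (`gene_biotype`) and GENCODE
#' (`gene_type`) attribute dialects are accepted.
#'
#' @param gtf_path path to a GTF with `gene` and `exon` records carrying
#'   `gene_id` attributes.
#' @return a `FeatureIndex` with `genes` and `exons` (`GRanges`), reduced
#'   per-gene exons, and biotype/name lookups.
#' @export
build_feature_index <- function(gtf_path) {
  ln <- readLines(gtf_path)
  body <- which(!grepl("^#", ln) & nzchar(ln))
  bad <- body[!grepl("gene_id", ln[body], fixed = TRUE)]
  .check(length(bad) == 0L,
         "GTF record without gene_id attribute at line %d of %s",
         if (length(bad)) bad[1] else 0L, gtf_path)

  gr <- rtracklayer::import(gtf_path)
  .check(length(gr) > 0L, "empty GTF: %s", gtf_path)
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype
             else if ("gene_type" %in% names(mc)) mc$gene_type
             else rep("protein_coding", length(gr))
  biotype[is.na(biotype)] <- "protein_coding"
  gr$biotype <- biotype

  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  .check(length(genes) > 0L, "GTF has no gene records: %s", gtf_path)

  # collapse overlapping exons per gene so exonic coverage is not
  # double-counted
  ex_by_gene <- S4Vectors::split(GenomicRanges::granges(exons), exons$gene_id)
  ex_red <- unlist(GenomicRanges::reduce(ex_by_gene))
  ex_red$gene_id <- names(ex_red)
  names(ex_red) <- NULL

  gene_biotype <- stats::setNames(genes$biotype, genes$gene_id)
  gene_name <- stats::setNames(
    if ("gene_name" %in% names(S4Vectors::mcols(genes)) &&
        !all(is.na(genes$gene_name))) genes$gene_name else genes$gene_id,
    genes$gene_id)
  is_pseudo <- stats::setNames(grepl("pseudogene", gene_biotype),
                               names(gene_biotype))

  structure(list(genes = genes, exons = ex_red,
                 gene_biotype = gene_biotype, gene_name = gene_name,
                 is_pseudo = is_pseudo), class = "FeatureIndex")
}

#' @export
print.FeatureIndex <- function(x, ...) {
  cat(sprintf("FeatureIndex: %d genes (%d pseudogene), %d reduced exons on %d seqnames\n",
              length(x$genes), sum(x$is_pseudo), length(x$exons),
              length(unique(as.character(GenomicRanges::seqnames(x$genes))))))
  invisible(x)
}

#' Annotate alignment intervals against a feature index
#'
#' Each query interval (0-based half-open, stranded) is classified with the
#' precedence exonic > intronic > pseudogene > intergenic. A locus is
#' exonic when at least `exon_frac` of its bases overlap the (reduced)
#' exons of a single non-pseudogene gene on the same strand; otherwise
#' intronic if it overlaps that gene's body; otherwise pseudogene if it
#' overlaps any pseudogene-biotype gene; otherwise intergenic. Only sense
#' (same-strand) overlap counts; antisense overlap is intergenic. Queries on
#' chromosomes absent from the index are intergenic and counted in the
#' `unknown_chrom` attribute.
#'
#' @param index a [build_feature_index()] result.
#' @param chrom,start,end,strand parallel vectors describing the intervals
#'   (`start` 0-based, `end` exclusive, strand "+" or "-").
#' @param exon_frac minimum fraction of aligned bases overlapping exons for
#'   an exonic call (default 0.5).
#' @return data.frame with `feature` (factor: exonic, intronic, pseudogene,
#'   intergenic) and `gene_id` (NA for intergenic); attribute
#'   `unknown_chrom` counts queries on unindexed chromosomes.
#' @export
annotate_intervals <- function(index, chrom, start, end, strand,
                               exon_frac = 0.5) {
  stopifnot(inherits(index, "FeatureIndex"))
  n <- length(chrom)
  .check(all(start < end), "interval start must be < end")
  feature <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  known <- chrom %in% GenomeInfoDb::seqlevels(index$genes)
  unknown_chrom <- sum(!known)
  if (any(known)) {
    q <- GenomicRanges::GRanges(chrom[known],
                                IRanges::IRanges(start[known] + 1L, end[known]),
                                strand = strand[known])
    qi <- which(known)

    np_exons <- index$exons[!index$is_pseudo[index$exons$gene_id]]
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, np_exons))
    if (length(hits) > 0L) {
      ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                      np_exons[S4Vectors::subjectHits(hits)])
      dt <- data.table::data.table(
        qh = S4Vectors::queryHits(hits),
        gene = np_exons$gene_id[S4Vectors::subjectHits(hits)],
        w = GenomicRanges::width(ov))
      cov <- dt[, .(w = sum(w)), by = .(qh, gene)]
      data.table::setorder(cov, qh, -w, gene)
      best <- cov[!duplicated(qh)]
      qw <- GenomicRanges::width(q)[best$qh]
      ex <- best[best$w / qw >= exon_frac]
      feature[qi[ex$qh]] <- "exonic"
      gene_id[qi[ex$qh]] <- ex$gene
    }

    rest <- which(feature[qi] == "intergenic")
    if (length(rest) > 0L) {
      np_genes <- index$genes[!index$is_pseudo[index$genes$gene_id]]
      hits <- suppressWarnings(GenomicRanges::findOverlaps(q[rest], np_genes))
      if (length(hits) > 0L) {
        ov <- GenomicRanges::pintersect(q[rest][S4Vectors::queryHits(hits)],
                                        np_genes[S4Vectors::subjectHits(hits)])
        dt <- data.table::data.table(
          qh = S4Vectors::queryHits(hits),
          gene = np_genes$gene_id[S4Vectors::subjectHits(hits)],
          w = GenomicRanges::width(ov))
        data.table::setorder(dt, qh, -w, gene)
        best <- dt[!duplicated(qh)]
        feature[qi[rest[best$qh]]] <- "intronic"
        gene_id[qi[rest[best$qh]]] <- best$gene
      }
    }

    rest <- which(feature[qi] == "intergenic")
    if (length(rest) > 0L && any(index$is_pseudo)) {
      ps_genes <- index$genes[index$is_pseudo[index$genes$gene_id]]
      hits <- suppressWarnings(GenomicRanges::findOverlaps(q[rest], ps_genes))
      if (length(hits) > 0L) {
        dt <- data.table::data.table(
          qh = S4Vectors::queryHits(hits),
          gene = ps_genes$gene_id[S4Vectors::subjectHits(hits)])
        data.table::setorder(dt, qh, gene)
        best <- dt[!duplicated(qh)]
        feature[qi[rest[best$qh]]] <- "pseudogene"
        gene_id[qi[rest[best$qh]]] <- best$gene
      }
    }
  }
  out <- data.frame(feature = factor(feature, levels = .FEATURE_LEVELS),
                    gene_id = gene_id)
  attr(out, "unknown_chrom") <- unknown_chrom
  out
}

#' Annotate one interval
#'
#' @inheritParams annotate_intervals
#' @return a list of class `FeatureClass` with `value` and `gene_id`.
#' @export
annotate_interval <- function(index, chrom, start, end, strand,
                              exon_frac = 0.5) {
  df <- annotate_intervals(index, chrom, start, end, strand, exon_frac)
  structure(list(value = as.character(df$feature), gene_id = df$gene_id),
            class = "FeatureClass")
}
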