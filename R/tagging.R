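# Spatial barcode / UMI extraction from paired FASTQ. Read 1 carries the
# spot barcode and UMI; read 2 is the cDNA fragment that gets aligned. The
# default geometry is Visium: barcode = first 16 bases, UMI = next 12.

#' Describe the barcode/UMI geometry of read 1
#'
#' @param barcode_length barcode length in bases.
#' @param umi_length UMI length in bases.
#' @param barcode_offset 0-based offset of the barcode within read 1.
#' @return a `ReadStructure` list.
#' @export
read_structure <- function(barcode_length = 16L, umi_length = 12L,
                           barcode_offset = 0L) {
  barcode_length <- as.integer(barcode_length)
  umi_length <- as.integer(umi_length)
  barcode_offset <- as.integer(barcode_offset)
  .check(barcode_length > 0L && umi_length > 0L && barcode_offset >= 0L,
         "barcode/UMI lengths must be positive and offset non-negative")
  structure(list(barcode_length = barcode_length, umi_length = umi_length,
                 barcode_offset = barcode_offset), class = "ReadStructure")
}

# Read a FASTQ file (possibly gzipped) into a data.frame of id/seq/qual.
.read_fastq <- function(path) {
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(
    read_id = sub("\\s.*$", "", names(dss)),
    sequence = as.character(dss),
    qualities = as.character(S4Vectors::mcols(dss)$qualities),
    row.names = NULL
  )
}

# Strip an old-style /1 or /2 mate suffix for pairing comparisons.
.strip_mate <- function(id) sub("/[12]$", "", id)

#' Extract spatial barcodes and UMIs from paired FASTQ
#'
#' Parses record-synchronized R1/R2 FASTQ files, extracts the barcode and
#' UMI from R1 per `structure`, and attaches them to the cDNA read (R2).
#' Pairs whose R1 is too short for the declared geometry are rejected; with
#' a whitelist, barcodes are matched exactly (no error correction) and
#' barcodes containing N are rejected.
#'
#' @param r1_path,r2_path paths to the paired FASTQ files (plain or .gz).
#' @param structure a [read_structure()]; Visium geometry by default.
#' @param whitelist optional character vector (or path to a one-per-line
#'   text file) of valid barcodes.
#' @return a list of class `xeno_tags`: `reads` (data.frame with `read_id`,
#'   `sequence`, `qualities`, `barcode`, `umi`) and `stats` (list with
#'   `total`, `accepted`, `too_short`, `not_in_whitelist`).
#' @export
tag_reads <- function(r1_path, r2_path, structure = read_structure(),
                      whitelist = NULL) {
  stopifnot(inherits(structure, "ReadStructure"))
  r1 <- .read_fastq(r1_path)
  r2 <- .read_fastq(r2_path)
  .check(nrow(r1) == nrow(r2),
         "R1 has %d records but R2 has %d", nrow(r1), nrow(r2))
  mism <- which(.strip_mate(r1$read_id) != .strip_mate(r2$read_id))
  .check(length(mism) == 0L,
         "R1/R2 desynchronized at record %d ('%s' vs '%s')",
         mism[1], r1$read_id[mism[1]], r2$read_id[mism[1]])
  if (!is.null(whitelist) && length(whitelist) == 1L && file.exists(whitelist)) {
    whitelist <- readLines(whitelist)
  }

  need <- structure$barcode_offset + structure$barcode_length +
    structure$umi_length
  long_enough <- nchar(r1$sequence) >= need
  bc <- substr(r1$sequence, structure$barcode_offset + 1L,
               structure$barcode_offset + structure$barcode_length)
  umi <- substr(r1$sequence,
                structure$barcode_offset + structure$barcode_length + 1L,
                need)
  in_wl <- if (is.null(whitelist)) rep(TRUE, nrow(r1)) else
    bc %in% whitelist & !grepl("N", bc, fixed = TRUE)

  accepted <- long_enough & in_wl
  reads <- data.frame(read_id = .strip_mate(r2$read_id)[accepted],
                      sequence = r2$sequence[accepted],
                      qualities = r2$qualities[accepted],
                      barcode = bc[accepted],
                      umi = umi[accepted],
                      row.names = NULL)
  stats <- list(total = nrow(r1),
                accepted = sum(accepted),
                too_short = sum(!long_enough),
                not_in_whitelist = sum(long_enough & !in_wl))
  base::structure(list(reads = reads, stats = stats, structure = structure),
                  class = "xeno_tags")
}

#' @export
print.xeno_tags <- function(x, ...) {
  cat(sprintf("xeno_tags: %d/%d pairs accepted (%d too short, %d not in whitelist)\n",
              x$stats$accepted, x$stats$total, x$stats$too_short,
              x$stats$not_in_whitelist))
  invisible(x)
}

# SAM-escape nothing: barcodes/UMIs are plain DNA. Tags follow the 10X
# convention: CB/UB corrected (here: accepted raw), CR/UR raw.
#' Write tagged reads as an unaligned SAM file
#'
#' Each accepted read becomes one unmapped SAM record carrying its barcode
#' in `CB`/`CR` and its UMI in `UB`/`UR` tags.
#'
#' @param tags a [tag_reads()] result.
#' @param path output SAM path.
#' @export
write_tagged_sam <- function(tags, path) {
  stopifnot(inherits(tags, "xeno_tags"))
  r <- tags$reads
  recs <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s\tCR:Z:%s\tUR:Z:%s",
                  r$read_id, r$sequence, r$qualities, r$barcode, r$umi,
                  r$barcode, r$umi)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", recs), path)
  invisible(path)
}

#' Read barcode/UMI tags back from an unaligned SAM file
#'
#' @param path SAM file written by [write_tagged_sam()].
#' @return data.frame with `read_id`, `sequence`, `qualities`, `barcode`,
#'   `umi`.
#' @export
read_tagged_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual"), tag = c("CB", "UB")))[[1]]
  data.frame(read_id = res$qname,
             sequence = as.character(res$seq),
             qualities = as.character(res$qual),
             barcode = res$tag$CB,
             umi = res$tag$UB,
             row.names = NULL)
}
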