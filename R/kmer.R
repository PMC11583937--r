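# Canonical k-mer index over a host/graft genome pair, and the read
# classifier that replaces an external xenograft-sorting tool. Each stored
# k-mer carries one of three labels: present only in the host genome, only
# in the graft genome, or in both (shared). Reads are classified into the
# five categories used by xenograft sorters: host, graft, both, ambiguous,
# neither.

.KMER_LABELS <- c("HOST_ONLY", "GRAFT_ONLY", "SHARED")
.SPECIES_CALLS <- c("host", "graft", "both", "ambiguous", "neither")

# Unique canonical k-mers of a genome (named character vector of
# chromosome sequences). K-mers containing non-ACGT letters are skipped.
.genome_canonical_kmers <- function(seqs, k) {
  km <- unlist(lapply(toupper(seqs), .kmers, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  unique(canonical_kmer(km))
}

#' Build a host/graft canonical k-mer index
#'
#' Enumerates all canonical k-mers of the two genomes and labels each as
#' host-only, graft-only, or shared. The index is the species-evidence
#' lookup used by [classify_read()] on reads that align to both genomes.
#'
#' @param host_fasta path to the host genome FASTA, or a named character
#'   vector of chromosome sequences.
#' @param graft_fasta graft genome, same forms accepted.
#' @param k odd k-mer length, at most 31 (11-31 recommended for real
#'   genomes; tiny fixtures may use less). Odd k prevents
#'   self-reverse-complement palindromes, so canonicalization is unambiguous.
#' @param host_name,graft_name labels stored for reporting.
#' @return an object of class `XenoKmerIndex` with elements `k`, `kmer`
#'   (canonical k-mer vector), `label` (parallel factor), `host_name`,
#'   `graft_name`.
#' @examples
#' idx <- build_kmer_index(c(chr1 = "AAAAAAAA"), c(chr1 = "CCCCCCCC"), k = 5)
#' table(idx$label)
#' @export
build_kmer_index <- function(host_fasta, graft_fasta, k = 25L,
                             host_name = "host", graft_name = "graft") {
  k <- as.integer(k)
  .check(k %% 2L == 1L, "k must be odd (got %d)", k)
  .check(k >= 3L && k <= 31L, "k must be in [3, 31] (got %d)", k)
  host <- if (is.character(host_fasta) && length(host_fasta) == 1L &&
              file.exists(host_fasta)) .read_fasta_chr(host_fasta) else host_fasta
  graft <- if (is.character(graft_fasta) && length(graft_fasta) == 1L &&
               file.exists(graft_fasta)) .read_fasta_chr(graft_fasta) else graft_fasta
  .check(length(host) > 0L && sum(nchar(host)) >= k,
         "host genome is empty or shorter than k")
  .check(length(graft) > 0L && sum(nchar(graft)) >= k,
         "graft genome is empty or shorter than k")

  hk <- .genome_canonical_kmers(host, k)
  gk <- .genome_canonical_kmers(graft, k)
  shared <- intersect(hk, gk)
  h_only <- setdiff(hk, shared)
  g_only <- setdiff(gk, shared)

  structure(list(
    k = k,
    kmer = c(h_only, g_only, shared),
    label = factor(rep(.KMER_LABELS, c(length(h_only), length(g_only),
                                       length(shared))), levels = .KMER_LABELS),
    host_name = host_name,
    graft_name = graft_name
  ), class = "XenoKmerIndex")
}

#' @export
print.XenoKmerIndex <- function(x, ...) {
  cat(sprintf("XenoKmerIndex k=%d (%s vs %s)\n", x$k, x$host_name, x$graft_name))
  print(table(x$label))
  invisible(x)
}

#' Classify reads into the five xenograft-sorting categories
#'
#' Counts, for every read, how many of its canonical k-mers are host-only
#' (`h`), graft-only (`g`) or shared (`s`) in the index, out of `m` valid
#' (ACGT-only) k-mers, and applies a deterministic decision rule, in order:
#' \enumerate{
#'   \item `(h+g+s)/m < min_frac_present` (or `m == 0`) -> `neither`
#'   \item `h >= min_specific` and `g == 0` -> `host`
#'   \item `g >= min_specific` and `h == 0` -> `graft`
#'   \item `h == 0` and `g == 0` -> `both`
#'   \item otherwise (conflicting or weak species-specific evidence) ->
#'     `ambiguous`
#' }
#' Requiring `min_specific` k-mers before a species call routes single-k-mer
#' evidence (one sequencing error can create one spurious specific k-mer) to
#' `ambiguous`, where the annotation-priority rescue decides.
#'
#' @param seqs character vector of read sequences, each at least `k` long.
#' @param index a [build_kmer_index()] result.
#' @param min_frac_present minimum fraction of a read's k-mers that must be
#'   present in the index before any species call is attempted.
#' @param min_specific minimum count of species-specific k-mers for a
#'   host/graft call.
#' @return data.frame with columns `label` (factor over the five calls),
#'   `h`, `g`, `s`, `m`; one row per read, rownames from `names(seqs)`.
#' @export
classify_reads <- function(seqs, index, min_frac_present = 0.5,
                           min_specific = 2L) {
  stopifnot(inherits(index, "XenoKmerIndex"))
  k <- index$k
  seqs <- toupper(seqs)
  .check(all(nchar(seqs) >= k),
         "all read sequences must be at least k=%d long", k)
  n <- length(seqs)
  if (n == 0L) {
    return(data.frame(label = factor(character(0), levels = .SPECIES_CALLS),
                      h = integer(0), g = integer(0), s = integer(0),
                      m = integer(0)))
  }
  nk <- nchar(seqs) - k + 1L
  ids <- rep.int(seq_len(n), nk)
  km <- unlist(lapply(seqs, .kmers, k = k), use.names = FALSE)
  valid <- !grepl("[^ACGT]", km)
  ids <- ids[valid]
  lab <- index$label[match(canonical_kmer(km[valid]), index$kmer)]

  m <- tabulate(ids, nbins = n)
  h <- tabulate(ids[!is.na(lab) & lab == "HOST_ONLY"], nbins = n)
  g <- tabulate(ids[!is.na(lab) & lab == "GRAFT_ONLY"], nbins = n)
  s <- tabulate(ids[!is.na(lab) & lab == "SHARED"], nbins = n)

  present <- h + g + s
  label <- rep("ambiguous", n)
  label[h >= min_specific & g == 0L] <- "host"
  label[g >= min_specific & h == 0L] <- "graft"
  label[h == 0L & g == 0L] <- "both"
  label[m == 0L | present / pmax(m, 1L) < min_frac_present] <- "neither"

  out <- data.frame(label = factor(label, levels = .SPECIES_CALLS),
                    h = h, g = g, s = s, m = m)
  rownames(out) <- names(seqs)
  out
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param sequence one read sequence.
#' @return a list of class `SpeciesCall` with `label`, `h`, `g`, `s`, `m`.
#' @export
classify_read <- function(sequence, index, min_frac_present = 0.5,
                          min_specific = 2L) {
  df <- classify_reads(sequence, index, min_frac_present, min_specific)
  structure(list(label = as.character(df$label), h = df$h, g = df$g,
                 s = df$s, m = df$m), class = "SpeciesCall")
}

#' Write a k-mer index to a tabular text file
#'
#' Plain TSV with a versioned header; round-trips with [read_kmer_index()].
#'
#' @param index a `XenoKmerIndex`.
#' @param path output file.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "XenoKmerIndex"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#xeno_kmer_index\t1",
               sprintf("#k\t%d", index$k),
               sprintf("#host\t%s", index$host_name),
               sprintf("#graft\t%s", index$graft_name)), con)
  utils::write.table(data.frame(kmer = index$kmer,
                                label = as.character(index$label)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  hdr <- readLines(path, n = 4L)
  .check(grepl("^#xeno_kmer_index", hdr[1]), "not a k-mer index file: %s", path)
  fields <- strsplit(hdr, "\t", fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", skip = 4L,
                           col.names = c("kmer", "label"),
                           colClasses = "character")
  structure(list(
    k = as.integer(fields[[2]][2]),
    kmer = tab$kmer,
    label = factor(tab$label, levels = .KMER_LABELS),
    host_name = fields[[3]][2],
    graft_name = fields[[4]][2]
  ), class = "XenoKmerIndex")
}
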