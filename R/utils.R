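# Small shared helpers for sequence handling.

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement for plain character vectors (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of one sequence, in order (character(0) if too short).
.kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (is.na(n) || n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

#' Canonicalize k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, so both strands map to one key.
#'
#' @param kmers character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# Random DNA sequence of length n under the current RNG state.
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases at a per-base rate; substitutions only, never to the
# same base. Returns the mutated string.
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# Hamming distance between two equal-length strings.
.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
.cigar_refwidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Read FASTA into a named character vector (upper case).
.read_fasta_chr <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dss)), sub("\\s.*$", "", names(dss)))
}

.write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) if (!ok) stop(sprintf(...), call. = FALSE)
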