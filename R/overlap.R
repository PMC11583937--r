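# Dual-genome alignment bookkeeping: partition reads by where they
# aligned, run the k-mer classifier on reads aligned in both species
# ("overlapping aligned reads"), and resolve both/ambiguous calls with the
# annotation-priority rescue rule.

.ROUTES <- c("unique_host", "unique_graft", "sorted_host", "sorted_graft",
             "rescued_host", "rescued_graft", "unresolved", "neither",
             "unaligned")

#' Read alignments from a SAM/BAM file
#'
#' Thin wrapper over Rsamtools that returns a flat data.frame of alignment
#' records with 0-based half-open reference coordinates.
#'
#' @param path SAM or BAM file.
#' @param species label attached to every record ("host" or "graft").
#' @return data.frame with `read_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mapq`, `secondary`, `n_hits` (NH tag where
#'   present, else per-read record count), `species`; unmapped records are
#'   dropped but their read ids are kept in the `unmapped` attribute.
#' @export
read_alignments <- function(path, species = "host") {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
    tag = c("NH", "CB", "UB")))[[1]]
  unmapped <- bitwAnd(res$flag, 4L) > 0L
  rw <- .cigar_refwidth(res$cigar[!unmapped])
  df <- data.frame(
    read_id = res$qname[!unmapped],
    chrom = as.character(res$rname[!unmapped]),
    start = res$pos[!unmapped] - 1L,
    end = res$pos[!unmapped] - 1L + rw,
    strand = as.character(res$strand[!unmapped]),
    mapq = res$mapq[!unmapped],
    secondary = bitwAnd(res$flag[!unmapped], 256L) > 0L,
    species = species,
    row.names = NULL)
  nh <- res$tag$NH
  df$n_hits <- if (!is.null(nh)) nh[!unmapped] else
    as.integer(table(df$read_id)[df$read_id])
  attr(df, "unmapped") <- unique(res$qname[unmapped])
  df
}

#' Partition reads by alignment presence in host and graft genomes
#'
#' A read is *overlapping* iff it has at least one (mapped) alignment in
#' each species. The four sets are disjoint and cover all tagged reads.
#'
#' @param host_aln,graft_aln alignment data.frames from
#'   [read_alignments()] (mapped records only).
#' @param read_ids character vector of all tagged read ids.
#' @return list of class `xeno_partition` with character-vector elements
#'   `host_unique`, `graft_unique`, `overlapping`, `unaligned`.
#' @export
partition_reads <- function(host_aln, graft_aln, read_ids) {
  h <- unique(host_aln$read_id)
  g <- unique(graft_aln$read_id)
  extra <- setdiff(union(h, g), read_ids)
  .check(length(extra) == 0L,
         "%d aligned reads absent from the tagged-read set (e.g. '%s'); pipeline order violated",
         length(extra), if (length(extra)) extra[1] else "")
  overlapping <- intersect(h, g)
  structure(list(
    host_unique = setdiff(h, g),
    graft_unique = setdiff(g, h),
    overlapping = overlapping,
    unaligned = setdiff(read_ids, union(h, g))
  ), class = "xeno_partition")
}

#' @export
print.xeno_partition <- function(x, ...) {
  cat(sprintf("xeno_partition: %d host-unique, %d graft-unique, %d overlapping, %d unaligned\n",
              length(x$host_unique), length(x$graft_unique),
              length(x$overlapping), length(x$unaligned)))
  invisible(x)
}

#' Annotation-priority rescue rule for both/ambiguous reads
#'
#' Compares the feature class of a read's best host alignment with that of
#' its best graft alignment. Priority: exonic (3) > intronic (2) >
#' intergenic (1) > pseudogene (0); the higher-priority species wins, equal
#' priority is a tie. Pseudogene ranks below intergenic: a pseudogene hit
#' is a homology artifact, weaker evidence than an anonymous intergenic
#' locus, and an exonic alignment in the other species should override it.
#'
#' @param host_feature,graft_feature character vectors of feature classes
#'   ("exonic", "intronic", "intergenic", "pseudogene").
#' @return character vector over `c("host", "graft", "tie")`.
#' @examples
#' priority_resolve("exonic", "intergenic")  # "host"
#' priority_resolve("pseudogene", "exonic")  # "graft"
#' @export
priority_resolve <- function(host_feature, graft_feature) {
  score <- c(exonic = 3, intronic = 2, intergenic = 1, pseudogene = 0)
  hs <- score[as.character(host_feature)]
  gs <- score[as.character(graft_feature)]
  .check(!anyNA(hs) && !anyNA(gs),
         "unknown feature class in priority_resolve")
  out <- rep("tie", length(hs))
  out[hs > gs] <- "host"
  out[hs < gs] <- "graft"
  out
}

# Feature of the primary alignment of each read, as a data.frame keyed by
# read_id. `aln` must carry `feature` and `gene_id` columns. Secondary
# records never outrank the primary's feature.
.primary_feature <- function(aln) {
  dt <- data.table::as.data.table(aln)
  data.table::setorder(dt, read_id, secondary, chrom, start)
  best <- dt[!duplicated(read_id)]
  data.frame(read_id = best$read_id,
             feature = as.character(best$feature),
             gene_id = best$gene_id, row.names = NULL)
}

#' Resolve overlapping aligned reads
#'
#' Applies [classify_reads()] to reads aligned in both genomes. K-mer calls
#' `host`/`graft` are routed directly (`sorted_host`/`sorted_graft`); calls
#' `both`/`ambiguous` fall to the annotation-priority rule
#' ([priority_resolve()]) on the two species' primary-alignment features
#' (`rescued_host`/`rescued_graft`, ties `unresolved`); call `neither`
#' routes to `neither` and is dropped from quantification.
#'
#' @param read_ids overlapping read ids.
#' @param seqs named character vector of read sequences (names = read ids).
#' @param index a [build_kmer_index()] result.
#' @param host_features,graft_features data.frames with `read_id`,
#'   `feature`, `gene_id` giving each read's primary-alignment feature in
#'   that species (see [annotate_intervals()]).
#' @param min_frac_present,min_specific passed to [classify_reads()].
#' @return data.frame with `read_id`, `call` (k-mer category), `route`,
#'   `final_species` ("host", "graft" or "unassigned").
#' @export
resolve_overlapping <- function(read_ids, seqs, index, host_features,
                                graft_features, min_frac_present = 0.5,
                                min_specific = 2L) {
  if (length(read_ids) == 0L) {
    return(data.frame(read_id = character(0), call = character(0),
                      route = character(0), final_species = character(0)))
  }
  .check(all(read_ids %in% names(seqs)),
         "missing read sequences for overlapping reads")
  cls <- classify_reads(seqs[read_ids], index, min_frac_present, min_specific)
  call <- as.character(cls$label)

  hf <- stats::setNames(as.character(host_features$feature),
                        host_features$read_id)[read_ids]
  gf <- stats::setNames(as.character(graft_features$feature),
                        graft_features$read_id)[read_ids]

  route <- character(length(read_ids))
  route[call == "host"] <- "sorted_host"
  route[call == "graft"] <- "sorted_graft"
  route[call == "neither"] <- "neither"
  amb <- call %in% c("both", "ambiguous")
  if (any(amb)) {
    .check(!anyNA(hf[amb]) && !anyNA(gf[amb]),
           "overlapping both/ambiguous reads lack feature annotations")
    win <- priority_resolve(hf[amb], gf[amb])
    route[amb] <- c(host = "rescued_host", graft = "rescued_graft",
                    tie = "unresolved")[win]
  }
  final_species <- rep("unassigned", length(read_ids))
  final_species[route %in% c("sorted_host", "rescued_host")] <- "host"
  final_species[route %in% c("sorted_graft", "rescued_graft")] <- "graft"
  data.frame(read_id = read_ids, call = call, route = route,
             final_species = final_species, row.names = NULL)
}
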