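# End-to-end orchestration: tag -> align -> annotate -> partition ->
# k-mer sort -> priority rescue -> multimapper filter -> UMI
# quantification -> MTX output, with a statistics report whose identities
# mirror the sorting-statistics table of a xenograft run.

.required_pipeline_fields <- c("r1", "r2", "host_fasta", "host_gtf",
                               "graft_fasta", "graft_gtf", "positions",
                               "out_dir")

#' Run the full xenograft sorting pipeline
#'
#' Executes every stage on one sample and writes two 10X-style matrix
#' trios (`<out>/host/`, `<out>/graft/`), a per-read assignment table and
#' a stats JSON. Alignments may be supplied (`host_sam`/`graft_sam`, from
#' any aligner) or produced by the built-in [toy_align()].
#'
#' @param config a named list, or path to a YAML file, with fields:
#'   `r1`, `r2` (FASTQ paths), `host_fasta`, `host_gtf`, `graft_fasta`,
#'   `graft_gtf`, `positions` (CSV with barcode,x,y columns), `out_dir`;
#'   optional: `host_sam`, `graft_sam`, `kmer_index` (prebuilt index
#'   file), `k` (default 25), `barcode_length` (16), `umi_length` (12),
#'   `whitelist_from_positions` (default TRUE: spot barcodes act as the
#'   whitelist), `min_frac_present` (0.5), `min_specific` (2),
#'   `exon_frac` (0.5), `include_intronic` (FALSE), `max_mismatch` (3).
#' @param quiet suppress stage banners.
#' @return list of class `xeno_run`: `stats`, `host_matrix`,
#'   `graft_matrix`, `assignments` (per-read data.frame), `partition`,
#'   `tags`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  missing_fields <- setdiff(.required_pipeline_fields, names(config))
  .check(length(missing_fields) == 0L,
         "pipeline config is missing required field(s): %s",
         paste(missing_fields, collapse = ", "))
  for (f in .required_pipeline_fields[.required_pipeline_fields != "out_dir"]) {
    .check(file.exists(config[[f]]), "input '%s' not found: %s", f,
           config[[f]])
  }
  opt <- function(name, default) if (is.null(config[[name]])) default else
    config[[name]]
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  elapsed <- function() sprintf("[%.1fs]",
                                as.numeric(Sys.time() - t0, units = "secs"))

  positions <- utils::read.csv(config$positions,
                               colClasses = c(barcode = "character"))

  say("== tagging reads %s", elapsed())
  rs <- read_structure(opt("barcode_length", 16L), opt("umi_length", 12L))
  wl <- if (isTRUE(opt("whitelist_from_positions", TRUE)))
    positions$barcode else NULL
  tags <- tag_reads(config$r1, config$r2, rs, whitelist = wl)
  seqs <- stats::setNames(tags$reads$sequence, tags$reads$read_id)

  say("== aligning %s", elapsed())
  mmx <- opt("max_mismatch", 3L)
  host_sam <- opt("host_sam", NULL)
  graft_sam <- opt("graft_sam", NULL)
  if (is.null(host_sam)) {
    host_sam <- tempfile("host_toy", fileext = ".sam")
    toy_align(seqs, config$host_fasta, host_sam, max_mismatch = mmx,
              tags = tags$reads)
  }
  if (is.null(graft_sam)) {
    graft_sam <- tempfile("graft_toy", fileext = ".sam")
    toy_align(seqs, config$graft_fasta, graft_sam, max_mismatch = mmx,
              tags = tags$reads)
  }
  host_aln <- read_alignments(host_sam, "host")
  graft_aln <- read_alignments(graft_sam, "graft")

  say("== annotating genomic features %s", elapsed())
  exon_frac <- opt("exon_frac", 0.5)
  host_fi <- build_feature_index(config$host_gtf)
  graft_fi <- build_feature_index(config$graft_gtf)
  ann_h <- annotate_intervals(host_fi, host_aln$chrom, host_aln$start,
                              host_aln$end, host_aln$strand, exon_frac)
  host_aln$feature <- ann_h$feature
  host_aln$gene_id <- ann_h$gene_id
  ann_g <- annotate_intervals(graft_fi, graft_aln$chrom, graft_aln$start,
                              graft_aln$end, graft_aln$strand, exon_frac)
  graft_aln$feature <- ann_g$feature
  graft_aln$gene_id <- ann_g$gene_id

  say("== building k-mer index %s", elapsed())
  index <- if (!is.null(config$kmer_index)) read_kmer_index(config$kmer_index)
    else build_kmer_index(config$host_fasta, config$graft_fasta,
                          k = opt("k", 25L))

  say("== partitioning and sorting reads %s", elapsed())
  part <- partition_reads(host_aln, graft_aln, tags$reads$read_id)
  hf <- .primary_feature(host_aln[host_aln$read_id %in% part$overlapping, ])
  gf <- .primary_feature(graft_aln[graft_aln$read_id %in% part$overlapping, ])
  res <- resolve_overlapping(part$overlapping, seqs, index, hf, gf,
                             opt("min_frac_present", 0.5),
                             opt("min_specific", 2L))

  set_df <- function(ids, route, species) {
    data.frame(read_id = ids, call = rep(NA_character_, length(ids)),
               route = rep(route, length(ids)),
               final_species = rep(species, length(ids)))
  }
  assignments <- rbind(
    set_df(part$host_unique, "unique_host", "host"),
    set_df(part$graft_unique, "unique_graft", "graft"),
    res,
    set_df(part$unaligned, "unaligned", "unassigned"))
  bc_of <- stats::setNames(tags$reads$barcode, tags$reads$read_id)
  umi_of <- stats::setNames(tags$reads$umi, tags$reads$read_id)
  assignments$barcode <- unname(bc_of[assignments$read_id])
  assignments$umi <- unname(umi_of[assignments$read_id])

  say("== filtering multimappers and quantifying %s", elapsed())
  include_intronic <- isTRUE(opt("include_intronic", FALSE))
  quantify_species <- function(aln, fi, species) {
    ids <- assignments$read_id[assignments$final_species == species]
    kept <- .filter_multimappers(aln[aln$read_id %in% ids, , drop = FALSE])
    kept$barcode <- unname(bc_of[kept$read_id])
    kept$umi <- unname(umi_of[kept$read_id])
    build_spot_matrix(kept, species, barcodes = positions$barcode,
                      gene_names = fi$gene_name,
                      genes = sort(names(fi$gene_name)),
                      include_intronic = include_intronic)
  }
  host_matrix <- quantify_species(host_aln, host_fi, "host")
  graft_matrix <- quantify_species(graft_aln, graft_fi, "graft")

  stats <- pipeline_stats(tags, part, res, host_matrix, graft_matrix)

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_matrix(host_matrix, file.path(out_dir, "host"))
  write_spot_matrix(graft_matrix, file.path(out_dir, "graft"))
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("== done %s", elapsed())

  structure(list(stats = stats, host_matrix = host_matrix,
                 graft_matrix = graft_matrix, assignments = assignments,
                 partition = part, tags = tags, out_dir = out_dir),
            class = "xeno_run")
}

#' Assemble the sorting-statistics report
#'
#' @param tags,part,res,host_matrix,graft_matrix stage outputs of
#'   [run_pipeline()].
#' @return nested list of per-species and global counts; the conservation
#'   identities among them are checked by [check_conservation()].
#' @export
pipeline_stats <- function(tags, part, res, host_matrix = NULL,
                           graft_matrix = NULL) {
  route <- res$route
  per_species <- function(sp) {
    uniq <- length(part[[paste0(sp, "_unique")]])
    sorted <- sum(route == paste0("sorted_", sp))
    rescued <- sum(route == paste0("rescued_", sp))
    list(total_aligned = uniq + length(part$overlapping),
         uniquely_aligned = uniq,
         sorted_by_kmer = sorted,
         rescued_by_priority = rescued,
         final_assigned = uniq + sorted + rescued)
  }
  out <- list(
    total_reads = tags$stats$accepted,
    tagging = tags$stats,
    host = per_species("host"),
    graft = per_species("graft"),
    overlapping = length(part$overlapping),
    unresolved = sum(route == "unresolved"),
    neither = sum(route == "neither"),
    unaligned = length(part$unaligned))
  if (!is.null(host_matrix)) {
    out$host$genes_detected <- sum(Matrix::rowSums(host_matrix$counts) > 0)
    out$host$umis <- sum(host_matrix$counts)
  }
  if (!is.null(graft_matrix)) {
    out$graft$genes_detected <- sum(Matrix::rowSums(graft_matrix$counts) > 0)
    out$graft$umis <- sum(graft_matrix$counts)
  }
  out
}

#' Check the conservation identities of a stats report
#'
#' Verifies that host-unique + graft-unique + overlapping + unaligned
#' equals the total tagged reads, that sorted + rescued + unresolved +
#' neither covers all overlapping reads, and that each species' final
#' assigned count equals unique + sorted + rescued.
#'
#' @param stats a [pipeline_stats()] result.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
check_conservation <- function(stats) {
  .check(stats$host$uniquely_aligned + stats$graft$uniquely_aligned +
           stats$overlapping + stats$unaligned == stats$total_reads,
         "partition does not conserve reads")
  .check(stats$host$sorted_by_kmer + stats$graft$sorted_by_kmer +
           stats$host$rescued_by_priority + stats$graft$rescued_by_priority +
           stats$unresolved + stats$neither == stats$overlapping,
         "overlapping routes do not conserve reads")
  for (sp in c("host", "graft")) {
    .check(stats[[sp]]$final_assigned == stats[[sp]]$uniquely_aligned +
             stats[[sp]]$sorted_by_kmer + stats[[sp]]$rescued_by_priority,
           "%s final assigned != unique + sorted + rescued", sp)
  }
  invisible(TRUE)
}

#' @export
print.xeno_run <- function(x, ...) {
  s <- x$stats
  cat(sprintf("xeno_run: %d reads | host %d assigned (%d unique + %d sorted + %d rescued) | graft %d (%d + %d + %d) | %d overlapping, %d unresolved, %d neither, %d unaligned\n",
              s$total_reads, s$host$final_assigned, s$host$uniquely_aligned,
              s$host$sorted_by_kmer, s$host$rescued_by_priority,
              s$graft$final_assigned, s$graft$uniquely_aligned,
              s$graft$sorted_by_kmer, s$graft$rescued_by_priority,
              s$overlapping, s$unresolved, s$neither, s$unaligned))
  invisible(x)
}

#' Simulate a dataset and run the pipeline on it
#'
#' Convenience wrapper used by tests and examples: generates the synthetic
#' genome pair and reads under `config`, runs [run_pipeline()], and scores
#' the assignments against the simulation truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param quiet passed to [run_pipeline()].
#' @return list: `run` (`xeno_run`), `genomes`, `reads`, `score`
#'   (`xeno_score`).
#' @export
simulate_and_run <- function(config = sim_config(),
                             out_dir = tempfile("xenorun"), quiet = TRUE) {
  genomes <- simulate_genome_pair(config, file.path(out_dir, "sim"))
  reads <- simulate_reads(genomes, config)
  run <- run_pipeline(list(
    r1 = reads$r1, r2 = reads$r2,
    host_fasta = genomes$host$fasta, host_gtf = genomes$host$gtf,
    graft_fasta = genomes$graft$fasta, graft_gtf = genomes$graft$gtf,
    positions = reads$positions_csv,
    out_dir = file.path(out_dir, "out")), quiet = quiet)
  score <- score_classification(reads$truth, run$assignments)
  list(run = run, genomes = genomes, reads = reads, score = score)
}
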