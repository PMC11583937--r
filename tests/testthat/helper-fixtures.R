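# Shared fixtures, built in code at test time.

write_fastq_fixture <- function(ids, seqs, path,
                                quals = strrep("I", nchar(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One full default-condition simulation + pipeline run, computed once per
# test session and reused by the acceptance-property tests.
.default_run_cache <- new.env(parent = emptyenv())
default_sim_run <- function() {
  if (is.null(.default_run_cache$res)) {
    .default_run_cache$res <- simulate_and_run(sim_config(seed = 1L),
                                               quiet = TRUE)
  }
  .default_run_cache$res
}

# Small-genome simulation shared by cheaper tests.
.small_run_cache <- new.env(parent = emptyenv())
small_sim_run <- function() {
  if (is.null(.small_run_cache$res)) {
    cfg <- sim_config(genome_length = 30000L, n_genes = 8L,
                      pseudogene_count = 2L, n_spots = 12L,
                      reads_per_spot = 40L, seed = 11L)
    .small_run_cache$res <- simulate_and_run(cfg, quiet = TRUE)
  }
  .small_run_cache$res
}

# Tiny GTF writer for feature-annotation tests: `genes` and `exons` are
# data.frames with 1-based inclusive coordinates.
write_gtf_fixture <- function(genes, exons, path) {
  glines <- sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
    genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id,
    genes$gene_name, genes$biotype)
  st <- setNames(genes$strand, genes$gene_id)
  ch <- setNames(genes$chrom, genes$gene_id)
  bio <- setNames(genes$biotype, genes$gene_id)
  nm <- setNames(genes$gene_name, genes$gene_id)
  elines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s"; transcript_id "%s.t1";',
    ch[exons$gene_id], exons$start, exons$end, st[exons$gene_id],
    exons$gene_id, nm[exons$gene_id], bio[exons$gene_id], exons$gene_id)
  writeLines(c(glines, elines), path)
  path
}
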