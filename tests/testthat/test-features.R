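# GTF feature index and locus annotation with the declared precedence.

simple_gtf <- function() {
  genes <- data.frame(chrom = "chr1", gene_id = "G1", gene_name = "G1",
                      biotype = "protein_coding", start = 101, end = 200,
                      strand = "+")
  exons <- data.frame(gene_id = "G1", start = 101, end = 150)
  write_gtf_fixture(genes, exons, tempfile(fileext = ".gtf"))
}

test_that("a one-gene GTF is indexed with its gene body and exon", {
  fi <- build_feature_index(simple_gtf())
  expect_equal(length(fi$genes), 1L)
  expect_equal(length(fi$exons), 1L)
  # GTF 1-based inclusive coordinates preserved internally
  expect_equal(GenomicRanges::start(fi$exons), 101L)
  expect_equal(GenomicRanges::end(fi$exons), 150L)
})

test_that("exonic, intronic, intergenic and strand rules apply", {
  fi <- build_feature_index(simple_gtf())
  # fully inside the exon (0-based half-open query)
  ex <- annotate_interval(fi, "chr1", 110, 130, "+")
  expect_equal(ex$value, "exonic")
  expect_equal(ex$gene_id, "G1")
  # inside the gene body, outside the exon
  expect_equal(annotate_interval(fi, "chr1", 159, 169, "+")$value, "intronic")
  # outside any gene
  inter <- annotate_interval(fi, "chr1", 300, 350, "+")
  expect_equal(inter$value, "intergenic")
  expect_true(is.na(inter$gene_id))
  # antisense overlap does not count
  expect_equal(annotate_interval(fi, "chr1", 110, 130, "-")$value,
               "intergenic")
  # unknown chromosome -> intergenic with a warning counter
  res <- annotate_intervals(fi, "chrUn", 10, 20, "+")
  expect_equal(as.character(res$feature), "intergenic")
  expect_equal(attr(res, "unknown_chrom"), 1L)
})

test_that("exonic overlap below the fraction threshold is intronic", {
  fi <- build_feature_index(simple_gtf())
  # 40 bases: 10 overlap the exon (25%) -> intronic at the default 50%
  expect_equal(annotate_interval(fi, "chr1", 140, 180, "+")$value,
               "intronic")
  expect_equal(annotate_interval(fi, "chr1", 140, 180, "+",
                                 exon_frac = 0.2)$value, "exonic")
})

test_that("a protein-coding exon outranks an overlapping pseudogene", {
  genes <- data.frame(chrom = "chr1",
                      gene_id = c("G1", "PS1"), gene_name = c("G1", "PS1"),
                      biotype = c("protein_coding", "processed_pseudogene"),
                      start = c(101, 101), end = c(200, 200),
                      strand = c("+", "+"))
  exons <- data.frame(gene_id = c("G1", "PS1"), start = c(101, 101),
                      end = c(150, 200))
  fi <- build_feature_index(write_gtf_fixture(genes, exons,
                                              tempfile(fileext = ".gtf")))
  hit <- annotate_interval(fi, "chr1", 110, 130, "+")
  expect_equal(hit$value, "exonic")
  expect_equal(hit$gene_id, "G1")
  # outside G1 entirely: only the pseudogene remains
  ps <- annotate_interval(fi, "chr1", 250, 270, "+")
  expect_equal(ps$value, "intergenic")
  ps2 <- annotate_interval(fi, "chr1", 160, 199, "+")
  expect_equal(ps2$value, "intronic")  # G1 body outranks PS1
})

test_that("a GTF record without gene_id errors with its line number", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\tgene\t1\t100\t.\t+\t.\tgene_id "G1"; gene_biotype "protein_coding";',
    'chr1\ttest\texon\t1\t50\t.\t+\t.\tsomething "else";'), f)
  expect_error(build_feature_index(f), "line 2")
})

test_that("annotation equals a linear-scan oracle on a simulated GTF", {
  cfg <- sim_config(genome_length = 60000L, n_genes = 25L,
                    pseudogene_count = 5L, seed = 33L)
  g <- simulate_genome_pair(cfg)
  fi <- build_feature_index(g$host$gtf)
  genes <- g$host$genes
  exons <- g$host$exons
  strand_of <- setNames(genes$strand, genes$gene_id)
  pseudo <- setNames(grepl("pseudogene", genes$biotype), genes$gene_id)

  # independent linear scan over the simulator's own gene tables
  oracle <- function(s0, e0, strand, frac = 0.5) {
    qs <- s0 + 1; qe <- e0  # 1-based inclusive
    ov <- function(a1, a2) max(0, min(a2, qe) - max(a1, qs) + 1)
    cover <- vapply(genes$gene_id, function(gid) {
      if (strand_of[gid] != strand) return(0)
      ex <- exons[exons$gene_id == gid, ]
      sum(vapply(seq_len(nrow(ex)),
                 function(i) ov(ex$start[i], ex$end[i]), numeric(1)))
    }, numeric(1))
    body <- vapply(seq_len(nrow(genes)), function(i) {
      if (genes$strand[i] != strand) return(0)
      ov(genes$start[i], genes$end[i])
    }, numeric(1))
    np <- !pseudo[genes$gene_id]
    best_ex <- cover * np
    if (max(best_ex) / (qe - qs + 1) >= frac) return("exonic")
    if (any(body[np] > 0)) return("intronic")
    if (any(body[!np] > 0)) return("pseudogene")
    "intergenic"
  }

  set.seed(5)
  s0 <- sample.int(59000, 300)
  e0 <- s0 + 90
  strand <- sample(c("+", "-"), 300, replace = TRUE)
  got <- annotate_intervals(fi, rep("chr1", 300), s0, e0, strand)
  want <- vapply(seq_along(s0), function(i) oracle(s0[i], e0[i], strand[i]),
                 character(1))
  expect_equal(as.character(got$feature), unname(want))
})

test_that("GTF coordinates round-trip through the index", {
  cfg <- sim_config(genome_length = 30000L, n_genes = 10L,
                    pseudogene_count = 0L, seed = 4L)
  g <- simulate_genome_pair(cfg)
  fi <- build_feature_index(g$graft$gtf)
  tab <- g$graft$genes
  idx_genes <- fi$genes[match(tab$gene_id, fi$genes$gene_id)]
  expect_equal(GenomicRanges::start(idx_genes), tab$start)
  expect_equal(GenomicRanges::end(idx_genes), tab$end)
  expect_equal(as.character(GenomicRanges::strand(idx_genes)), tab$strand)
})
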