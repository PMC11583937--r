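# Synthetic xenograft generator and the toy aligner.

tiny_cfg <- function(...) {
  args <- list(genome_length = 20000L, n_genes = 6L, pseudogene_count = 0L,
               n_spots = 8L, reads_per_spot = 25L, seed = 5L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("generators are byte-identical under a fixed seed", {
  g1 <- simulate_genome_pair(tiny_cfg())
  g2 <- simulate_genome_pair(tiny_cfg())
  expect_identical(readLines(g1$host$fasta), readLines(g2$host$fasta))
  expect_identical(readLines(g1$graft$gtf), readLines(g2$graft$gtf))
  r1 <- simulate_reads(g1)
  r2 <- simulate_reads(g2)
  expect_identical(readLines(r1$r2), readLines(r2$r2))
  expect_identical(readLines(r1$r1), readLines(r2$r1))
  # different seed changes the sequence
  g3 <- simulate_genome_pair(tiny_cfg(seed = 6L))
  expect_false(identical(readLines(g1$host$fasta),
                         readLines(g3$host$fasta)))
})

test_that("read and truth counts follow the configuration", {
  cfg <- tiny_cfg(n_spots = 20L, reads_per_spot = 10L)
  g <- simulate_genome_pair(cfg)
  r <- simulate_reads(g, cfg)
  fq <- readLines(r$r2)
  expect_equal(length(fq) / 4, 200)
  expect_equal(nrow(r$truth), 200)
  expect_equal(nrow(r$positions), 20)
  # R1 geometry: barcode + UMI
  r1 <- readLines(r$r1)
  expect_true(all(nchar(r1[seq(2, length(r1), 4)]) ==
                    cfg$barcode_length + cfg$umi_length))
})

test_that("shared_fraction controls the shared k-mer content", {
  g0 <- simulate_genome_pair(tiny_cfg(shared_fraction = 0))
  idx0 <- build_kmer_index(g0$host$fasta, g0$graft$fasta, k = 15)
  expect_lte(sum(idx0$label == "SHARED"), 2)  # chance collisions only
  g1 <- simulate_genome_pair(tiny_cfg(shared_fraction = 1, divergence = 0))
  idx1 <- build_kmer_index(g1$host$fasta, g1$graft$fasta, k = 15)
  # every k-mer of every graft gene body is an exact copy in the host
  gene_kmers <- unlist(lapply(seq_len(nrow(g1$graft$genes)), function(i) {
    body <- substr(g1$graft$seq, g1$graft$genes$start[i],
                   g1$graft$genes$end[i])
    xenosort:::.kmers(body, 15)
  }))
  lab <- idx1$label[match(canonical_kmer(gene_kmers), idx1$kmer)]
  expect_true(all(lab == "SHARED"))
})

test_that("an error-free read from a host-specific gene classifies as host", {
  cfg <- tiny_cfg(shared_fraction = 0.3, error_rate = 0)
  g <- simulate_genome_pair(cfg)
  r <- simulate_reads(g, cfg)
  idx <- build_kmer_index(g$host$fasta, g$graft$fasta, k = 25)
  spec_host <- r$truth[r$truth$true_species == "host" &
                         r$truth$true_region == "specific", ]
  fq <- readLines(r$r2)
  seqs <- setNames(fq[seq(2, length(fq), 4)],
                   sub("^@", "", fq[seq(1, length(fq), 4)]))
  take <- head(spec_host$read_id, 10)
  calls <- classify_reads(seqs[take], idx)
  expect_true(all(calls$label == "host"))
})

test_that("the toy aligner reports unique and duplicated loci with NH", {
  set.seed(55)
  block <- random_dna(120)
  genome <- c(chr1 = paste0(random_dna(500), block, random_dna(300),
                            block, random_dna(200)))
  reads <- c(uniq = substr(genome[[1]], 100, 189),
             dup = substr(block, 10, 99),
             lost = random_dna(90))
  sam <- tempfile(fileext = ".sam")
  toy_align(reads, genome, sam)
  aln <- read_alignments(sam, "host")
  expect_equal(sort(unique(aln$read_id)), c("dup", "uniq"))
  expect_equal(unique(aln$n_hits[aln$read_id == "uniq"]), 1L)
  expect_equal(unique(aln$n_hits[aln$read_id == "dup"]), 2L)
  expect_equal(aln$start[aln$read_id == "uniq"], 99L)  # 0-based
  expect_true("lost" %in% attr(aln, "unmapped"))
})

test_that("toy alignments equal an exhaustive Hamming-scan oracle", {
  set.seed(66)
  genome <- c(chr1 = random_dna(1500))
  gseq <- genome[[1]]
  # reads with 0-3 substitutions, both strands, plus one unalignable
  reads <- character(0)
  for (i in 1:12) {
    pos <- sample.int(1500 - 89, 1)
    frag <- substr(gseq, pos, pos + 89)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample.int(90, nmut)
      ch <- strsplit(frag, "")[[1]]
      for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1)
      frag <- paste(ch, collapse = "")
    }
    if (i %% 2 == 0) frag <- revcomp(frag)
    reads[sprintf("rd%02d", i)] <- frag
  }
  reads["none"] <- strrep("AC", 45)
  sam <- tempfile(fileext = ".sam")
  toy_align(reads, genome, sam, max_mismatch = 3)
  aln <- read_alignments(sam, "host")

  # oracle: slide every read (both orientations) along the genome
  oracle_hits <- function(read) {
    hits <- data.frame(start = integer(0), strand = character(0),
                       mm = integer(0))
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else revcomp(read)
      for (s in seq_len(nchar(gseq) - nchar(q) + 1)) {
        mm <- xenosort:::.hamming(q, substr(gseq, s, s + nchar(q) - 1))
        if (mm <= 3) hits <- rbind(hits,
                                   data.frame(start = s, strand = strand,
                                              mm = mm))
      }
    }
    if (nrow(hits) == 0) return(hits)
    hits[hits$mm == min(hits$mm), ]
  }
  for (id in names(reads)) {
    want <- oracle_hits(reads[[id]])
    got <- aln[aln$read_id == id, ]
    expect_equal(nrow(got), nrow(want), info = id)
    if (nrow(want) > 0) {
      o <- order(want$start)
      g <- order(got$start)
      expect_equal(got$start[g] + 1L, want$start[o], info = id)
      expect_equal(got$strand[g], want$strand[o], info = id)
    }
  }
})

test_that("truth rows, FASTQ records and SAM query names are conserved", {
  res <- small_sim_run()
  truth <- res$reads$truth
  fq <- readLines(res$reads$r2)
  expect_equal(nrow(truth), length(fq) / 4)
  # all truth reads appear in the pipeline assignment table exactly once
  expect_setequal(res$run$assignments$read_id, truth$read_id)
})

test_that("classification scoring matches a brute-force tally", {
  truth <- data.frame(read_id = sprintf("r%d", 1:6),
                      true_species = c("host", "host", "host", "graft",
                                       "graft", "graft"),
                      true_region = c("specific", "specific", "homologous",
                                      "specific", "homologous", "specific"))
  asg <- data.frame(read_id = sprintf("r%d", 1:5),
                    final_species = c("host", "graft", "host", "graft",
                                      "unassigned"))
  sc <- score_classification(truth, asg)
  expect_equal(as.vector(sc$confusion["host", ]), c(2L, 1L, 0L))
  expect_equal(as.vector(sc$confusion["graft", ]), c(0L, 1L, 2L))
  # specific reads: r1 ok, r2 wrong, r4 ok, r6 unassigned -> 2/4 correct
  expect_equal(sc$specific_accuracy, 0.5)
  expect_equal(sc$cross_misassignment, 0.25)  # r2 only
  expect_equal(sc$homologous_accuracy, 0.5)   # r3 ok, r5 unassigned
  # empty assignment set: everything lands in the unassigned column
  sc0 <- score_classification(truth,
                              data.frame(read_id = character(0),
                                         final_species = character(0)))
  expect_equal(sum(sc0$confusion[, "unassigned"]), 6L)
})
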