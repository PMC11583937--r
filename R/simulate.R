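# Ground-truthed synthetic xenograft data. A graft (human-like) genome and
# a host (mouse-like) genome are simulated with annotated genes; a
# configurable fraction of graft gene bodies is copied into the host at a
# controlled per-base divergence, emulating host/graft homology. Reads are
# drawn from exons with a spatially structured species mixture (graft-rich
# central disc = tumor epithelium, host-rich periphery = stroma), so every
# pipeline stage can be tested against known truth without downloads.

#' Simulation configuration
#'
#' Defaults describe a desk-scale xenograft: two 200 kb genomes, 40 genes
#' each, 30\% of graft genes copied into the host at 5\% per-base
#' divergence (placing roughly a quarter to a third of aligned reads in
#' the dual-alignment regime typical of PDX experiments), 4 pseudogene
#' copies per species, 50 Visium-style spots with 200 reads each, 90 bp
#' reads with 0.1\% sequencing error. Substitutions only - no indels - so
#' the bundled Hamming-distance aligner is an exact model of the data.
#'
#' @param genome_length genome length per species (bases).
#' @param shared_fraction fraction of graft genes copied into the host as
#'   homologous blocks.
#' @param divergence per-base substitution rate applied to copied blocks.
#' @param n_genes genes per species (before homolog copies).
#' @param pseudogene_count processed-pseudogene copies per species.
#' @param n_spots number of spatial spots (hexagonal spiral layout).
#' @param reads_per_spot read pairs per spot.
#' @param read_length cDNA (R2) read length.
#' @param error_rate per-base sequencing substitution rate.
#' @param seed integer seed; every generator is fully determined by it.
#' @param barcode_length,umi_length read 1 geometry.
#' @param center_graft_prop,periphery_graft_prop probability that a read
#'   from a central-disc / peripheral spot originates from the graft.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(genome_length = 200000L, shared_fraction = 0.3,
                       divergence = 0.05, n_genes = 40L,
                       pseudogene_count = 4L, n_spots = 50L,
                       reads_per_spot = 200L, read_length = 90L,
                       error_rate = 0.001, seed = 1L,
                       barcode_length = 16L, umi_length = 12L,
                       center_graft_prop = 0.9,
                       periphery_graft_prop = 0.1) {
  cfg <- list(genome_length = as.integer(genome_length),
              shared_fraction = shared_fraction, divergence = divergence,
              n_genes = as.integer(n_genes),
              pseudogene_count = as.integer(pseudogene_count),
              n_spots = as.integer(n_spots),
              reads_per_spot = as.integer(reads_per_spot),
              read_length = as.integer(read_length),
              error_rate = error_rate, seed = as.integer(seed),
              barcode_length = as.integer(barcode_length),
              umi_length = as.integer(umi_length),
              center_graft_prop = center_graft_prop,
              periphery_graft_prop = periphery_graft_prop,
              exon_length = 450L, intron_length = 300L, exons_per_gene = 2L)
  .check(cfg$shared_fraction >= 0 && cfg$shared_fraction <= 1 &&
           cfg$divergence >= 0 && cfg$divergence <= 1 &&
           cfg$error_rate >= 0 && cfg$error_rate <= 1,
         "fractions and rates must be in [0, 1]")
  .check(cfg$genome_length > 0 && cfg$n_genes > 0 && cfg$n_spots > 0 &&
           cfg$reads_per_spot > 0 && cfg$read_length > 0,
         "counts and lengths must be positive")
  structure(cfg, class = "SimConfig")
}

# One gene model: exons_per_gene exons of exon_length separated by
# intron_length, total body span.
.gene_span <- function(cfg) {
  cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
}

# Lay out n element starts in [1, genome_length - span], evenly slotted
# with jitter so elements never overlap.
.place_elements <- function(n, span, genome_length) {
  slot <- genome_length %/% n
  .check(slot > span + 10L,
         "genome too short: %d elements of span %d exceed genome length %d",
         n, span, genome_length)
  jitter <- sample.int(slot - span - 1L, n, replace = TRUE)
  as.integer((seq_len(n) - 1L) * slot + jitter)
}

# Build gene + exon tables for one species. Gene ids <prefix>G###; symbols
# human-style (upper) for graft, title-case for host.
.make_gene_tables <- function(starts, cfg, prefix, symbol_case) {
  n <- length(starts)
  span <- .gene_span(cfg)
  sym <- sprintf("GENE%d", seq_len(n))
  if (symbol_case == "title") {
    sym <- paste0(substr(sym, 1, 1), tolower(substr(sym, 2, nchar(sym))))
  }
  genes <- data.frame(
    gene_id = sprintf("%sG%03d", prefix, seq_len(n)),
    gene_name = sym,
    biotype = "protein_coding",
    chrom = "chr1",
    start = starts,
    end = starts + span - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    row.names = NULL)
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    es <- starts[i] +
      (seq_len(cfg$exons_per_gene) - 1L) * (cfg$exon_length + cfg$intron_length)
    data.frame(gene_id = genes$gene_id[i], start = es,
               end = es + cfg$exon_length - 1L)
  }))
  list(genes = genes, exons = exons)
}

# Write a species' annotation as GTF through rtracklayer.
.write_gtf <- function(genes, exons, path) {
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  name_of <- stats::setNames(genes$gene_name, genes$gene_id)
  bio_of <- stats::setNames(genes$biotype, genes$gene_id)
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end),
                              strand = genes$strand)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    type = "gene", gene_id = genes$gene_id, gene_name = genes$gene_name,
    gene_biotype = genes$biotype, transcript_id = NA_character_)
  e <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(exons$start, exons$end),
                              strand = strand_of[exons$gene_id])
  S4Vectors::mcols(e) <- S4Vectors::DataFrame(
    type = "exon", gene_id = exons$gene_id,
    gene_name = name_of[exons$gene_id],
    gene_biotype = bio_of[exons$gene_id],
    transcript_id = paste0(exons$gene_id, ".t1"))
  gr <- c(g, e)
  gr <- gr[order(GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# Replace genome[start..start+nchar(block)-1] with block.
.splice_in <- function(genome, start, block) {
  paste0(substr(genome, 1L, start - 1L), block,
         substr(genome, start + nchar(block), nchar(genome)))
}

#' Simulate an annotated host/graft genome pair with controlled homology
#'
#' The graft genome is random sequence annotated with `n_genes` two-exon
#' genes. The host genome carries its own `n_genes` genes plus, for a
#' `shared_fraction` sample of graft genes, a copy of the graft gene body
#' mutated at `divergence` - these homologous blocks are annotated as host
#' genes (mouse-style symbols) and drive dual-genome alignment. Each
#' species additionally receives `pseudogene_count` exact copies of one of
#' its own gene's first exons, annotated with a processed_pseudogene
#' biotype, creating within-species multimappers and pseudogene rescue
#' cases. Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir directory for FASTA/GTF outputs (created; default a
#'   fresh temporary directory).
#' @return list of class `xeno_sim_genomes` with per-species `fasta`,
#'   `gtf` paths, sequences and gene/exon tables, the `truth_regions`
#'   table (region = specific/homologous per gene), and the `homolog_map`
#'   (human_symbol, mouse_symbol).
#' @export
simulate_genome_pair <- function(config = sim_config(),
                                 out_dir = tempfile("xenosim")) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  span <- .gene_span(config)
  n_shared <- as.integer(round(config$shared_fraction * config$n_genes))

  # graft: own genes + pseudogene copies
  graft_seq <- .random_dna(config$genome_length)
  g_slots <- .place_elements(config$n_genes + config$pseudogene_count,
                             span, config$genome_length)
  g_tab <- .make_gene_tables(g_slots[seq_len(config$n_genes)], config,
                             "hs", "upper")

  # host: own genes + homolog copies of shared graft genes + pseudogenes
  host_seq <- .random_dna(config$genome_length)
  h_slots <- .place_elements(config$n_genes + n_shared + config$pseudogene_count,
                             span, config$genome_length)
  h_tab <- .make_gene_tables(h_slots[seq_len(config$n_genes)], config,
                             "mm", "title")
  h_tab$genes$gene_name <- sub("^Gene", "Geneh", h_tab$genes$gene_name)

  shared_idx <- sort(sample.int(config$n_genes, n_shared))
  homolog_map <- data.frame(human_symbol = character(0),
                            mouse_symbol = character(0))
  if (n_shared > 0L) {
    hom_starts <- h_slots[config$n_genes + seq_len(n_shared)]
    hom_genes <- g_tab$genes[shared_idx, ]
    hom_tab <- .make_gene_tables(hom_starts, config, "mmHOM", "title")
    # homolog symbol mirrors the graft symbol in mouse case
    hom_tab$genes$gene_name <- paste0(
      "Gene", sub("^GENE", "", hom_genes$gene_name))
    hom_tab$genes$strand <- hom_genes$strand
    for (i in seq_len(n_shared)) {
      block <- substr(graft_seq, hom_genes$start[i], hom_genes$end[i])
      block <- .mutate_seq(block, config$divergence)
      host_seq <- .splice_in(host_seq, hom_starts[i], block)
    }
    h_tab$genes <- rbind(h_tab$genes, hom_tab$genes)
    h_tab$exons <- rbind(h_tab$exons, hom_tab$exons)
    homolog_map <- data.frame(human_symbol = hom_genes$gene_name,
                              mouse_symbol = hom_tab$genes$gene_name)
  }

  # Processed pseudogenes: exact retrocopies of a source gene's first
  # exon. Half copy the species' own genes (creating within-species
  # multimappers that exercise the multimapper filter); the other half
  # copy the *other* species' genes - the cross-species homology trap
  # that the annotation-priority rescue exists for: a read from the
  # source exon then aligns exonic in its own species but pseudogenic in
  # the other, and exonic evidence must win.
  exon1_seq <- function(tab, seq, gid) {
    ex1 <- tab$exons[tab$exons$gene_id == gid, ][1, ]
    substr(seq, ex1$start, ex1$end)
  }
  n_own <- ceiling(config$pseudogene_count / 2)
  cross_src <- list(graft = character(0), host = character(0))
  add_pseudo <- function(seq, tab, other_tab, other_seq, slots, prefix) {
    np <- config$pseudogene_count
    if (np == 0L) return(list(seq = seq, tab = tab, cross = character(0)))
    own_src <- sample.int(config$n_genes, min(n_own, np))
    oth_src <- if (np > length(own_src))
      sample.int(config$n_genes, np - length(own_src)) else integer(0)
    blocks <- c(
      vapply(own_src, function(i)
        exon1_seq(tab, seq, tab$genes$gene_id[i]), character(1)),
      vapply(oth_src, function(i)
        exon1_seq(other_tab, other_seq, other_tab$genes$gene_id[i]),
        character(1)))
    ps <- data.frame(
      gene_id = sprintf("%sPS%03d", prefix, seq_len(np)),
      gene_name = sprintf("%sPS%03d", prefix, seq_len(np)),
      biotype = "processed_pseudogene",
      chrom = "chr1",
      start = slots,
      end = slots + config$exon_length - 1L,
      strand = sample(c("+", "-"), np, replace = TRUE),
      row.names = NULL)
    for (i in seq_len(np)) seq <- .splice_in(seq, slots[i], blocks[i])
    tab$genes <- rbind(tab$genes, ps)
    tab$exons <- rbind(tab$exons,
                       data.frame(gene_id = ps$gene_id, start = ps$start,
                                  end = ps$end))
    list(seq = seq, tab = tab,
         cross = other_tab$genes$gene_id[oth_src])
  }
  gp <- add_pseudo(graft_seq, g_tab, h_tab, host_seq,
                   g_slots[config$n_genes + seq_len(config$pseudogene_count)],
                   "hs")
  graft_seq <- gp$seq; g_tab <- gp$tab; cross_src$host <- gp$cross
  hp <- add_pseudo(host_seq, h_tab, g_tab, graft_seq,
                   h_slots[config$n_genes + n_shared +
                             seq_len(config$pseudogene_count)], "mm")
  host_seq <- hp$seq; h_tab <- hp$tab; cross_src$graft <- hp$cross

  # a gene region is homologous when any cross-species copy of it exists:
  # a diverged homolog gene or an exact pseudogene retrocopy
  g_homologous <- g_tab$genes$gene_id %in%
    c(g_tab$genes$gene_id[shared_idx], cross_src$graft)
  h_homologous <- grepl("^mmHOM", h_tab$genes$gene_id) |
    h_tab$genes$gene_id %in% cross_src$host
  truth_regions <- rbind(
    data.frame(species = "graft", gene_id = g_tab$genes$gene_id,
               start = g_tab$genes$start, end = g_tab$genes$end,
               region = ifelse(g_homologous, "homologous", "specific"),
               biotype = g_tab$genes$biotype),
    data.frame(species = "host", gene_id = h_tab$genes$gene_id,
               start = h_tab$genes$start, end = h_tab$genes$end,
               region = ifelse(h_homologous, "homologous", "specific"),
               biotype = h_tab$genes$biotype))

  host_fasta <- file.path(out_dir, "host.fa")
  graft_fasta <- file.path(out_dir, "graft.fa")
  host_gtf <- file.path(out_dir, "host.gtf")
  graft_gtf <- file.path(out_dir, "graft.gtf")
  .write_fasta(c(chr1 = host_seq), host_fasta)
  .write_fasta(c(chr1 = graft_seq), graft_fasta)
  .write_gtf(h_tab$genes, h_tab$exons, host_gtf)
  .write_gtf(g_tab$genes, g_tab$exons, graft_gtf)

  structure(list(
    host = list(fasta = host_fasta, gtf = host_gtf, seq = host_seq,
                genes = h_tab$genes, exons = h_tab$exons),
    graft = list(fasta = graft_fasta, gtf = graft_gtf, seq = graft_seq,
                 genes = g_tab$genes, exons = g_tab$exons),
    truth_regions = truth_regions,
    homolog_map = homolog_map,
    config = config,
    out_dir = out_dir
  ), class = "xeno_sim_genomes")
}

# Hexagonal spiral of n points around the origin, unit spacing.
.hex_spiral <- function(n) {
  ax <- matrix(0, nrow = 0, ncol = 2)
  q <- r <- 0L
  ax <- rbind(ax, c(0L, 0L))
  dirs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  ring <- 1L
  while (nrow(ax) < n) {
    q <- -ring; r <- ring  # start of ring (axial)
    for (d in seq_len(6)) {
      for (s in seq_len(ring)) {
        if (nrow(ax) >= n) break
        ax <- rbind(ax, c(q, r))
        q <- q + dirs[d, 1]; r <- r + dirs[d, 2]
      }
    }
    ring <- ring + 1L
  }
  ax <- ax[seq_len(n), , drop = FALSE]
  data.frame(array_row = ax[, 2], array_col = ax[, 1],
             x = ax[, 1] + ax[, 2] / 2, y = ax[, 2] * sqrt(3) / 2)
}

#' Simulate spatially structured xenograft reads
#'
#' Spots lie on a hexagonal spiral; spots within half the maximum radius
#' of the centroid draw reads from the graft with probability
#' `center_graft_prop` (epithelium-like), peripheral spots with
#' `periphery_graft_prop` (stroma-like). Each read is an exonic fragment
#' of a randomly chosen non-pseudogene gene of the drawn species, read on
#' the gene's strand, with substitution errors at `error_rate`. R1 is
#' barcode + UMI in the Visium geometry. Deterministic under the seed.
#'
#' @param genomes a [simulate_genome_pair()] result.
#' @param config the same [sim_config()].
#' @param out_dir output directory (default: the genomes' directory).
#' @return list of class `xeno_sim_reads`: `r1`, `r2` FASTQ paths,
#'   `positions` (data.frame + `positions_csv` path), `truth` (per-read
#'   truth data.frame + `truth_tsv` path).
#' @export
simulate_reads <- function(genomes, config = genomes$config,
                           out_dir = genomes$out_dir) {
  stopifnot(inherits(genomes, "xeno_sim_genomes"))
  set.seed(config$seed + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rl <- config$read_length
  .check(rl <= config$exon_length,
         "read_length %d exceeds the shortest exon (%d)", rl,
         config$exon_length)

  hex <- .hex_spiral(config$n_spots)
  radius <- sqrt(hex$x^2 + hex$y^2)
  central <- radius <= max(radius) / 2
  barcodes <- character(0)
  while (length(barcodes) < config$n_spots) {
    barcodes <- unique(c(barcodes, vapply(
      seq_len(config$n_spots - length(barcodes)),
      function(i) .random_dna(config$barcode_length), character(1))))
  }
  positions <- data.frame(barcode = barcodes, in_tissue = 1L,
                          array_row = hex$array_row,
                          array_col = hex$array_col, x = hex$x, y = hex$y)

  pick_from <- function(side) {
    tab <- genomes[[side]]
    ok <- tab$genes$biotype != "processed_pseudogene"
    tab$genes$gene_id[ok]
  }
  host_genes <- pick_from("host")
  graft_genes <- pick_from("graft")
  exon_of <- list(host = split(genomes$host$exons, genomes$host$exons$gene_id),
                  graft = split(genomes$graft$exons,
                                genomes$graft$exons$gene_id))
  strand_of <- list(
    host = stats::setNames(genomes$host$genes$strand,
                           genomes$host$genes$gene_id),
    graft = stats::setNames(genomes$graft$genes$strand,
                            genomes$graft$genes$gene_id))
  region_of <- stats::setNames(genomes$truth_regions$region,
                               genomes$truth_regions$gene_id)

  n_reads <- config$n_spots * config$reads_per_spot
  spot_idx <- rep(seq_len(config$n_spots), each = config$reads_per_spot)
  p_graft <- ifelse(central[spot_idx], config$center_graft_prop,
                    config$periphery_graft_prop)
  species <- ifelse(stats::runif(n_reads) < p_graft, "graft", "host")
  gene <- character(n_reads)
  gene[species == "host"] <- sample(host_genes, sum(species == "host"),
                                    replace = TRUE)
  gene[species == "graft"] <- sample(graft_genes, sum(species == "graft"),
                                     replace = TRUE)

  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    ex <- exon_of[[species[i]]][[gene[i]]]
    ex <- ex[ex$end - ex$start + 1L >= rl, , drop = FALSE]
    .check(nrow(ex) > 0L, "no exon of gene %s can hold a %d bp read",
           gene[i], rl)
    e <- ex[sample.int(nrow(ex), 1L), ]
    s <- e$start + sample.int(e$end - e$start - rl + 2L, 1L) - 1L
    frag <- substr(genomes[[species[i]]]$seq, s, s + rl - 1L)
    if (strand_of[[species[i]]][gene[i]] == "-") frag <- revcomp(frag)
    seqs[i] <- .mutate_seq(frag, config$error_rate)
  }

  umis <- vapply(seq_len(n_reads),
                 function(i) .random_dna(config$umi_length), character(1))
  read_id <- sprintf("read%06d", seq_len(n_reads))
  r1_seq <- paste0(barcodes[spot_idx], umis)

  r1_path <- file.path(out_dir, "reads_R1.fastq")
  r2_path <- file.path(out_dir, "reads_R2.fastq")
  .write_fastq(read_id, r1_seq, r1_path)
  .write_fastq(read_id, seqs, r2_path)

  truth <- data.frame(read_id = read_id, true_species = species,
                      true_gene = gene,
                      true_region = unname(region_of[gene]),
                      barcode = barcodes[spot_idx],
                      x = hex$x[spot_idx], y = hex$y[spot_idx])
  pos_csv <- file.path(out_dir, "positions.csv")
  utils::write.csv(positions, pos_csv, row.names = FALSE, quote = FALSE)
  truth_tsv <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(r1 = r1_path, r2 = r2_path, positions = positions,
                 positions_csv = pos_csv, truth = truth,
                 truth_tsv = truth_tsv),
            class = "xeno_sim_reads")
}

.write_fastq <- function(ids, seqs, path) {
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}

#' Exhaustive seed-and-extend toy aligner
#'
#' A deliberately simple ungapped aligner for desk-scale genomes: exact
#' 20-mer seeds at staggered offsets (pigeonhole-complete for up to
#' `max_mismatch` substitutions when the read covers four seed windows),
#' full-read Hamming extension on both strands, reporting *all* equally
#' best loci within `max_mismatch`, with the NH tag set. Unaligned reads
#' are emitted as unmapped records so read populations are conserved.
#'
#' @param reads path to a FASTQ file, or a named character vector of read
#'   sequences.
#' @param genome_fasta path to the genome FASTA (or named character
#'   vector of chromosomes).
#' @param out_sam output SAM path.
#' @param max_mismatch maximum substitutions for a reported alignment.
#' @param seed_len exact seed length (default 20).
#' @param tags optional data.frame (`read_id`, `barcode`, `umi`) whose
#'   barcodes/UMIs are written as CB/UB tags.
#' @return `out_sam`, invisibly; attribute `alignments` holds the
#'   alignment data.frame.
#' @export
toy_align <- function(reads, genome_fasta, out_sam,
                      max_mismatch = 3L, seed_len = 20L, tags = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- .read_fastq(reads)
    quals <- stats::setNames(fq$qualities, fq$read_id)
    reads <- stats::setNames(fq$sequence, fq$read_id)
  } else {
    quals <- stats::setNames(strrep("I", nchar(reads)), names(reads))
  }
  genome <- if (is.character(genome_fasta) && length(genome_fasta) == 1L &&
                file.exists(genome_fasta)) .read_fasta_chr(genome_fasta)
            else genome_fasta
  .check(sum(nchar(genome)) <= 5e6,
         "toy aligner is for genomes up to ~5 Mb")
  .check(all(nchar(reads) >= seed_len), "reads shorter than the seed length")

  # genome seed table: every seed_len-mer with its position
  gdt <- data.table::rbindlist(lapply(names(genome), function(ch) {
    km <- .kmers(genome[[ch]], seed_len)
    data.table::data.table(kmer = km, chrom = ch, gpos = seq_along(km))
  }))
  data.table::setkey(gdt, kmer)

  rl <- nchar(reads)
  fwd <- unname(reads)
  rev <- revcomp(fwd)
  # staggered seed offsets per read (1-based); pigeonhole-complete for
  # max_mismatch substitutions when the read holds enough disjoint windows
  offsets_of <- function(len) unique(c(seq(1L, len - seed_len + 1L,
                                           by = seed_len),
                                       len - seed_len + 1L))
  seed_one_strand <- function(seqs, strand) {
    if (length(unique(rl)) == 1L) {
      off <- offsets_of(rl[1])
      data.table::data.table(
        ri = rep(seq_along(seqs), each = length(off)),
        strand = strand,
        off = rep(off, length(seqs)),
        kmer = substring(rep(seqs, each = length(off)),
                         rep(off, length(seqs)),
                         rep(off, length(seqs)) + seed_len - 1L))
    } else {
      data.table::rbindlist(lapply(seq_along(seqs), function(i) {
        off <- offsets_of(rl[i])
        data.table::data.table(ri = i, strand = strand, off = off,
                               kmer = substring(seqs[i], off,
                                                off + seed_len - 1L))
      }))
    }
  }
  seed_dt <- data.table::rbindlist(list(seed_one_strand(fwd, "+"),
                                        seed_one_strand(rev, "-")))

  cand <- gdt[seed_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  chrlen <- stats::setNames(nchar(genome), names(genome))
  if (nrow(cand) > 0L) {
    cand[, start := gpos - off + 1L]
    cand <- cand[start >= 1L & start + rl[ri] - 1L <= chrlen[chrom]]
    cand <- unique(cand[, .(ri, strand, chrom, start)])
  }

  aln <- NULL
  if (!is.null(cand) && nrow(cand) > 0L) {
    qseq <- ifelse(cand$strand == "+", fwd[cand$ri], rev[cand$ri])
    mmv <- integer(nrow(cand))
    for (ch in unique(cand$chrom)) {
      ii <- which(cand$chrom == ch)
      gs <- substring(genome[[ch]], cand$start[ii],
                      cand$start[ii] + rl[cand$ri[ii]] - 1L)
      mmv[ii] <- vapply(seq_along(ii),
                        function(j) .hamming(qseq[ii[j]], gs[j]), integer(1))
    }
    cand[, mm := mmv]
    cand <- cand[mm <= max_mismatch]
    if (nrow(cand) > 0L) {
      cand[, best := min(mm), by = ri]
      aln <- cand[mm == best]
      data.table::setorder(aln, ri, chrom, start, strand)
      aln[, nh := .N, by = ri]
      aln[, primary := !duplicated(ri)]
    }
  }

  ids <- names(reads)
  tag_suffix <- rep("", length(reads))
  if (!is.null(tags)) {
    bc <- stats::setNames(tags$barcode, tags$read_id)[ids]
    um <- stats::setNames(tags$umi, tags$read_id)[ids]
    tag_suffix <- sprintf("\tCB:Z:%s\tUB:Z:%s", bc, um)
  }

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
           "@PG\tID:toyalign\tPN:toyalign")
  recs <- character(0)
  mapped <- integer(0)
  if (!is.null(aln) && nrow(aln) > 0L) {
    mapped <- unique(aln$ri)
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(aln$primary, 0L, 256L)
    seq_out <- ifelse(aln$strand == "+", fwd[aln$ri], rev[aln$ri])
    qual_out <- unname(quals[ids[aln$ri]])
    qual_out <- ifelse(aln$strand == "+", qual_out,
                       vapply(qual_out, function(q)
                         paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                         character(1)))
    recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d%s",
                    ids[aln$ri], flag, aln$chrom, aln$start,
                    ifelse(aln$nh == 1L, 255L, 3L), rl[aln$ri],
                    seq_out, qual_out, aln$nh, tag_suffix[aln$ri])
  }
  un <- setdiff(seq_along(reads), mapped)
  if (length(un) > 0L) {
    recs <- c(recs,
              sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s%s",
                      ids[un], fwd[un], unname(quals[ids[un]]),
                      tag_suffix[un]))
  }
  writeLines(c(hdr, recs), out_sam)
  out <- invisible(out_sam)
  attr(out, "alignments") <- if (is.null(aln)) NULL else as.data.frame(aln)
  out
}

#' Score pipeline assignments against simulation truth
#'
#' Builds the 2x3 confusion matrix (true species x assigned
#' host/graft/unassigned) and reports assignment accuracy separately for
#' reads from species-specific regions and from homologous regions, plus
#' the cross-species misassignment rate on specific-region reads.
#'
#' @param truth per-read truth data.frame from [simulate_reads()].
#' @param assignments data.frame with `read_id` and `final_species`
#'   ("host"/"graft"/"unassigned"); reads missing from it count as
#'   unassigned.
#' @return list of class `xeno_score`: `confusion`, `specific_accuracy`,
#'   `homologous_accuracy`, `cross_misassignment`.
#' @export
score_classification <- function(truth, assignments) {
  .check(all(assignments$read_id %in% truth$read_id),
         "assignment read ids not in the truth table")
  assigned <- stats::setNames(rep("unassigned", nrow(truth)), truth$read_id)
  hit <- assignments$read_id[assignments$final_species %in% c("host", "graft")]
  assigned[hit] <- assignments$final_species[
    assignments$final_species %in% c("host", "graft")]
  conf <- table(true = factor(truth$true_species, c("host", "graft")),
                assigned = factor(assigned[truth$read_id],
                                  c("host", "graft", "unassigned")))
  spec <- truth$true_region == "specific"
  correct <- assigned[truth$read_id] == truth$true_species
  wrong_species <- assigned[truth$read_id] %in% c("host", "graft") & !correct
  structure(list(
    confusion = conf,
    specific_accuracy = mean(correct[spec]),
    homologous_accuracy = if (any(!spec)) mean(correct[!spec]) else NA_real_,
    cross_misassignment = mean(wrong_species[spec])
  ), class = "xeno_score")
}

#' @export
print.xeno_score <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("specific-region accuracy:  %.4f\n", x$specific_accuracy))
  cat(sprintf("homologous-region accuracy: %.4f\n", x$homologous_accuracy))
  cat(sprintf("cross-misassignment (specific): %.4f\n",
              x$cross_misassignment))
  invisible(x)
}
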