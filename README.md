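# xenosort

Host/graft read sorting for xenograft spatial transcriptomics.

## The problem

Patient-derived xenografts (PDX) grow human tumor tissue (the **graft**,
typically epithelium) in a mouse (the **host**, typically stroma).
Spatially resolved transcriptomics of a PDX section yields a mixture of
human and mouse reads, and — because xenografts require strong host/graft
homology — a sizable fraction of reads aligns to *both* genomes.
Standard spatial pipelines have no mechanism for apportioning these
reads, so conserved genes leak between species and stroma–epithelium
signaling analyses are built on contaminated matrices.

xenosort assigns every spatially barcoded read to host or graft:

* reads aligned in both genomes are classified against a **canonical
  k-mer index** of the genome pair into host / graft / both / ambiguous /
  neither;
* `both`/`ambiguous` reads are **rescued** by an annotation-priority rule
  — exonic > intronic > intergenic > pseudogene — comparing each
  species' alignment locus, so an exonic alignment overrides an
  intergenic or pseudogenic one in the other species;
* multimappers are filtered (kept only with exactly one exonic
  alignment), UMIs deduplicated per (barcode, gene, UMI) triple, and one
  sparse barcode-by-gene matrix written per species (10X-style MTX trio).

Downstream, the package computes host/graft homolog expression
comparisons, Shannon-entropy cell-type specificity (bits), and
permutation z-scores for spatial ligand–receptor co-localization within
and across the stroma/epithelium compartments:

    S = Σ_i L(i)R(i) + Σ_{(i,j) adjacent} [ L(i)R(j) + L(j)R(i) ]
    z = (S − mean(S_perm)) / sd(S_perm)

with L and R permuted independently across spots in the null.

A ground-truthed synthetic xenograft simulator (genome pair with
controlled homology and pseudogene traps, hexagonal spot layout,
spatially structured reads, exhaustive toy aligner) makes the entire
pipeline testable with no downloads; every simulated read carries a truth
row, so assignment accuracy is measurable exactly.

## Worked example

```r
library(xenosort)

cfg <- sim_config(seed = 1)        # default synthetic study conditions
res <- simulate_and_run(cfg)

res$run
#> xeno_run: 10000 reads | host 5965 assigned (5365 unique + 479 sorted +
#>   121 rescued) | graft 4003 (3476 + 438 + 89) | 1159 overlapping,
#>   30 unresolved, 2 neither, 0 unaligned

res$score
#>        assigned
#> true    host graft unassigned
#>   host  5965     0         16
#>   graft    0  4003         16
#> specific-region accuracy:  1.0000
#> homologous-region accuracy: 0.9889
#> cross-misassignment (specific): 0.0000
```

Reading the output: of 10,000 simulated reads, 1,159 aligned to both
genomes (the homology regime the sorter exists for). The k-mer classifier
resolved 479 + 438 of them directly; the annotation-priority rescue
recovered another 121 + 89 that pure k-mer evidence could not decide.
Only priority ties (30) and index-absent reads (2) stay unassigned — they
are excluded from both matrices rather than double-counted. Every read
from a species-specific region is assigned to the correct species and no
read is assigned across species.

The two matrices land in `res$run$out_dir` as
`host/{matrix.mtx,barcodes.tsv,features.tsv}` and likewise `graft/`,
ready for Seurat/scanpy-style loaders, alongside `stats.json` and a
per-read `assignments.tsv`.

## Command line

A thin dispatcher over the package functions is installed at
`inst/cli/xeno.R`:

```sh
Rscript inst/cli/xeno.R simulate --out sim --seed 1
Rscript inst/cli/xeno.R index --host sim/host.fa --graft sim/graft.fa -k 25 --out idx.tsv
Rscript inst/cli/xeno.R run --config run.yaml
```

See `vignettes/xenograft-read-sorting.Rmd` for the model, parameter
rationale, and the simulator's scope.
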