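# AREscan

Antioxidant response element (ARE) discovery by ChIP-supported PSSM
scanning of gene regulatory regions.

## The problem

NRF2 (NFE2L2) and its small-MAF partners (MAFF/MAFG/MAFK, with BACH1 as a
competitor) bind AREs — 11-bp motifs with consensus `NTGACnnnGCn` — in the
promoters of antioxidant and, as it turns out, epigenetic-regulator genes.
Predicting candidate AREs for a gene set requires combining three kinds of
evidence:

1. **sequence**: how well an 11-mer matches the NRF2 binding profile
   (JASPAR matrix MA0150.1);
2. **occupancy**: whether the site lies inside a ChIP-seq peak for any
   ARE-binding factor;
3. **context**: whether it falls in the gene's regulatory neighbourhood —
   the transcript plus 5 000 bp upstream of the TSS — and in which
   regulatory-segmentation state (TSS, enhancer, transcribed, ...).

AREscan implements this analysis as a tested R pipeline, plus a seeded
synthetic-data generator so every stage is verifiable without genome or
ChIP-Atlas downloads.

## The score

A position frequency matrix `n(b, j)` (base *b*, position *j*) is converted
to a log2-odds PSSM with a pseudocount (default 1):

    score(b, j) = log2( ((n(b,j) + 1) / (N_j + 4)) / p_b )

with `N_j` the column count sum and `p_b` the background probability
(default uniform 0.25). A window's absolute score is the sum of its
per-position scores, and its **relative score** is

    (absolute + |minScore|) / (|maxScore| + |minScore|)

where maxScore/minScore are the best and worst achievable window scores, so
the optimal 11-mer scores exactly 1.0. Sites with relative score below 0.8
are discarded (the threshold is inclusive: ≥ 0.8 is kept); both strands are
scanned.

## Worked example

```r
library(AREscan)

pssm <- build_pssm(read_jaspar_pfm(ma0150_pfm_path()))
relative_score(pssm, score_window(pssm, "ATGACTCAGCA"))
#> [1] 1
relative_score(pssm, score_window(pssm, "CTGACTCAGCC"))
#> [1] 0.8830129

# a fully synthetic scenario: genome + peaks + transcript + segmentation
sc <- generate_scenario(seed = 3, out_dir = tempfile("demo"))
rows <- run_pipeline(sc$config)
rows[, c("gene", "coordinates", "motif", "rel_score_rounded",
         "strand", "regulatory_elements", "tfs")]
```

```
     gene    coordinates       motif rel_score_rounded strand regulatory_elements    tfs
1 SynGene chrS:1443-1454 ATCACTCAGCA             0.896      +                 TSS Nfe2l2
2 SynGene chrS:2694-2705 ATGACTCAGCA             1.000      -                 TSS   Mafk
3 SynGene chrS:6125-6136 GTGACACTGCA             0.918      +                   T Nfe2l2
4 SynGene chrS:6156-6167 ATGACTCAGCT             0.928      -                   T Nfe2l2
```

Each row is a putative ARE: its genomic span (0-based half-open), the
11-mer as read on the reported strand, the relative score, the
segmentation states it overlaps, and the TFs whose peaks support it. The
scenario's truth manifest (`sc$plants`) records what was planted where,
with expected scores computed by standalone rescoring, so the pipeline
output can be checked mechanically (`tests/testthat/` does exactly that).

Real data run the same way: point `pipeline_config()` at a genome FASTA, a
UCSC-style transcript table, per-TF peak BEDs and a segmentation BED, then
`run_pipeline()` / `write_report()`.

## Command line

A thin CLI ships in `inst/cli/arescan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/arescan.R", package="AREscan"))')" \
    pipeline --config config.yml --out report.tsv
```

Subcommands: `build-pssm`, `scan`, `pipeline`, `synth` (see the script
header for the flat key–value config format).

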