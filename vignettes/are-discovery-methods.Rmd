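---
title: "ARE discovery: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ARE discovery: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AREscan)
```

## The model

AREscan predicts antioxidant response elements (AREs) — the 11-bp binding
sites of NRF2/small-MAF dimers — by scoring sequence windows against a
position-specific scoring matrix (PSSM) and keeping only windows that are
both high-scoring and supported by transcription factor ChIP-seq peaks
inside a gene's regulatory region.

### From counts to scores

The input is a position frequency matrix (PFM): integer counts $n(b,j)$ of
base $b$ at motif position $j$, here JASPAR entry MA0150.1 (NFE2L2,
width 11, every column summing to 20; vendored at
`inst/extdata/MA0150.1.jaspar`). Scores are log2 odds ratios of observed
versus expected base frequency, with one unit added to every raw count
before normalising each column, so that zero counts never produce
$\log(0)$:

$$ s(b,j) \;=\; \log_2\frac{(n(b,j) + c)\,/\,(N_j + 4c)}{p_b}, \qquad c = 1 . $$

$N_j$ is the count sum of column $j$ (columns are normalised independently
because PFMs need not have equal column sums) and $p_b$ the background
probability of base $b$.

A window's absolute score is $\sum_j s(w_j, j)$; with the cached extrema
$S_{\max} = \sum_j \max_b s(b,j)$ and $S_{\min} = \sum_j \min_b s(b,j)$ the
**relative score** is

$$ r \;=\; \frac{S + |S_{\min}|}{|S_{\max}| + |S_{\min}|} \in [0, 1], $$

an affine rescaling (for the usual case $S_{\min} < 0 < S_{\max}$) that is
monotone in $S$, with the per-column argmax word at exactly 1 and the
argmin word at exactly 0 — two fixed points the test suite checks for
random matrices, backgrounds and pseudocounts.

### The pipeline

For each transcript the regulatory region is the transcript body plus
5 000 bp upstream of the TSS (strand-aware, clamped to the chromosome; the
body is kept because many validated sites fall in transcribed sequence).
Regions are intersected with every per-TF ChIP-seq peak set; each
overlapping peak's sequence is extracted from the genome and scanned at
every offset on both strands (reverse-strand candidates score the reverse
complement of the window and report the same forward coordinates with
strand "−"). Hits must lie wholly inside the peak and inside the region.
Identical sites found through several peaks collapse to one row whose TF
annotation is the sorted unique union. Finally each site is annotated with
the ordered unique labels of the regulatory-segmentation intervals it
overlaps ("None" when there are none — segmentation is an annotation,
never a filter).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pseudocount` | 1 | counts | keeps all log-odds finite; one unit per cell is the smallest count-scale regulariser |
| `background` | 0.25 each | probability | no genome-composition source is assumed; uniform background reproduces the published per-motif scores (see below) |
| `flank` | 5000 | bp | the promoter window upstream of the TSS in which AREs are sought |
| `threshold` | 0.8 | relative score | the conventional TFBS cutoff; inclusive ("below 0.8 discarded") |
| `report_digits` | 3 | decimals | human tables print 3 decimals, mouse tables 2; rounding is half-up and only applied at report time |

The uniform-background choice was an open question (the original analysis
does not state its expected frequencies). It was settled empirically
before freezing the fixture: with $c = 1$ and uniform $p_b$ the vendored
MA0150.1 counts reproduce *every* published per-motif relative score to
within ±0.005 at the printed precision, so no alternative background was
needed.

## What the synthetic generator emulates

`generate_scenario()` builds a self-contained world: a uniform-random
chromosome (default 50 kb), one + strand transcript whose extended region
spans 7 kb, 200-bp "peaks", a tiled segmentation, and planted 11-mers of
three classes — in-peak above-threshold (must be recovered), off-peak
above-threshold (must not be reported), and in-peak below-threshold (must
be discarded). Plants sit in disjoint slots at least one motif width
apart; the manifest's expected scores come from standalone rescoring of
the planted word, never from the pipeline under test, and the generator
re-reads every planted window from the final genome to rule out
collisions. Everything is a deterministic function of the seed
(`withr::with_seed`; the global RNG stream is untouched).

What it does **not** emulate: read-level ChIP-seq signal or peak calling
(peaks are intervals by construction), genome base composition and repeat
structure, multi-chromosome layouts, or overlapping plants (tests that
need overlap construct it manually). A green planted-recovery test
therefore establishes the bookkeeping — coordinate mapping, strand
handling, thresholding, deduplication — not performance on real chromatin.
Background false positives in random sequence are expected at threshold
0.8 (about one per few kb of scanned peak on both strands) and are legal:
tests cross-check any extra hit against the brute-force oracle instead of
forbidding it.

## Numerical choices and degenerate inputs

* Scores are kept at full double precision end-to-end; rounding (half-up,
  because base R's `round()` is half-even) happens only in the written
  report.
* `relative_score()` rejects absolute scores outside
  $[S_{\min}, S_{\max}]$ with a relative tolerance of $10^{-9}$.
* Windows containing non-ACGT characters are skipped silently and counted
  in the run log (`windows_skipped`).
* Sequences shorter than the motif width scan to an empty result, not an
  error.
* A pseudocount of 0 is allowed only when no count is zero; otherwise the
  error names the $\log(0)$ hazard.
* All qualifying windows are reported, including mutually overlapping
  ones; ties are not broken because nothing is ranked.
* Output rows sort deterministically by (gene, chrom, start, strand), so
  reports are byte-reproducible.

## Design choices where the design was open

* **Strand reporting.** Published tables give strand relative to the
  transcript sense; AREscan reports the unambiguous genomic strand and a
  derived transcript-relative `tx_strand` column alongside.
* **Per-gene rows.** A site inside peaks belonging to two genes' regions
  yields one row per gene, matching per-gene report organisation;
  deduplication is per (gene, coordinates, strand).
* **Segmentation multi-labels.** When concatenated multi-cell-type
  segmentations disagree, all overlapping state labels are emitted in
  genomic order, deduplicated, rather than choosing one.
* **Interval engine.** Pairwise overlap is delegated to
  `GenomicRanges::findOverlaps` behind the module contract; the contract
  is enforced by equivalence tests against a quadratic all-pairs oracle.
* **BED/PFM readers are hand-written** so parse errors carry line numbers
  and the peak-file TF label is attached on read; FASTA I/O and reverse
  complementation use Biostrings.

## Limitations

* Only fixed-width mononucleotide PSSMs; no di-nucleotide models, no
  p-value calibration of scores, no de novo motif discovery.
* No retrieval from UCSC/ChIP-Atlas and no liftOver: genomes, peak sets
  and segmentations are consumed as local files, so reproducing a full
  published site table requires obtaining those inputs separately.
* Genomes are held in memory (desk scale, tens of Mb); no FAI/2bit
  indexed access.
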