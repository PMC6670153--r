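---
title: "Profiling intragenic promoters and nested transcripts with IntraProm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling intragenic promoters and nested transcripts with IntraProm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IntraProm)
```

# The analysis

`IntraProm` asks a simple question of a genomic region: does any part of it
look like a promoter, across many cell types, and is there transcript
evidence for a nested gene starting there? The motivating setting is an
intron that harbors translocation breakpoint cluster regions (BCRs):
promoter-like chromatin inside such an intron suggests a nested, often
antisense, non-coding RNA whose transcription keeps the local chromatin
open — a candidate explanation for why breaks cluster there.

The pipeline has five analytic stages plus a synthetic-data generator.
This vignette records the models, the parameters that matter, and the
design decisions taken where the underlying procedures are usually left
unstated.

# Coordinates

All external files (BED, region tables, EST tables) are 0-based half-open;
internally the package uses `GRanges` (1-based closed), with conversion
confined to readers and writers. Region tables may declare rows as
`0-half-open` or `1-closed` (the ENSEMBL export convention); a `1-closed`
row `(s, e)` becomes `(s-1, e)` in half-open coordinates. Accepting both at
the boundary avoids guessing which convention an external table used.

# Module binning and hotspot prevalence

A region of length $L$ is subdivided into $\lceil L / w \rceil$ contiguous
bins of width $w$ (default 2,500 bp), anchored at the lower genomic
coordinate; the genomically-last bin is truncated and reported at its true
width (counts are not width-normalized). Labels are Roman numerals; under
`label_orientation = "gene_sense"` (the default) and a minus-strand host
gene, label I is the genomically-highest bin so that labels read 5′→3′
along the host mRNA, which is how modules of a minus-strand gene's intron
are conventionally described.

Prevalence of assay $a$ in module $m$ is the number of *distinct* cell
types with at least one hotspot interval overlapping $m$ by $\geq 1$ bp.
Decisions made here, each of them deliberate and tested:

* **Overlap threshold is 1 bp.** Visual counting in a genome browser (the
  procedure these surveys typically use) cannot resolve a threshold; the
  most inclusive programmatic rule is used and documented. A
  boundary-spanning hotspot therefore counts in every module it touches.
* **Cell types, not hotspots.** Multiple hotspots of one cell type in one
  module contribute 1. This makes counts monotone under track addition and
  under hotspot widening (both property-tested), and bounded by the number
  of assayed cell types — which should be supplied via `nCellTypes` when
  some assayed cell types have no hotspot in the region at all.
* **Inputs are pre-called hotspot intervals**, not signal; no peak calling
  is performed.

The implementation (interval overlap via `GenomicRanges::findOverlaps`) is
verified against a per-base brute-force oracle that marks every covered
base per cell type, on hundreds of randomized instances.

# Initiator-element scanning

Core promoter prediction tools keep internal motif models; the published
quantity is usually just a cutoff (0.99 here). To make such a cutoff
interpretable the scanner uses **max-ratio normalization**:

$$S(w) = \frac{\prod_i p_i(w_i)}{\prod_i \max_b p_i(b)} \in (0, 1],$$

so the per-position-argmax (consensus) window scores exactly 1 and 0.99
admits only near-consensus windows. Log-odds scoring was deliberately not
made the default because no published background model accompanies the
cutoff.

The default matrix (`inst/extdata/inr_pwm.tsv`) is a hand-curated
7-position frequency matrix consistent with the canonical initiator
consensus YYANWYY, with the +1 adenine at offset 2 and pseudocount 0.01.
Because the original online tool's matrix is unpublished, the matrix is a
configurable input (`readPWM()`); counts obtained with a different matrix
are not comparable, and reproducing another tool's exact counts is a
calibration exercise, not a unit-testable property.

Both strands are scanned by default; minus-strand windows are scored on the
reverse complement and centers mapped back to forward coordinates
(`center' = L - 1 - center`). Overlapping hits are all retained. `N` scores
as the minimum probability in its column — conservative, so an all-`N`
sequence yields nothing. Hits are assigned to subregions (e.g. BCR
intervals) by half-open membership of the center; a hit inside two
overlapping subregions counts in both, and an `outside` remainder is
always reported.

# Stranded TSS profiling

CAGE-HMM TSS predictions arrive as stranded BED6 intervals, possibly wider
than 1 bp. Each record is reduced to its 5′ end in transcription sense
(start for `+`, `end - 1` for `-`) — a declared rule, since no convention
exists for assigning multi-bp predictions to bins. Counts per module are
split by *genomic* strand and summed over cell types without
deduplication (the reported totals in cross-cell-type surveys are sums; a
`dedupe` switch exists but defaults off). Sense relative to the host gene
is derivable from the module set's declared gene strand rather than
baked into the strand labels. Conservation (module sums + outside tally =
records loaded) is property-tested.

# EST consensus

ESTs are single-pass, error-bearing cDNA fragments; the reconstruction
procedure is:

1. **Selection** by $\geq 1$ bp region overlap and genomic strand, or by an
   explicit accession list (the mode used when a hand-picked set is named).
2. **Orientation**: sequences are stored in read orientation (5′→3′ on
   their strand); ESTs whose strand differs from the transcript's are
   reverse-complemented before alignment.
3. **Pairwise alignment**: global with free end gaps (fragments of one
   transcript overlap partially), linear scoring fixed at match +1,
   mismatch −1, gap −2 — standard EST-overlap defaults, declared because
   none are published. Traceback ties resolve diagonal > up > left, and
   the end cell ties resolve toward the fewest end gaps, making output
   deterministic. The DP is implemented in C++ and verified against (a)
   exhaustive alignment-path enumeration at small sizes — every monotone
   path scored, end-gap columns free — and (b) `Biostrings`
   `pairwiseAlignment(type = "overlap")` scores at moderate sizes.
4. **Center-star MSA**: the center maximizes summed pairwise score; other
   rows are merged under "once a gap, always a gap", insertions
   left-aligned within their block. Degapping any row reproduces its input
   exactly, and the center's pairwise score against every row is preserved
   by the merge (both invariants tested).
5. **Consensus**: per column over non-gap residues, drop if depth < 2,
   else call the majority residue if its support $\geq$ 0.5 and `N`
   otherwise; tied majorities are always `N`. Conservative by design for
   1%-error single-pass reads.
6. **Placement**: Smith–Waterman local alignment of the consensus against
   a user-supplied transcript set (the offline replacement for a remote
   BLAST), reporting identity over aligned columns and a
   `below_threshold` flag at 50% identity.

# In-silico PCR

Primer sites are exhaustive substring matches (no indels) with a mismatch
budget, with two realism rules: the 3′-terminal base must match (a
polymerase cannot extend a mismatched 3′ end) and `N` in the template never
matches. Amplicons combine forward-strand sites of the forward primer with
reverse-strand sites of the reverse primer downstream of them, capped at
5,000 bp to suppress spurious distant pairings. Thermodynamics (melting
temperature, annealing) is deliberately not modeled — the purpose is size
prediction, e.g. showing that exon-flanking primers on a spliced vs an
intron-retaining template give products differing by exactly the intron
length. Site finding delegates to `Biostrings::matchPattern` and is
verified against a hand-written sliding-window oracle.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the scale of the motivating study, with ground truth recorded:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 25,000 bp | a 10-module region at 2.5-kb width |
| `gc_fraction` | 0.41 | human genome-wide GC |
| `host_gene_strand` | `-` | minus-strand host, so gene-sense labels descend genomically |
| `planted_promoters` | one at 1,250, `+`, 3 INR motifs | antisense promoter in the genomically-lowest module (module X in gene sense — the BCR3-like bin) |
| `n_cell_types_dnase` / `h3k4me3` / `cage` | 124 / 51 / 35 | the survey's cell-type panel sizes |
| `background_hotspot_rate` | 1 / 10 kb / cell type | sparse accessible background; H3K4me3 background is one tenth of this (it is a promoter mark, not general accessibility) |
| `promoter_presence_prob` | 0.8 | "open in most cell types" |
| `hotspot_length_mean/sd` | 200 / 50 bp (min 50, resampled) | typical hotspot widths |
| `cage_tss_per_promoter_mean` | 0.6 / cell type | ~20 predictions per promoter module over 35 cell types |
| `cage_jitter_sd` | 25 bp | TSS micro-heterogeneity |
| `cage_false_rate` | 0.012 / 10 kb / cell type | ~1 spurious prediction per 25-kb gene-free region over 35 cell types |
| `lnc_length`, `n_ests`, `est_error_rate` | 600 nt, 8, 1% | a short nested lncRNA sampled by a small noisy EST cloud |

Determinism: one random substream per output file, derived in fixed order
from the master seed, so adding an output never perturbs existing ones;
identical config + seed gives bit-identical files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mappability artifacts and batch structure across
ENCODE cell types, correlated (cell-lineage) hotspot presence, spliced
ESTs and chimeric clones, sequence composition beyond i.i.d. bases, and
any relationship between motif content and hotspot placement beyond the
planted promoters. Recovery rates on synthetic data are upper bounds.

# Numerical choices and degenerate inputs

* Scan scores are computed in log space and compared to the cutoff with a
  $10^{-9}$ absolute tolerance so a floating-point consensus window cannot
  miss a cutoff of 1.
* Empty sequences scan to empty hit sets (not an error); cutoffs outside
  $(0, 1]$, non-positive module widths, inverted BED intervals (with line
  number), duplicate region names and unknown convention tags are hard
  errors.
* Hotspots on a different chromosome than the region are ignored with a
  recorded count, not an error.
* Clamped-normal draws (hotspot and EST lengths) resample rather than
  truncate, keeping the distribution shape above the floor.
* `promoter_like(module)` = DNase prevalence $\geq f_D n_D$ AND H3K4me3
  prevalence $\geq f_H n_H$ with $f_D = f_H = 0.5$: an explicitly labelled
  heuristic written into the output header, configurable, and never used
  as an acceptance surface.

# Problem sizes used in the test suite

The suite runs everything at desk scale by choice of problem size, not by
weakening checks: oracle-equivalence suites use hundreds of randomized
instances at region lengths $\leq$ 5 kb and alignment lengths $\leq$ 7 nt
(exhaustive path enumeration grows as the Delannoy numbers, so 7 is the
largest size at which *all* paths can be scored; `Biostrings` provides the
independent cross-check at moderate lengths). Planted-signal recovery runs
the full default scenario (124/51/35 cell types, 25 kb) over 100 seeds,
and transcript recovery at the full default (8 ESTs, 600-nt lncRNA, 1%
error).

# Known limitations

* Prevalence is descriptive: no enrichment test between regions is
  performed, matching the visual-counting procedure it reproduces.
* INR counts depend entirely on the supplied matrix; without the original
  tool's matrix, only procedure-level (not count-level) reproduction of
  published scans is possible.
* The center-star alignment is $O(k^2)$ in the number of ESTs and is meant
  for hand-sized sets (tens), not EST-database scale.
* Local alignment allocates the full DP matrix; consensus-vs-transcript
  comparisons should stay below a few megabases of product size.
* No spliced alignment: ESTs are treated as contiguous fragments of the
  transcript.
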