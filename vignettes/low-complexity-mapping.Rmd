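---
title: "Low-complexity mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-complexity mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

`complexmap` profiles a genome assembly with one window statistic, the
k-mer complexity score: the number of distinct k-mers divided by the number
of counted k-mer positions in a window,

$$ s = \frac{\#\{\text{distinct } k\text{-mers}\}}{\#\{\text{counted
positions}\}}, \qquad \frac{1}{n} \le s \le \min\!\left(1,
\frac{4^k}{n}\right), $$

where $n$ is the count of window positions whose k-mer contains only
A/C/G/T. The score approaches 0 in tandem repeats (a period-$p$ array
contains at most $p$ distinct k-mers regardless of window size) and, for
$4^k \gg n$, stays near 1 in unique sequence. The exact expectation for
i.i.d. uniform random sequence follows the birthday/occupancy model: with
$m = 4^k$ alternatives and $n$ draws, $E[\text{distinct}] =
m\,(1 - (1 - 1/m)^n)$. At $k = 10$, $m = 4^{10}$, and a full 50 kb window
($n = 49{,}991$) this gives $s \approx 0.976$ — the "unique background"
level against which repeats stand out. The test suite checks the compiled
counter against a naive substring-set oracle and against this closed form.

Two scales are profiled by default:

* **k = 10, "distant memory"** — sensitive to long-range repeat structure.
  All segmentation and haplotype comparison operate on this track.
* **k = 3, "local memory"** — a long window nearly always contains all 64
  possible 3-mers, so this track sits at $\approx 64/n$ genome-wide and
  moves only where short-range composition is anomalous (homopolymer or
  microsatellite spikes). It is emitted for inspection but not segmented.

## Windowing and counting policies

Windows are 50 kb advanced in 25 kb steps (both configurable). Window
starts are $0, S, 2S, \dots$ for every start below the chromosome length;
final windows are truncated at the chromosome end and kept as long as they
fit the largest k, because the terminal signal is exactly where telomeric
and subtelomeric blocks live. Truncation is visible through `end - start`.
Coordinates are 0-based half-open throughout (BED convention).

Counting policies, recorded in each profile's provenance attribute:

* k-mers containing any non-ACGT character are excluded from numerator
  *and* denominator. N-joined pseudochromosome gaps therefore contribute
  nothing rather than registering as spuriously distinct k-mers; an all-N
  window has $n = 0$ and an `NA` score.
* Counting is literal-strand by default. A canonical mode (collapse each
  k-mer with its reverse complement) is available as a flag; it changes
  scores only marginally in practice and is off by default because the
  statistic is defined by direct substring tabulation.
* Case-insensitive: soft-masked (lowercase) bases count like uppercase, so
  RepeatMasker-processed assemblies profile identically to unmasked ones.
* "Distinct k-mers" could alternatively be read as k-mers occurring exactly
  once (singletons). The distinct-count reading matches the notion of
  k-mer *diversity* and the documented 0-to-1 range, so it is the default;
  a `mode = "singleton"` alternative is provided for comparison.

Per-window tabulation is exact (a sorted 2-bit encoding in C++, $k \le
31$), not a sketch: windows are at most tens of kilobases, exactness is
cheap, and it is what makes oracle testing possible.

## Segmentation into repetitive blocks

Windows with score below `score_threshold` (default 0.1) are
low-complexity. "Near zero" is operationalized as 0.1 because the two
regimes the statistic produces are far apart: tandem arrays score below
0.01 at $k = 10$ while random background scores above 0.9, so any
threshold in between separates them; 0.1 leaves generous room for noisy or
partially-covered windows. Maximal runs of low windows become blocks; up to
`merge_gap` (default 1) consecutive high or NA windows are bridged when
both flanks are low, so a single dispersed element nested inside an
extensive satellite block does not split the call. Blocks shorter than
`min_span` are suppressed — 100 kb at the package's desk scale, 5 Mb being
the equivalent choice for full-size (tens of Mb) chromosomes.

A block is *terminal* when it starts inside the left tenth or ends inside
the right tenth of its chromosome (`terminal_fraction = 0.1`); ties between
ends go to the nearer end, then left. Chromosomes are ranked by the
fraction of low-complexity windows rather than by mean score — robust to a
few NA or truncated windows — with mean complexity deficit and name as tie
breakers; both metrics are emitted.

## Haplotype comparison

Two haplotype profiles computed with identical window settings are matched
window-for-window by chromosome name and start coordinate — deliberately
*not* by alignment, which is a different (and out-of-scope) machinery;
coordinate matching is the analogue of laying the two per-chromosome maps
side by side. Each matched pair is classified with a threshold $t$ and a
margin $m$ (defaults 0.1 and 0.3):

| score$_{h1}$ | score$_{h2}$ | category |
|---|---|---|
| $< t$ | $< t$ | conserved_repetitive |
| $\ge t+m$ | $\ge t+m$ | conserved_unique |
| $< t$ | $\ge t+m$ | h1_specific_lc |
| $\ge t+m$ | $< t$ | h2_specific_lc |
| otherwise / NA | | indeterminate |

The margin band exists so that windows straddling the threshold on one
haplotype are never promoted to "haplotype-specific": a window must be
clearly repetitive on one side *and* clearly unique on the other. NA on
either side is always indeterminate. Windows past the end of the shorter
chromosome (e.g. after a translocation changes lengths) are reported as
indeterminate overhang rather than dropped silently.

Per chromosome, the divergence score is the fraction of classified
(non-indeterminate) windows that are haplotype-specific, and the terminal
asymmetry is the signed difference in terminal block span (hap2 minus
hap1, per end): positive means hap2 carries the larger terminal repetitive
block. Swapping the inputs negates deltas and asymmetries and exchanges
the two specific labels exactly — an invariant the tests enforce.

## Telomere scanning

Each chromosome end is scanned over its terminal 10 kb: the left end for
the motif (default plant-canonical `TTTAGGG`), the right end for its
reverse complement (`CCCTAAA`), the standard orientation convention.
Counting is greedy non-overlapping left-to-right; for a motif like
`TTTAGGG`, which cannot overlap itself, this equals the total occurrence
count while remaining unambiguous for motifs that can. An end is telomeric
at `min_count = 50` occurrences (about 350 bp of repeat): random
background yields well under one expected occurrence per 10 kb
($10^4/4^7 \approx 0.6$), so planted or real arrays clear the threshold by
about two orders of magnitude. Chromosomes are classed `both`,
`left_only`, `right_only` or `none`. The choice of motif is a parameter
because telomere search tools are typically run with an explicit or
clade-default motif.

## The synthetic diploid generator

The generator exists so that every downstream stage has ground truth. Its
default configuration is the package's reference study and mirrors the
repeat landscape reported for haplotype-resolved citrus assemblies, scaled
to desk size:

* 9 chromosomes per haplotype, 1 Mb each (real pseudochromosomes are
  30+ Mb; the statistic's behaviour is scale-free, so tests run at 1 Mb
  with proportionally reduced features), GC 0.5, shared background between
  haplotypes so differences are exactly the planted ones.
* Telomere arrays of 2 kb at four chromosomes' both ends and five
  chromosomes' single ends (4 both + 5 one-end, the accounting typical of
  such assemblies).
* Terminal tandem blocks with haplotype asymmetry: chr2 hap1 150 kb vs
  hap2 50 kb, chr8 and chr9 the reverse (hap2 150 kb vs hap1 50 kb) — 15%
  and 5% of the chromosome, standing in for the multi-Mb terminal blocks
  of full-size chromosomes.
* Two interior 150 kb blocks on chr5 (both haplotypes), making chr5 the
  most repetitive chromosome by a clear margin.
* Three dispersed 2 kb repeat families, 15 copies each, placed identically
  on both haplotypes away from other features and SV breakpoints.
* A heterozygous inversion on chr2 (hap1, [0.3 L, 0.5 L)) and a
  heterozygous reciprocal translocation between chr5 and chr7 (hap2,
  breakpoints at 0.6 L and 0.7 L).

Block and repeat-family monomers are drawn from the seeded stream rather
than hard-coded, and redrawn if the resulting array would contain the
telomere motif or its reverse complement, so satellite never mimics
telomere. SVs are applied after sequence features, which lets an inversion
relocate complexity signal; truth coordinates are remapped through each SV
(mirror map for inversions, offset-and-relabel for translocations), so
every truth interval remains extractable from the emitted FASTA. An SV
whose breakpoint would split a planted feature is rejected as a
configuration error rather than silently truncating it.

What the generator does **not** emulate: real base composition beyond GC,
repeat-family sequence evolution (copies are identical), nested or
diverged satellites, gaps (N runs appear only if a user plants them), and
read- or assembly-level artifacts. Passing tests therefore demonstrate
that the statistics and the segmentation/comparison/telomere logic recover
planted structure under clean conditions — not that any particular real
assembly is correctly annotated.

## Numerical choices and degenerate inputs

* Score for $n = 0$ is NA (never 0/0), written as `NA` in TSV and omitted
  from bedGraph.
* Windows shorter than the largest k are dropped from the grid; a
  chromosome shorter than k yields an empty profile for that chromosome.
* Ranking ties break deterministically (deficit, then name); terminal-end
  ties go left; block calls at identical parameters are idempotent.
* Chromosomes present in only one haplotype are excluded from comparison
  summaries and reported, never silently merged.
* The compiled counter supports $k \le 31$ (2-bit rolling encoding in a
  64-bit word); the package validates k against both this limit and the
  window size.

## Problem sizes used by the tests

The shipped tests and the acceptance script run entirely on generated
data: the reference study at 9 × 1 Mb (50 kb/25 kb grid), a 50-configuration
block-recovery sweep at 2 × 250 kb (10 kb/5 kb grid, `min_span` 20 kb), a
20-seed divergence sweep at 9 × 300 kb (15 kb/7.5 kb grid), and 20-seed
telomere-recovery sweeps at 6 × 100 kb. These sizes were chosen so the
whole suite exercises every stage, at full window counts per chromosome, in
a few minutes on a single core.

## Known limitations

* Window-grid matching assumes the two haplotypes share a coordinate
  system at the window scale; large-scale rearrangements appear as
  haplotype-specific or indeterminate windows rather than being traced to
  their partner location (SV calling is explicitly out of scope).
* The complexity score is insensitive to dispersed repeats whose copies
  fall in different windows — by design, it measures *within-window*
  diversity.
* Telomere calling reports motif counts, not array length estimates, and
  will not discover unknown motifs.
* `fraction_low` depends on the window/step ratio; profiles computed with
  different grids are refused for comparison rather than resampled.
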