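---
title: "Constrained multi-level thresholding for ChIP-Seq peak calling: methods and design"
author: "cmtseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained multi-level thresholding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtseq)
```

# The problem and the model

ChIP-Seq maps protein–DNA interactions by sequencing immunoprecipitated
fragments and aligning the reads to a reference genome. The per-nucleotide
count of aligned, fragment-extended reads forms a coverage histogram in
which binding events appear as peaks separated from their neighbours by
valleys. `cmtseq` treats peak finding as one-dimensional clustering along
the genomic axis: each enriched region is a cluster, and the boundary
between neighbouring clusters is placed where the two are best separated.

The pipeline is:

1. **Histogram construction.** Each read is extended in its strand
   direction to the average sonication fragment length (a plus-strand read
   keeps its 5' start; a minus-strand read keeps its 3' coordinate), and
   the fragments are piled into a dense per-nucleotide histogram per
   chromosome, separately for experiment and control.
2. **Constrained segmentation.** Starting from the beginning of the
   chromosome, division points between neighbouring peaks are placed by
   maximizing a between-class variance criterion inside a window whose
   extent is bounded by the user's minimum and maximum target region
   sizes. Gaps — windows whose maximum height never reaches the minimum
   supported-read threshold — are skipped without analysis.
3. **Refinement and selection.** Candidates are shrunk from their borders
   to the contiguous footprint around the summit where coverage stays at
   or above a cut-off; a shrunk region is kept when its size lies in the
   target range and its squared coverage density exceeds `k`-fold the
   (depth-scaled) control density. Kept regions are ranked by fold
   enrichment.

## The separation criterion

For a window of bins $i = 1, \dots, n$ with coverage $h_i$, define weights
$p_i = h_i / \sum_j h_j$. A split after bin $t$ partitions the window into
$C_1 = \{1..t\}$ and $C_2 = \{t{+}1..n\}$ with class masses
$\omega_1 = \sum_{i \le t} p_i$, $\omega_2 = 1 - \omega_1$ and class mean
*positions* $\mu_1, \mu_2$; $\mu_T$ is the overall mean position. The
between-class variance

$$\sigma_B^2(t) \;=\; \omega_1(\mu_1 - \mu_T)^2 + \omega_2(\mu_2 - \mu_T)^2
\;=\; \omega_1\,\omega_2\,(\mu_1 - \mu_2)^2$$

is the classical Otsu separability criterion applied *positionally*: bin
index is the value axis and normalized coverage the weight. It is largest
when the split places two concentrations of coverage mass far apart on
either side — exactly what a valley between two peaks does. The criterion
is invariant to positive scaling of the counts, so per-window
normalization is numerically safe and does not change the argmax.

`findDivisionPoint()` maximizes $\sigma_B^2$ over splits whose left part
(the emitted region) has length in $[\texttt{minRegion},
\texttt{maxRegion})$, then the scan resumes at the division point. This
realizes multi-level segmentation as a sequence of two-class decisions,
one per window.

## Admissible division points

A design question the criterion alone does not settle: over a window
containing a *single* contiguous block of signal and little else, the
unrestricted positional argmax falls in the block's interior (with all
mass on one side, $\sigma_B^2 = 0$; the best non-degenerate split is
inside the mass). A division point is meant to *separate two neighbouring
peaks*, so the implementation restricts admissible splits to valley bins —
positions whose height is below the minimum supported-read threshold —
within the constrained range. When the entire range is supported (a domain
broader than `maxRegion`, e.g. a histone-modification block scanned with a
transcription-factor-scale window), every position in the range is
admissible and broad signal is divided into `maxRegion`-bounded pieces,
which is what the size constraint intends. The test suite's brute-force
oracle implements the same admissibility rule while recomputing every
class statistic by direct summation.

**Tie-breaking.** Zero-coverage valleys make $\sigma_B^2$ exactly constant
across the valley. Among maximizing splits the centre of the first maximal
plateau (middle element of the run) is returned: symmetric within a
valley, and reproducible.

**Other numerical choices.** The vectorized sweep uses the identity
$\sigma_B^2(t) = (\mu_T\omega_1 - m_1)^2 / (\omega_1\omega_2)$ with
cumulative sums $\omega_1, m_1$, giving $O(1)$ work per split; tests
require agreement with direct recomputation to $10^{-9}$ relative
tolerance. Plateau detection uses a $10^{-12}$ relative tolerance so that
float noise cannot fragment an exact plateau. Windows are shrunk at the
chromosome's right edge; trailing signal too short to admit a constrained
split is emitted as a final candidate and left to the size filter.
Fragments extending past the chromosome origin are clipped at position 1;
right clipping requires an optional chromosome-sizes table, since a BED
file alone does not carry chromosome lengths.

## Enrichment selection

"Squared density" of a region is implemented as the mean of squared
per-nucleotide heights, $D = \frac{1}{|r|}\sum_{i \in r} h_i^2$; the
square-of-mean alternative is available via
`squaredDensity(method = "squared-mean")` for sensitivity analysis. A
region passes when its size is within the target range and
$D_{\mathrm{exp}} \ge k \cdot D_{\mathrm{ctrl}}$ (default $k = 2$).
Control heights are scaled by the experiment/control total-fragment ratio
before squaring, so unequal sequencing depths do not bias the test;
`scaleControl = FALSE` restores the raw comparison. When the control
density is zero but the experiment's is positive, the region passes — a
sparse control must not veto strong signal — and the reported fold
enrichment uses a floor of $1/|r|$ in the denominator to stay finite.

The border-shrinking cut-off defaults to 1 (keep the contiguous part of
the region supported by at least one fragment). Shrinking walks outward
from the summit and stops at the first bin *strictly below* the cut-off on
each side, so signal blocks disconnected from the summit are dropped; they
are recovered only if the scanner emitted them as separate candidates.

# Parameters

| parameter        | units | default | meaning |
|------------------|-------|---------|---------|
| `fragmentLength` | bp    | 200     | sonication fragment length; reads are extended to it |
| `minRegion`      | bp    | 100     | minimum target region size (admissible split range, size filter) |
| `maxRegion`      | bp    | 1000    | maximum target region size (scan window, size filter) |
| `cutoff`         | reads | 1       | border-shrinking height threshold |
| `minReads`       | reads | 5       | minimum supported height (gap skipping, valley definition) |
| `kFold`          | —     | 2       | minimum experiment/control squared-density fold change |

`minRegion`/`maxRegion` are the instrument for targeting a feature class:
roughly 10 bp–1 kbp for transcription-factor footprints, tens of kbp for
histone-modification domains. `minReads` should sit clearly above the
background coverage; see below for a principled choice.

# The synthetic data generator

`simulateReads()` emulates the structure the caller exploits: uniform
background reads on random strands, plus planted peaks whose extra reads
have fragment midpoints uniform over the peak interval and strand-aware 5'
placements, so that after extension the pileup shows the fragment-shaped
ramp of real ChIP signal. The control is the same background process at a
configurable depth ratio. It does **not** model chromatin accessibility
bias, mappability, duplicated reads or sequencing error — so passing tests
demonstrate correctness of the algorithmic chain on idealized signal, not
robustness to every artefact of real libraries (the method itself makes no
background-shape assumption).

The package's reference conditions, used by the end-to-end tests: a 1-Mbp
chromosome, 20,000 background reads of 36 bp extended to 200-bp fragments
(expected background coverage $4\times$), one planted 300-bp peak of
10-fold enrichment, and an equally deep control. Analysis parameters for
these conditions: `minRegion = 100`, `maxRegion = 1000`, `cutoff = 8`
(twice the expected background coverage) and `minReads = 20`. The last
value is a pre-registered tail bound: per-bin background coverage is
Poisson(4), and 20 is the smallest $m$ with
$L \cdot P(\mathrm{Pois}(4) \ge m) < 0.02$ for $L = 10^6$, so a
background-only chromosome is expected to produce a supported bin in well
under 1 in 10 runs. Problem sizes in the test suite (50 simulation seeds
for recovery and null calibration, 20 for the enrichment-score null,
windows up to $10^4$ bins for the oracle sweep) were chosen to give stable
Monte-Carlo estimates at desk scale.

# Evaluation machinery

- **Swap FDR** (`swapFdr`): exchange experiment and control, re-call with
  identical parameters; FDR = 100 × swapped / original counts.
  `fdrCurve()` traces it over top-N thresholds of the ranking.
- **Motif enrichment** (`enrichmentScore`): occurrences of IUPAC motifs in
  peaks divided by occurrences in per-chromosome random intervals of the
  same number and lengths (uniform starts, fully contained; intervals may
  overlap). Scanning counts all overlapping matches on both strands (the
  reference motifs are non-palindromic and binding is strand-agnostic;
  `bothStrands = FALSE` restricts to forward). `N` in a pattern matches
  any base; `N` in the sequence matches nothing. A zero denominator gets
  +1 smoothing with a warning.
- **Summit overlap** (`summitOverlap`): peak A is detected by method B
  when A's summit lies in a region of B; counts and percentages are
  directional.
- **Feature assignment** (`assignFeatures`): a peak receives every
  annotation label it overlaps by ≥ 1 bp (a peak in a gene's exon counts
  as both gene and exon), and `inter-genetic` when it overlaps nothing.

# Known limitations

- The criterion is positional and mass-based; it does not model read
  counts statistically, so no p-values are attached — ranking is by fold
  enrichment only.
- Sequential window-by-window division is not a joint optimization over
  all thresholds; a deliberately greedy design matching the linear-time
  scan (the evaluation count grows linearly with chromosome length at
  fixed signal density, which the tests assert by operation counting).
- Fragment length is a user input; no cross-correlation estimator is
  provided.
- Chromosome lengths are unknown from BED input alone, so fragments are
  right-clipped only when a chromosome-sizes file is supplied, and random
  intervals for enrichment scoring are drawn genome-wide rather than from
  mappable regions.

# A worked example

```{r example, eval = FALSE}
sim <- simulateReads(simulationConfig(seed = 7))
params <- cmtParams(fragmentLength = 200, minRegion = 100,
    maxRegion = 1000, cutoff = 8, minReads = 20, kFold = 2)
res <- callPeaks(sim$experiment, sim$control, params)
res$peaks
res$summary
```
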