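---
title: "Counting strategies, error rates and the hybrid region-level test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting strategies, error rates and the hybrid region-level test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbregions)
```

# The problem

A ChIP-seq experiment with biological replicates in two conditions asks
where protein–DNA binding differs between the conditions. When no
predefined region set exists, reads must first be summarized into counts
*de novo*, either over empirically called peaks or over sliding windows.
Both routes carry an error-control trap, and this package exists to expose
and fix both:

* defining peaks from the same data that is subsequently tested can bias
  the test (data snooping), with the size and direction of the bias
  determined by how peak calls are consolidated across libraries;
* applying Benjamini–Hochberg (BH) to all window P-values controls the
  false discovery rate over *windows*, whereas interpretation and
  validation happen per *region*; a strongly DB region contributes many
  detected windows, a false-positive region few, so the FDR across
  distinct regions is systematically higher than the window FDR.

# Models and procedures

## Count model and test

Counts for feature *i* in library *j* are modelled as negative binomial
with mean proportional to the effective library size and dispersion
$\varphi_i$ (variance $\mu + \varphi\mu^2$). Testing uses the
quasi-likelihood (QL) F-test: an abundance-dependent dispersion trend is
estimated by Cox–Reid adjusted profile likelihood, per-feature
quasi-dispersions are shrunk towards an abundance-level prior with
robustly estimated prior degrees of freedom, and the two-group contrast is
tested against an F reference whose denominator df are inflated by the
prior df. These steps are delegated to edgeR (`estimateDisp`,
`glmQLFit`/`glmQLFTest`), the standard implementation of this machinery;
the package authors the surrounding pipeline, the closed-form two-group NB
fit used for exposition (`fit_nb_glm`), and all region-level inference.

Two QL flavours are exposed (`ql = "adjusted"` or `"classic"`). The
adjusted-deviance flavour is the better calibrated on peak-scale counts:
in the null simulation below its observed type I error at nominal
0.01/0.05/0.10 is 0.010/0.051/0.100. Its robust empirical Bayes step,
however, degrades on sliding-window counts, where the coverage gradient
across a peak produces a heavy-tailed spread of quasi-dispersions: the
estimated prior df collapse (values around 10 in our performance
simulations), the moderated window P-values weaken, and region detection
becomes unstable between simulation iterations. The classic flavour keeps
high prior df in that regime and is therefore used by the window-based
pipelines (`run_fdr()`, `run_performance()` — for *both* methods inside
each comparison, so contrasts are engine-matched). This is a numerical
robustness choice, not a statistical disagreement: both flavours are
calibrated where they are used.

## Normalization

Composition bias between libraries is estimated by trimmed-mean-of-M-values
(TMM) applied to counts in 10 kbp bins — large equal bins so every genomic
region is represented once — and **without precision weighting**, so each
bin's M-value counts equally. The 30% two-sided M-trim tolerates up to 30%
of bins DB in one direction (up to 60% if balanced). Factors multiply raw
library sizes to give effective sizes. In all simulations the factors are
unity: DB spike-ins are balanced by construction, so no composition bias
exists.

## The peak caller and the seven consolidation strategies

The caller is a deliberately simplified Poisson scan standing in for a
classic ChIP-seq peak caller: 5′ positions are shifted by half the
fragment length ($f/2$) toward the fragment centre; windows of width $2f$
every $f/4$ bp are scored by the upper-tail Poisson probability of their
shifted-read count under a background rate; windows at or below a seed
threshold (0.1) merge into peaks when overlapping or adjacent; the peak
P-value is recomputed over the merged region; and only peaks at or below
the output cutoff ($10^{-5}$, the conventional default) are reported. The
scan width $2f$ (rather than $f$) matters for diffuse marks: a 100 bp
window holds only ~15% of a 1 kbp histone peak's reads and would leave
weak histone peaks uncallable at any sensible cutoff.

Background rates are dynamic. In single-sample mode the rate is the larger
of the genome-wide density and a 10 kbp local density (the peak's own
enrichment must not mask itself, so no narrower window enters). In
two-sample mode the rate comes from the control, as the maximum over the
peak region itself and 1/5/10 kbp neighbourhoods, scaled by the
library-size ratio and floored at the control's genome-wide rate —
including the region itself is what makes a matching control peak mask the
call, so that identical treatment and control yield no systematically
small P-values.

With $\nu$ libraries, the per-unit peak-calling P-values of one logical
peak, $P_l = \{\pi_{l1},\dots,\pi_{l\nu}\}$ (with $\pi_{lm}=1$ where unit
$m$ made no overlapping call), are consolidated by one of seven
strategies: per-library calling with union (1: $\min P_l$), intersection
(2: $\max P_l$) or at-least-two (3: second-smallest); group-pooled calling
with union (4) or intersection (5); two-sample calling between the pooled
groups, union over directions (6); or single-sample calling on the pool of
everything (7). Cross-unit matching uses single-linkage overlap clustering
of peak intervals (adjacency excluded); overlapping directional calls in
strategy 6 keep the smaller P. The retention threshold $\tau$ is set to
the $C$-th smallest consolidated value so every strategy reports the same
number of peaks; all peaks are kept when fewer than $C$ exist.

The type I error study (`run_type1()`) shows why only strategy 7 is safe:
at a nominal 0.05, our reduced-scale runs give roughly 0.049 for strategy
7 and the reference analysis, deflation for intersections (strategy 5
≈ 0.001) and per-library consolidations (0.013–0.042), inflation for the
group-pooled union (strategy 4 ≈ 0.13) and gross inflation for two-sample
calling (strategy 6 ≫ 0.3): peaks defined by the between-group contrast
are then tested for that same contrast. Pooling everything makes peak
selection depend (approximately) only on average abundance, which is
independent of the DB statistic.

## Windows, regions and the hybrid test

Window counts include every read whose fragment — the read directionally
extended to the average fragment length $f$, i.e. $[x, x+f)$ for a forward
read at $x$ and the $f$ bases ending at a reverse read's position — overlaps
the window. Windows are 1 bp for sharp transcription-factor (TF) analyses
and 150 bp (a nucleosome) for histone marks, spaced 25–100 bp. Features
with a total count below 20 are filtered as uninformative background
(the additional average-log-CPM filter is intended for real data and off by
default, and off in all simulations).

The naive sliding-window summary (`merge_db_windows()`) BH-adjusts window
P-values, keeps windows at or below the FDR threshold, and merges detected
windows closer than 100 bp with matching fold-change sign. The hybrid
procedure (`hybrid_regions()`) instead forms one cluster per
pooled-library peak from *all* windows overlapping it (a window overlapping
two peaks joins both clusters), combines each cluster's window P-values
with Simes' rule $p_s = \min_r\, n\,p_{(r)}/r$ — a valid test of the
cluster's global null even under the strong positive correlation of
overlapping windows — and BH-adjusts across clusters. Detection is then a
region-level event and BH controls the region-level FDR. Clustering by
pooled-library peaks is legitimate precisely because pooled calling is
independent of DB (strategy 7 above).

# The simulator

`simulate_dataset()` generates the study conditions used throughout:

* $N$ peaks at centres $c_i = i \cdot 10\,000$ bp on one artificial
  chromosome of length $(N+2)\cdot 10^4$ — deterministic spacing
  satisfying the minimum-separation constraint;
* per-peak dispersions $\varphi_i = 1/X$, $X \sim \chi^2_{20}$ (mean
  $1/18 \approx 0.056$; the unscaled reciprocal, which yields realistic
  ChIP-seq dispersions), shared by all libraries of a peak;
* per-library fragment counts NB($\mu_{ij}, \varphi_i$), with
  $\mu_{ij} = x_0$ for non-DB peaks and $\{\mu_{i1},\mu_{i2}\} =
  \{x_1,x_2\}$, $x_1 + x_2 = 2x_0$, for DB peaks — the same number
  spiked up in each group, so abundance is independent of DB and no
  composition bias arises;
* read placement: TF mode splits reads evenly between strands (an odd
  remainder goes forward with probability 1/2) and draws forward 5′ ends
  at $c_i - fX$ and reverse at $c_i + fX$, $X \sim \mathrm{Beta}(2,2)$,
  $f = 100$ — reproducing strand bimodality; histone mode draws positions
  from a Beta(2,2) scaled to $w = 1000$ bp around $c_i$ with uniform,
  position-independent strands. Continuous positions are rounded to the
  nearest base (unbiased for these symmetric densities) and clamped to the
  chromosome;
* optional background: contiguous 2 kbp blocks with
  $\mu_k \sim U(10, 50)$ and inverse-$\chi^2$ dispersions, both shared
  across libraries (so background is never DB), uniform placement within
  blocks. Background is generated only for the performance study; the
  type-I and FDR studies use none.

Reads are point events (a 5′ position and strand); read length itself is
never modelled because every counting rule consumes either the 5′ end or a
fragment-length extension anchored there. Per-peak read totals equal the
NB count matrix exactly, by construction. What the simulator does *not*
emulate: mappability and GC bias, duplicate reads, copy-number differences,
composition bias, irregular peak spacing and shapes, or unbalanced library
sizes — so passing simulations demonstrate the error-control arithmetic,
not robustness to those real-data artefacts.

# The three studies and their scales

`run_type1()`: null TF data ($x_0 = 20$, no DB), each strategy calls and
consolidates to the top $C$ peaks, retained peaks are re-mapped onto the
true peaks they overlap, 5′ ends are counted over the *true* intervals
(so differences between strategies reflect selection, not interval width),
totals below 20 filtered, QL-tested; the observed error is the fraction of
P-values under each nominal threshold. The reference analysis does the
same on $C$ randomly sampled true peaks. The paper-scale design is
$N = 50\,000$, $C = 10\,000$; the test suite runs $N = 10\,000$,
$C = 2\,000$ with 3 iterations and the acceptance script the full scale,
sizes chosen to keep a complete run in minutes on one CPU while leaving
Monte-Carlo errors an order of magnitude below the effects tested.

`run_fdr()`: $x_0 = 50$, $x_1 = 90$, $x_2 = 10$ with DB in 15% of peaks
(scaled proportionally when $N$ is reduced: the suite uses $N = 5\,000$,
$N' = 375$); sliding-window analysis at FDR 0.05 is scored both by its
window-level FDR (controlled) and region-level FDR (lost — increasingly so
at small spacings and for histone data, where each region spans more
windows), and the hybrid approach by its region-level FDR (controlled).

`run_performance()`: weaker peaks ($x_0 = 15$, $25/5$ for TF; $x_0 = 30$,
$50/10$ for histone) over NB background, $N' / N = 1/40$. The peak-based
method tests 5′-end counts over the *empirical* peak intervals — here
background contamination of the counts is exactly the phenomenon under
study — while the hybrid method tests windows. Both control the observed
FDR; TF power favours the hybrid (empirical peaks average ~2.5× the true
200 bp width, so peak counts are diluted by background while some window
isolates the summit), and histone power favours the peak-based method
(peak intervals match the true 1 kbp width, so whole-peak counts beat
150 bp windows, and Simes pays a multiplicity cost over ~40 windows per
cluster). Iteration seeds are `seed + i`, and all methods within an
iteration share its simulated data, so method contrasts are paired.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, BED-native; adjacency is
  never overlap. True TF regions are stored end-inclusive
  ($[c_i - f,\, c_i + f]$, width 201) so the placement support is covered
  exactly.
* P-values are floored at $10^{-300}$ before Simes/BH arithmetic.
* `simes_p()` errors on an empty set; clusters with no tested windows are
  omitted rather than imputed.
* Observed FDRs use the 0/0 := 0 convention (no detections, no error).
* Window grids anchor at multiples of the spacing from 0; with equal
  widths, midpoint spacing equals start spacing, so the anchor is
  immaterial and fixed for reproducibility.
* Ties at the retention threshold $\tau$ are broken by genomic position;
  the caller's P-values are discrete (Poisson tails), so ties are common
  among weak candidates and this keeps retention deterministic.
* `fit_nb_glm()`'s closed form is the exact MLE when effective sizes are
  equal within each group (always true in the simulations) and in the
  Poisson limit; elsewhere it is a moment-style approximation kept for
  exposition — the pipeline's real fits are edgeR GLM fits.
* The caller requires `scan_width` and `local_width` to be multiples of
  the step; empty libraries return empty peak sets; a two-sample call with
  an empty control errors.

# Known limitations

* The caller is an emulation: it reproduces the behavioural contrasts of
  the consolidation strategies, not any specific program's output. In
  particular the *magnitude* of strategy 6's inflation (and strategy 5's
  deflation) depends on how many peaks a two-sample caller emits on null
  data at its output cutoff, which published descriptions underdetermine;
  our implementation lands on the sparse-candidate side, making strategy 6
  look even worse (observed error ≈ 0.8 at nominal 0.05) and strategy 5
  even more conservative than the original report, with the qualitative
  ordering intact.
* In the TF performance study the peak-based method's observed FDR sits
  slightly above nominal (≈ 0.08): background noise peaks selected for
  extreme pooled totals are mildly anti-conservative under the QL test.
  The stated acceptance property (≤ 0.05 + 3 SE) still holds; the hybrid
  method is unaffected.
* Only two-group one-factor designs are supported; no general design
  matrices, paired-end data, or real-data ingestion beyond BED/TSV (BAM
  ingestion would slot behind `read_reads()` but is not needed by any
  analysis here).
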