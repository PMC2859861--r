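---
title: "Screening SSH cDNA libraries on two-colour microarrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SSH cDNA libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sshray)
```

## The screening problem

A suppression-subtractive-hybridization (SSH) library is *designed* to be
enriched for differentially expressed transcripts, and the SSH
normalization step deliberately flattens abundance differences. Two
consequences drive everything in this package. First, the default
assumption behind ordinary two-colour loess normalization — that most
spots show no differential signal — is false by construction, so
normalization must be anchored on spiked-in alien control spots instead.
Second, a clone's position in the library says nothing quantitative about
how strongly it responds to the treatment or how rare its transcript was,
which is exactly what one needs to know before spending sequencing effort;
the screen estimates both quantities per clone, with statistical support.

Each clone is summarised by two log2 ratios estimated from separate
contrast slide sets: **ER3** (differential expression; UT vs UC slides)
and **inverse ER2** (rarity before subtraction; UT vs ST slides for the
forward library, UC vs SC for the reverse). A negative inverse ER2 means
the subtracted sample carries relatively *more* of the fragment than the
unsubtracted one — the transcript was rare and SSH enriched it. Both
libraries can be screened from the same slides (`library = "both"`)
because the ER3 contrast carries information about every spotted clone.

## Pre-processing

**Spot quality.** A spot is excluded (weight 0) when its GenePix flag is
negative or its signal-to-noise ratio in either channel falls below
`snr_threshold` (default 3, dimensionless). When the scanner file carries
its own SNR columns those are used; otherwise SNR is computed as
(foreground median − background median) / background SD. Weight-0 spots
are excluded both from normalization-curve fitting and from model fitting,
but their values are still normalized, so nothing is silently dropped from
the output tables.

**Background.** The normexp convolution model (observed net intensity
x = B + S with B ~ N(mu, sigma²) and S ~ Exp(alpha)) is fitted per
array-channel by exact maximum likelihood and each spot is replaced by
E[S | x] plus an `offset` of 50 intensity units. The offset deliberately
biases very dim spots upward, damping the otherwise explosive variance of
log-ratios near zero intensity — a prerequisite for the downstream
empirical-Bayes machinery to see roughly comparable variances.

**Within-array normalization.** A robust local-linear loess of M on A
(span 0.3, 4 robustifying iterations) is fitted per print-tip group using
*only* the spike-in control spots (full weight to controls, zero to
library clones; `clone_weight` lets controls share the curve with
partially weighted clones if desired) and its fitted value is subtracted
from every spot's M. Three numerical choices matter:

* *Constant extrapolation.* Outside the controls' A-range the boundary
  fitted value is held constant. Only library spots live out there, and a
  local-linear fit extrapolated beyond its support produces arbitrary
  tails.
* *Fallback.* A print-tip group with fewer than `min_controls` (10)
  usable controls falls back to one array-wide control curve. Ten points
  is roughly the minimum for a loess with span 0.3 to have stable local
  windows; the per-group effective span is additionally widened to keep
  at least ~10 points per window, because dilution-series controls clump
  in A.
* *No usable controls at all* is an error, not a silent global loess —
  on an SSH array a clone-based curve would remove the biology.

**Between-array normalization.** A-values are quantile-normalized across
arrays (each array's sorted A replaced by the across-array mean at that
rank; ties share their ranks' mean). M-values are never touched. Note
that with ties — which arise from integer-quantized intensities — the
sorted A columns after normalization agree only up to the local tie gaps;
they are identical on tie-free data.

## The per-clone model

The two within-array duplicates of a clone are collapsed to their
quality-weighted mean M per array (the collapsed weight is the mean of the
duplicate weights, so weights stay in [0, 1]). Modelling the duplicate
correlation explicitly was considered and rejected: averaging is unbiased,
keeps the degrees-of-freedom bookkeeping per array, and with only two
duplicates the correlation parameter would be poorly identified.

For each clone, signed observations y_i = orientation_i · M_i (orientation
±1 encodes the dye swap) are combined by weighted least squares:
beta = Σw·y/Σw, s2 = Σw·(y−beta)²/d with d = (number of used
observations − 1), stdev_unscaled = 1/√Σw. Variances are then moderated:
a scaled-F prior (d0, s0²) is estimated across clones by the standard
method-of-moments on log variances, and

* s2_post = (d0·s0² + d·s2)/(d0 + d),
* t = beta/(stdev_unscaled·√s2_post) on d0 + d degrees of freedom
  (normal when d0 is infinite, which is the correct answer when the
  clone-wise variances show no excess spread),
* p-values are two-sided and Benjamini–Hochberg adjusted over the
  library's clone universe (`n_tests`; by default the number of clones
  with at least one usable observation, configurable because the spotted
  and screened counts can legitimately differ),
* the B-statistic is the log posterior odds of differential expression
  with prior probability `prior_p` = 0.5 — the defensible prior for a
  subtracted library, as opposed to the ~1% typical of whole-genome
  arrays. Changing `prior_p` (or v0, the variance of true log-ratios,
  estimated by moment-matching the top |t| values and floored at
  0.1·mean(stdev_unscaled²) for numerical safety on null data) shifts B
  but never reorders the moderated t.

Clones with a single usable observation are exactly the case
empirical-Bayes shrinkage rescues: they take s2_post = s0² on d0 degrees
of freedom. Clones with no usable observation carry NA and are excluded
from ranking.

## Top tables, quadrants, plots

The primary table per library has the eight published columns (ID,
logFC(ER3), AveExpr, t, P.Value, adj.P.Val, B, invER2) plus quadrant and
library, sorted by p with ties broken by |t| then ID for reproducibility.
A symmetric secondary table reports the ER2 contrast's own statistics (is
the clone significantly rare?). Quadrant labels follow the published
caption convention — forward: (+,−) Up.Rare, (+,+) Up.Abundant, (−,+)
Down.Rare, (−,−) Down.Abundant; reverse flips Up and Down. Note the
convention pairs "Rare" with negative inverse ER2 only on the
positive-ER3 side; the (−,−) corner is labelled Down.Abundant even though
its inverse ER2 is negative. Zero ER3 classifies with the positive side
and zero inverse ER2 with the abundant side: the boundary is a
measure-zero set and determinism matters more than the choice. The ER
plot highlights the `top_n` (300) most significant clones at
`alpha` = 0.05.

## Sequence redundancy grouping

Vector/adaptor trimming aligns each clone sequence against a small
vector/adaptor FASTA (both strands, local alignment, minimum score 16)
and removes maximal terminal runs of vector hits; an interior hit marks
the record as a putative chimera and rejects it. The packaged default
database contains *synthetic stand-ins* for cloning-vector arms and SSH
adaptors (`synthetic_vector_arms.fasta`); real screens should supply the
actual vector sequences via `vector_db`. Trimmed inserts shorter than
`min_length` = 30 nt are rejected — below that length no alignment can
reach the E-value cutoff anyway.

Pairs are scored by exact affine-gap local alignment (match +1, mismatch
−2, gap open 5, gap extend 2) over both relative strands, with a shared
11-mer prefilter to skip hopeless pairs, and converted to E-values
E = K·m·n·e^(−lambda·S) with lambda = 1.28, K = 0.46 — constants
approximating ungapped nucleotide-BLAST statistics for this scoring, kept
configurable. Pairs with E < 1e-10 are linked; groups are the connected
components. Transitive closure is a deliberate choice: overlapping
fragments of one transcript chain into one group even when the end
fragments share nothing, and it is the only partition stable under
incremental uploads (`add_to_groups()` preserves existing group ids,
merging under the smallest id involved). The longest member represents a
group (ties by smallest id); annotation defaults to the best imported hit
below the cutoff and can be overridden by a curation table.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` writes a complete, readable experiment: duplicate
spotting in replicate half-slides (duplicates are deliberately far apart,
as on the real arrays), a control row per block cycling four alien probes
through a 5-step two-fold dilution series, spike mass ratios 45/45/4.5/
0.45 ng with top spotting concentrations 100/130/150/180 ng/µl (the
compensating concentrations are what lets all four probes light up), three
contrast slide sets of `arrays_per_contrast` = 4 with two dye swaps each,
a smooth cubic dye bias of amplitude `dye_bias_amplitude` = 0.5 log2 units
applied to the Cy5 channel, exponential clone intensities
(`signal_scale` = 3000 fluorescence units) over normal background
(mean 400, SD 30) — matching the normexp assumption, with a gamma-signal
mode for misspecification checks — per-spot log2 noise `noise_sd` = 0.35,
~1% bad flags plus naturally dim spots giving ≈3% unusable spots overall,
10% truly DE clones at mean |log2 ratio| 2 (90% in the library's own
direction; the remainder emulate subtraction escapes), and 90% rare
transcripts. Redundant-partner structure is planted by cutting clone
fragments from shared transcripts, with vector contamination taken from
the packaged vector FASTA so trimming is exact.

Real data differ in ways the generator does not model: spatial artefacts
beyond print-tip structure, saturation, carry-over between adjacent
spots, sequence-dependent hybridization efficiency, and intensities that
are *rounded* but not otherwise discretized. Two knock-on consequences
are documented here deliberately: with `noise_sd = 0` the residual error
is the integer quantization of the written intensities (so "noiseless"
recovery is exact only to ~0.01–0.05 log2 units), and because the
generator gives control spots the same `noise_sd` as clones, the
control-spot M SD reduction from normalization is milder than on real
arrays, where controls are far less noisy than clones. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not performance guarantees on any particular real data set.

## Problem sizes and determinism

The test suite works at two scales, chosen to keep a full run inside a
few minutes on one CPU: a small bundle (300 + 300 clones, 8 blocks, 12
arrays) for unit-level checks, and the generator's default conditions
(2000 + 2000 clones, 24 blocks, 12 arrays) for the end-to-end
power/sign-accuracy checks; null-calibration and hyperparameter-recovery
simulations use 5 000 and 20 000 clones at the model level (no array
generation). Every stochastic step is seeded; the same configuration and
seed reproduce byte-identical GPR files and truth tables. The null
calibration check draws genewise variances from a scaled inverse
chi-square — the hierarchical model the moderated t assumes; under a
strictly homoskedastic null the finite estimated prior df leaves the
extreme p-values slightly miscalibrated, a known property of the method.

## Known limitations

* Only single-coefficient dye-swap designs are modelled; multi-factor
  designs and intensity-dependent variance trends are out of scope.
* The B-statistic's v0 is estimated once per contrast, not per clone
  subset.
* Grouping is O(pairs that share an 11-mer); for libraries of many
  thousands of sequenced clones an indexed aligner would be preferable.
* The Karlin–Altschul constants are approximations for gapped alignment;
  the E-value cutoff of 1e-10 is conservative enough that this does not
  affect grouping in practice, and the constants are configurable.
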