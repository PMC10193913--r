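---
title: "Methods: sequence-based flexibility, disorder, and their discrepancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based flexibility, disorder, and their discrepancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqflex)
```

## The model and its assumptions

`seqflex` predicts local side-chain flexibility from primary sequence
alone. The underlying assumption is compositional: each of the 20
amino acids carries a characteristic intrinsic mobility, observable as
its average crystallographic B-factor once thermal factors are
standardized per structure,

$$nBf_i = \frac{B_i - B_m}{B_\sigma},$$

with the sample mean $B_m$ and the sample ($n-1$) standard deviation
$B_\sigma$ of the structure's residue B-factors.
`normalize_bfactors()` implements exactly this standardization (output
mean 0 and sample SD 1, to numerical precision); the sample rather
than population SD is used because it is the common convention for
B-factor normalization and keeps small series well defined. Aggregated
over large structure sets, standardized B-factors yield a 20-residue
propensity scale; the packaged default is the average normalized
B-factor flexibility scale of Vihinen, Torkkila & Riikonen (1994),
which satisfies the orderings the analysis relies on (Leu above Phe,
Lys above Arg).

A sequence profile is the windowed average of scale values: residue
$i$ receives $\sum_d w_d\, s(\mathrm{aa}_{i+d})$ over a symmetric
window. Because the weights are positive and renormalized wherever the
window is truncated at a terminus, every profile value is a convex
combination of scale values and is bounded by the scale range — an
invariant the test suite checks against a brute-force oracle. A
residue read as `X` contributes the unweighted mean of the 20 scale
values, keeping the arithmetic defined without biasing it.

The segment index is the arithmetic mean over an inclusive residue
range,

$$mBf = \frac{1}{n}\sum_{i=\mathrm{start}}^{\mathrm{end}} nBf_i,$$

reported as a positive number where larger means more flexible. Two
companion values are always available: `relative = 1/mBf`, the form
used when flexibilities are drawn as bar heights, and `literal_eq2 =
-mBf`, for compatibility with formulations that write the mean with a
leading minus sign. Only the positive `mBf` enters any comparison in
this package, because reference values for ion-channel segments are
uniformly positive (roughly 1.25–2.4) and larger values are described
as more flexible; emitting both forms makes the convention explicit
rather than implicit.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| scale | `vihinen1994` | normalized B-factor | published, complete, satisfies known orderings |
| window width | 3 | residues (odd) | immediate N- and C-terminal neighbours only |
| window weights | 0.25, 0.5, 0.25 | sum to 1 | centre residue weighted as both neighbours together |
| `epsilon` | 0.01 | pD clamp | below the reporting resolution of per-residue predictors; keeps `nBf/pD` finite at pD = 0 |
| `k` | 2 | SD of log-quotient | conventional ~2-sigma outlier cut |
| `threshold` | 0.5 | pD | midpoint of the probability scale for binary disorder calls |

Wider windows (5, 7, …) smooth profiles further; the default keeps the
profile local because helical transitions of interest span a single
turn. All parameters are recorded in every pipeline run's `config.txt`
so a bundle is self-describing.

## Calibration: putting a scale on reference units

Reference mBf values for ion-channel segments exist on the units of a
per-residue table that was never published. The package therefore
treats the scale's *units* as a free affine degree of freedom and its
residue *ordering* as fixed scientific content: `calibrate_scale()`
fits one gain and one offset, shared by all 20 residues, by least
squares of anchor targets on raw anchor mBf values. Since mBf is
affine in the scale (weights sum to one), the fit is exact for two
anchors and over-determined beyond that; a non-positive or
unidentifiable gain falls back to an offset-only fit with a warning
rather than silently reversing residue order.

The packaged reference table (`printed_mbf_reference.tsv`) carries the
anchor targets: the two 3₁₀ anchors (targets 1.6 and 2.08) are used
for fitting and the two remaining anchors (2.4 and 1.4) are held out.
The full-length sequences of the four reference proteins are not
redistributed with the package, so the leave-out protocol is exercised
on *synthetic anchor segments*, generated to carry the reference
targets under a known affine distortion of the packaged scale (gain
5.9, offset −4.0, chosen so the targets map into the scale's range).
The protocol must then recover that distortion from the two fitting
anchors alone; `scripts/acceptance.R` reports the held-out residuals.
This validates the calibration machinery end to end. It does not — and
cannot, offline — validate the anchor values against the reference
proteins' actual sequences; users with those sequences in hand can run
the identical protocol on them via `calibrate_scale()` directly.

## Disorder tracks and the naive stand-in

Per-residue disorder probabilities are consumed, not predicted: the
generic dialect (`residue_number`, `residue`, `pd`) and the PrDOS
per-residue CSV export are parsed, validated into $[0,1]$, and paired
residue-by-residue with flexibility profiles. Length mismatches and
residue-letter disagreements are hard errors — silent truncation would
misalign every downstream quotient.

So the pipeline is testable with no external server, a clearly
labelled stand-in scorer (`naive_disorder_score()`) smooths the
TOP-IDP per-residue disorder propensity under the same window and
min–max rescales it using the *table's* extrema (not the
sequence's). Anchoring at the table extrema keeps scores comparable
across proteins, which sequence-local rescaling would destroy. The
stand-in is a deterministic composition heuristic: it reproduces the
broad tendency of flexible compositions to be disordered, and nothing
more. Tests and examples that use it say so; no result obtained with
it is presented as a predictor's output.

## Discrepancy quotients, dispersion, and flagging

Flexibility and disorder are related but not equivalent: one is a
side-chain degrees-of-freedom property, the other the absence of
stable structure. After clamping pD to $[\varepsilon, 1]$, the
package forms both reciprocal quotient tracks (`white = nBf/pD`,
`black = pD/nBf`, product exactly 1). Dispersion per protein is
reported on the raw white track (sample SD and SEM $= SD/\sqrt{n}$,
an exact identity in the implementation), matching how such
dispersions are conventionally tabulated; a reported (SD, SEM) pair
therefore back-solves to the analysed span length as $(SD/SEM)^2$.

Flagging operates on $\log(\mathrm{white})$, the only scale on which
the two reciprocal tracks are symmetric — inverting every quotient
flips the sign of each log-value, so the same residues are flagged
with directions exchanged, a property the tests verify. A residue is
flagged when its log-quotient deviates from the track mean by more
than $k$ track SDs; above the mean is `flexible-but-ordered`, below is
`rigid-but-disordered`. Under a Gaussian log-quotient null the flag
rate at $k = 2$ is the familiar ~4.6%.

## What the synthetic generator emulates

`generate_sequence()` draws uniform sequences (optionally restricted
to the stiff/flexible scale quartiles), and can steer the
whole-sequence mBf to a target by greedy single-residue substitution
(best improvement, leftmost tie-break), run to a local optimum; the
achieved gap must be within 0.05 of the target and is typically
~1e-5, the accuracy the calibration protocol needs once a gain of
~6 amplifies raw-scale errors.

`generate_disorder_track()` couples disorder to flexibility through a
logistic link: $pD = \mathrm{logit}^{-1}(a\,u + \epsilon)$ with $u$
the standardized profile, $\epsilon \sim N(0, \sigma_{\mathrm{noise}})$
and $a = \sigma_{\mathrm{noise}}\,\rho/\sqrt{1-\rho^2}$, the gain for
which the linearized link attains correlation $\rho$ (default target
0.8, realized within about 0.1 at length 300; the acceptance script
recomputes this). The default $\sigma_{\mathrm{noise}} = 0.1$ keeps
pD in a realistic mid-range band for transmembrane domains. Injected
discrepancy sites move the log-quotient at random positions by a
stated number of its baseline SDs in a random direction, and the
positions and directions are returned as ground truth.

What the generator does *not* emulate: real TRP/Kv residue
composition, autocorrelated disorder along the chain beyond window
smoothing, predictor-specific artefacts, or segment architecture.
Passing recovery experiments therefore demonstrate that the
pairing/quotient/flagging machinery detects controlled violations of
a known link — not that it would detect discrepancies in any
particular real protein.

Two quantitative caveats of the recovery design are worth stating
because they are visible in the reported rates. First, detection of a
3-SD injection against a roughly Gaussian null with a $k = 2$ cut has
probability near $P(|N(3,1)| > 2s) \approx 0.8$ once the injections
themselves inflate the flag-stage SD ($s \approx 1.07$), so measured
sensitivity sits at the 0.8 boundary and fluctuates a few percent
across seed sets. Second, precision with 5 true sites among 300
residues is bounded by the null flag rate: at $k = 2$ the ~3–4% null
exceedance contributes roughly 9–13 false flags per run against at
most 5 true positives, capping pooled precision near 0.3. High
precision at $k = 2$ and a ~4.6% Gaussian-null flag rate are mutually
exclusive at this site density; raising `k` (or flagging on a robust
scale estimate) trades the null rate against sensitivity. The
package reports both numbers as measured and leaves `k` a parameter.

## Numerical choices and degenerate inputs

* Terminal windows are truncated and renormalized, never padded, so
  convexity (and hence scale-range bounds) holds everywhere.
* A constant B-factor series ($B_\sigma = 0$) is an error, not a
  division by zero; a constant quotient track warns and flags nothing.
* Coordinates are 1-based and inclusive at both ends everywhere, with
  an explicit per-record `numbering_offset` so fragment fixtures keep
  full-length numbering; all range errors name the valid span.
* `X` is the only non-standard residue accepted (scale mean); B, Z,
  U, O and gaps are rejected at parse time with position and character.
* Greedy mBf targeting breaks ties at the leftmost position, making
  generation reproducible bit-for-bit for a fixed seed; the disorder
  track uses `seed + 1` so sequence and track draws do not share a
  stream.

## Problem sizes

The shipped experiments use anchor segments of 25 residues, recovery
sequences of length 300 with 5 injected sites over 100 seeds, and
40-seed grids for the effect-size sweep — sizes at which every
stochastic summary above stabilises to the precision discussed while
the whole suite runs in seconds.

## Known limitations

* The packaged scale is a published literature scale, not the
  (unpublished) table behind the reference mBf values; absolute mBf
  units are therefore meaningful only after calibration, and only the
  machinery — not the reference sequences — is validated offline.
* The stand-in disorder scorer is not a disorder predictor; real
  analyses should import predictor output.
* The helix-class comparison is descriptive (rank-sum as a helper
  statistic); segments from homologous channels are not independent
  samples, so no inferential claim is made, and all-pairwise
  comparisons apply a Benjamini–Hochberg correction only as a
  convenience.
* Grouping relies entirely on the user's segment annotations; the
  package does not infer helix classes from sequence or structure.
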