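---
title: "Comparing HLA class I immunopeptidomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing HLA class I immunopeptidomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
library(dplyr)
```

This vignette is the package's account of the statistical methods it
implements, the choices made where the methodology was genuinely open,
and the limits of what its synthetic-data tests demonstrate.

## The analytical problem

Eluted-ligand mass spectrometry yields, per HLA allotype, a table of
peptide identifications with per-identification confidence scores.
Comparing the repertoires of micropolymorphic allotypes requires a chain
of analyses that are individually simple but sensitive to conventions:
which identifications to keep, how to tabulate and compare motifs, how to
call a residue "enriched" relative to the source proteome, how to detect
dependencies between peptide positions, how to compare repertoires in a
physicochemical rather than purely symbolic space, how to count shared
peptides when the two data sets were sampled with different depth, and
how to turn targeted-MS areas and melt curves into comparable numbers.
`immunopep` fixes each convention explicitly and tests each stage against
generators with known ground truth.

## Filtering and identity

`filter_repertoire()` applies, in order: the confidence cutoff
(`confidence >= cutoff`, applied per record *before* pooling replicates),
contaminant removal (endogenous-HLA ligand list, generic contaminant
list, and substring matching against HLA protein sequences), and
deduplication by identity key, keeping the highest-confidence instance
with ties broken by first occurrence so output is deterministic. The
default cutoff of 95 approximates a 5% local FDR in common search-engine
output; exact per-replicate values (typically 95.2–97) can be supplied.
Ambiguous residue codes (B, J, O, U, X, Z) are rejected at read time with
a row-level error report rather than recoded: every downstream statistic
assumes the 20-letter alphabet.

Two identity modes exist because both are legitimate: modified and
unmodified forms of a sequence are distinct species
(`sequence_plus_modifications`, the default for overlap analysis), but
motif work and cross-study comparison are usually done by bare sequence
(`sequence_only`). Every result object records which mode produced it.

## Enrichment against a background proteome

For peptides of one length, the observed prevalence `p_obs = k/n` of a
residue at a position is compared with its background prevalence `p_ref`
using the normal approximation to the binomial:

$$z = \frac{p_{obs} - p_{ref}}{\sqrt{p_{ref}(1-p_{ref})/n}}$$

two-sided at `alpha = 0.05`. Significant cells are displayed on the
fold-change scale conventional for ligand-enrichment plots: `FC =
p_obs/p_ref >= 1` for enrichment, the converted fold change `FC_con =
-1/FC <= -1` for depletion, and a `-100` sentinel for residues absent
from the data. The variance uses the *reference* proportion — the test
asks whether the observation is consistent with sampling from the
proteome — which means the z magnitude is not symmetric under swapping
observed and reference distributions (the sign is; the package's tests
assert exactly that).

The embedded background is the mean amino-acid composition of the
reviewed human proteome (Swiss-Prot). Proteome releases drift by ~0.1
percentage points per residue, which propagates to a few percent of a
fold change; comparisons against values computed with other tool/release
combinations should allow roughly ±0.05 on FC. A FASTA-derived
background is supported, with a `1e-6` frequency floor so a residue
absent from a small FASTA cannot produce an infinite fold change.

Under the null (peptides drawn i.i.d. from the background), the
expected fraction of significant cells is slightly below the nominal 5%
because the binomial is discrete at modest `n`; the acceptance suite
measures ~4.8–5.0% over 200 seeded repertoires of 500 nonamers.

## Positional coupling

Statistical coupling between sites asks how the residue distribution at
site *j* moves when the peptide set is conditioned on a residue at site
*i*. For each residue *x* with subset count `n_x >= n_min`:

$$\Delta_{ij|x} = \sqrt{\sum_a \tilde f_{j|x}(a)\,
  \ln^2\!\frac{\tilde f_{j|x}(a)}{\tilde f_j(a)}}, \qquad
  \mathrm{coupling}(i,j) = \sum_x \frac{n_x}{n}\,\Delta_{ij|x}$$

with smoothed frequencies `f~ = (1 - eps) f + eps/20` (`eps = 0.05`).
Two design choices deserve justification:

* **Frequency weighting.** An unweighted sum of squared log-ratios over
  all 20 residues is dominated by residues that are merely *unobserved*
  in a small conditioning subset: each sampling zero contributes a large
  log-ratio that is pure noise, giving the statistic a positive bias
  proportional to the number of unobserved residues. At realistic
  repertoire sizes this ranks independent position pairs above genuinely
  coupled ones. Weighting each residue's squared log-ratio by its
  conditional frequency suppresses exactly those cells while leaving
  real distributional shifts intact.
* **Subset-size-independent smoothing.** Smoothing frequencies by
  mixture with the uniform distribution (rather than adding
  pseudo-counts, whose effect depends on the subset size) makes two
  identities exact: a site with an invariant residue has zero coupling
  with every other site, and duplicating the data set leaves the matrix
  unchanged. Both are verified in the test suite.

The subset floor defaults to `max(10, 0.1 n)`; conditional frequencies
from smaller subsets are sampling noise. The diagonal reports positional
conservation against a background `q` — by default the repertoire's own
pooled all-position composition, optionally a proteome reference; the
choice is exposed because neither is canonical. The matrix is reported
in full (conditioning is not symmetric) with a symmetrised mean-of-
transposes view for ranking and display. No claim is made that this
estimator reproduces any particular historical script numerically; its
calibration instrument is `coupling_permutation_null()`, which shuffles
each column independently, and the package requires an injected coupled
pair to exceed the null's 95th percentile.

## Physicochemical PCA and clustering

Peptides of one length are encoded position-major as four
physicochemical descriptors plus 20 identity indicators per position.
The descriptor scales are not canonical in the literature, so the
package fixes a documented, overridable set: average residue molecular
weight (Da), Kyte–Doolittle hydropathy, the theoretical maximum
accessible surface area of Tien et al. (2013) (Å²), and free-amino-acid
isoelectric points. Columns are standardised to zero mean / unit
variance before PCA — unavoidable when mixing daltons, Å² and 0/1
indicators, though it is a modelling choice that changes loadings
relative to an unstandardised analysis. Zero-variance columns are
dropped and recorded; a fully degenerate matrix (identical peptides) is
a typed error, not a silent result.

PCA is computed by SVD; each component is oriented so its
largest-magnitude loading is positive, making outputs reproducible up to
no ambiguity at all rather than up to sign. k-means (10 restarts, seeded)
runs on the first two component scores for each candidate `k` (default
2–6), and `k` is chosen at the peak of the mean silhouette coefficient.
Cluster labels are renumbered by increasing PC1 centre so labellings are
stable. Each peptide length is analysed independently. A fitted model
can classify new peptides via `encode_peptides(..., encoding = )` plus
`predict()`, which is how the package demonstrates the cluster-bias
inversion property: flipping a repertoire's Trp/Phe PΩ balance flips its
majority cluster within an unchanged basis.

## Overlap and the rescue rule

Data-dependent acquisition undersamples: a peptide confidently
identified in one eluate may be genuinely present but unsequenced in
another. The rescue rule operationalises this: dataset D's effective set
is everything at `confidence >= 95` in D, plus anything at
`confidence > 20` in D that reaches 95 in a *compared* data set (the
comparison set is the current call only). Confidence boundaries follow
that wording exactly: primary inclusive, rescue strict. Because the
published convention for denominators is ambiguous,
`overlap_proportions()` reports percentages against both the effective
and the core (unrescued) set sizes. With `rescue_cutoff =
primary_cutoff` the rule provably degenerates to plain intersection,
which the tests verify against a brute-force oracle on random instances.

## MRM validation and relative abundance

A (peptide, experiment) pair is a detection candidate only when all of
the peptide's 3–4 transitions co-elute; "co-elute" is operationalised as
a retention-time spread below `co_elution_tol` (default 0.2 min — a
value chosen as typical chromatographic peak width at base, exposed in
configuration because no protocol states it). Candidates with an
MRM-triggered MS/MS event in that experiment are confirmed; the rest are
rescued only if the peptide has confirmed detections elsewhere, the RT
lies within ±1.5 min (inclusive) of their mean, and the spectral dot
product exceeds 0.7 (strict). The dot product is the normalised inner
product of square-root-transformed intensities over the fragment union —
the convention of the targeted-proteomics library software ecosystem;
disjoint spectra score 0, and a single shared fragment is treated as an
error rather than evidence.

Quantification divides the summed transition areas by the experiment's
β2-microglobulin area (the amount of HLA captured), then expresses each
peptide as a proportion of its maximum normalised abundance across all
experiments in the call — a deliberate choice of the widest comparison
span, recorded here because per-panel normalisation is also defensible.
Proportions are invariant to per-experiment loading and to uniform
rescaling of any experiment's areas and β2m together, and recover
ground-truth proportions exactly at zero noise; at lognormal area noise
of sdlog 0.2 the rank correlation with truth exceeds 0.9 in the seeded
test.

## Thermal melts

Dye-based melt traces rise through the unfolding transition and then
decay as aggregates form and dye is released; a two-state model does not
describe the decay, so the trace is truncated at its global fluorescence
maximum before fitting the Boltzmann sigmoid

$$F(T) = B_l + \frac{B_u - B_l}{1 + e^{(T_m - T)/s}}$$

by Levenberg–Marquardt least squares, initialising `Tm` at the maximum
of the smoothed derivative (centred moving average, window 5). A trace
is declared transition-free — a typed error, never a silent number —
when the fluorescence maximum sits too early to leave a fittable rise,
when the fit fails, or when the fitted slope exceeds a quarter of the
scan span or `Tm` leaves the data range (a straight line fits only as an
absurdly broad sigmoid, which these bounds reject). Fitted `Tm` is kept
at full precision internally (so temperature-shift equivariance holds
exactly) and rounded to 0.1 °C in reports. Replicate summaries use the
sample (n−1) standard deviation; ΔTm = mean(variant) − mean(reference)
is classified by the conventional 1 °C rule, matching typical replicate
scatter. Published replicate-mean Tm values for the HLA-B57-family
complex series ship as a plain-text table (`b57_tm_summaries()`) and are
used as fixed inputs to the ΔTm arithmetic — the package does not claim
to re-derive instrument-software Tm values from unavailable raw traces.

## The synthetic-data module

Generators are pure functions of their specification (seed included) and
emulate exactly the structure each stage consumes: position-specific
profiles with anchor biases over a proteome-like background
(`anchor_profile()`), optional joint residue-pair injections for
covariation, confidence distributions with a low-confidence tail and
contaminant spikes, MRM areas as truth × fragment intensity × loading ×
lognormal noise with β2m factors proportional to loading, and Boltzmann
curves with post-peak decay and Gaussian noise. The bundled
`b57_example_spec()` mirrors the qualitative contrasts of the B57 family:
shared Ser/Thr/Ala/Val P2 and aromatic PΩ anchors, a Trp-major versus
Phe-major PΩ split, PΩ−2 Arg enrichment in one allotype only, and an
injected P2–PΩ coupling.

What the generators deliberately do **not** emulate bounds what passing
tests show about real data: synthetic allotypes are sampled
independently, so they share essentially no sequences (real repertoires
overlap heavily because they sample one proteome); there are no
post-translational modifications, no position-dependent detectability or
ionisation bias, no correlated confidence structure across replicates,
no chromatographic interference, and melt noise is i.i.d. Gaussian
rather than temperature-correlated. Green property tests therefore
demonstrate that the statistics behave as designed under their stated
models, not that any biological conclusion follows automatically from
real data.

## Problem sizes and numerical conventions

The test and acceptance suites run at sizes chosen to make sampling
error small relative to the tolerances they assert: 200 repertoires of
500 nonamers for null calibration, 500–1000 peptides for PCA recovery
and coupling detection, 20 peptides × 9 experiments for MRM, and 100
melt curves over 50–85 °C. Tolerances follow from the generators: ±3
binomial standard errors for frequency recovery, adjusted Rand > 0.9 for
planted clusters, rank correlation > 0.9 at sdlog 0.2, Tm bias < 0.05 °C
and RMSE < 0.2 °C at 2% noise. All stochastic code funnels through
seeded generators or `withr::with_seed()`; `run_pipeline()` stamps every
summary with the seed and a configuration hash, and reruns are
byte-identical.

## Known limitations

* The enrichment test treats positions and residues as independent
  binomials; it does not correct for multiple testing across the 20 × L
  cells (matching the display convention it implements), and the normal
  approximation under-rejects slightly for rare residues at small n.
* The coupling estimator is one member of a family of perturbation
  statistics; magnitudes are comparable within a matrix, not across
  studies or estimators.
* PCA standardisation and descriptor scales are choices, exposed but
  influential; loading rankings should be read qualitatively.
* MRM support starts at integrated transition areas; peak picking,
  transition optimisation and absolute quantification are out of scope.
* Melt fitting assumes a single two-state transition; multi-domain
  unfolding will be truncated or rejected rather than decomposed.
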