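---
title: "Methods: sex-bias screening and X-inactivation escape domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-bias screening and X-inactivation escape domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapex)
```

escapex implements a complete analysis chain for detecting sex-biased gene
expression on microarray-style log2 intensity data and for characterising
X-chromosome domains in which a female-biased protein-coding gene lies next
to a female-biased long non-coding RNA — the genomic signature of loci that
escape X-inactivation. Because the interesting behaviour of every stage
depends on knowing the truth behind the data, the package ships a
first-class simulator that generates annotation, expression, histone-mark
peaks and qPCR measurements with a recorded ground truth. This vignette
explains the statistical procedures, the parameters that matter, and the
design decisions taken where more than one defensible convention exists.

## The screening model

The expression unit is an `expr_set`: a probes × samples matrix of log2
intensities plus per-sample metadata (recorded sex, tissue, platform).
The screen proceeds in four steps, each its own function:

1. **Per-array standardization** (`standardize_arrays()`). Every sample
   column is affinely mapped to mean 8 and standard deviation 2 on the
   log2 scale — the conventional post-normalization scale for the array
   collections this pipeline emulates. We fix the *population* (1/n)
   standard deviation; either convention is defensible, but one must be
   chosen for bit-reproducibility, and the map is then exactly idempotent.

2. **Xist-based sex QC** (`xist_sex_check()`). Xist is transcribed only
   from the inactive X, so its signal is near-binary between the sexes
   (roughly four orders of magnitude). For each Xist probe a threshold is
   placed at the midpoint of the recorded-female and recorded-male
   medians; an array is flagged as sex-discordant only when *all* its
   Xist probes fall strictly on the wrong side of their thresholds. With
   the usual two probes this is exactly the "opposite quadrant" geometry
   of an Xist scatter plot. Medians are used because they are robust to
   the very mislabels the rule is hunting; requiring discordance on all
   probes is the conservative reading of the quadrant rule — an array
   discordant on one probe of two is retained.

3. **Sex balancing** (`balance_by_sex()`). After dropping flagged arrays,
   the larger sex group in each tissue is down-sampled uniformly at
   random (seeded) to the size of the smaller, so that the rank test sees
   equal group sizes.

4. **The screen itself** (`screen_tissue()`). Each probe is tested with a
   two-sided Wilcoxon–Mann–Whitney test comparing females to males. The
   nonparametric test avoids normality assumptions on per-probe signal
   distributions. p-values are adjusted by the Benjamini–Hochberg step-up
   procedure across *all probes of one tissue* — tissues are screened and
   reported separately, so the tissue is the natural BH family — and
   probes with adjusted p ≤ 0.05 are reported with a signed linear fold
   change, `+2^(Δmean)` for female-up and `−2^(−Δmean)` for male-up, so
   |FC| ≥ 1 and the sign encodes direction.

The U statistic is computed from joint midranks. The p-value is exact
(from the null U distribution) when the combined sample size is at most 12
and no ties are present; otherwise the normal approximation with tie
correction and continuity correction is used. The cut at combined n = 12
is a convention fixed here: real tissue screens involve tens of arrays per
sex, where the approximation is excellent, while the exact branch serves
very small designs. A vectorised batch path computes the approximation for
thousands of probes at once; the test suite verifies it row-by-row against
the scalar function, against `wilcox.test()`, and — for every group size
with combined n ≤ 10 — against brute-force enumeration of all label
assignments.

## Chromosome enrichment and cross-tissue structure

`chrom_enrichment()` summarises each tissue's hit list as observed vs
expected counts of *distinct genes* per chromosome (multiple significant
probes of one gene count once). The expected count allocates the
significant genes proportionally to annotated gene content, so expected
counts sum exactly to the number of significant genes; over-representation
is tested with the hypergeometric upper tail, the natural choice for
drawing genes without replacement from the finite set on the array.

`intersect_hits()` reports, for every subset of tissues, both the
exclusive Venn region (hits in exactly those tissues) and the plain
intersection; the exclusive regions partition the union of hit genes.
`classify_genes()` splits sex-chromosome genes into previously described
sex-biased genes — via a curated list shipped as an editable fixture
(`inst/extdata/known_sex_linked_genes.txt`) rather than hard-coded,
because it is curated knowledge, not computation — and novel candidates;
all other genes are autosomal.

## Escape domains and the co-localization null

Candidate escapee domains are built by `pair_coding_noncoding()`: each
female-biased non-coding X gene is paired with the nearest female-biased
coding X gene within 50 kb (or containing it). All coordinates are
0-based half-open; the gap is the distance between nearest interval
edges, 0 for overlap or nesting. The pair is classified as
`head_to_head` (opposite strands with 5' ends facing), `nested_intronic`
(one interval contained in the other), or `tandem`.

How surprising is it that several non-coding candidates all land next to
fixed genes of interest? `coloc_permutation_fdr()` answers with a
permutation null: hold the anchor genes fixed (the Xist-like and Jpx-like
loci plus the coding escapees; seven anchors by default), and in each of
10^4 permutations draw k = 4 distinct non-anchor X-linked probes uniformly
without replacement. A permutation succeeds when all four probes fall
within 50 kb up-/downstream of some anchor (gene body extended ±50 kb —
the windowing is body-anchored because nothing in the domain structure
singles out the TSS). The reported FDR is the success fraction. Three
conventions deserve note:

* draws exclude the anchors' own probes — letting the null draw an
  anchor's probe would trivially manufacture successes;
* draws are without replacement, matching the observed configuration of
  four distinct loci;
* success requires *all* k probes co-localized, since the observed
  configuration was 4 of 4.

Because in-window membership is a fixed per-probe property, the estimator
has a closed form, `choose(n_in, k) / choose(n_total, k)`, exposed as
`analytic_coloc_probability()` and used throughout the tests as the
independent oracle: the permutation estimate must sit within three
binomial standard errors of it across a parameter grid. At realistic
density — a 166 Mb X carrying ~1,000 probes and seven ≤10 kb anchors, so
~770 kb of windows — the all-four-in probability is ~10^-10 and the
permutation FDR rounds to 0.00.

`domain_peak_coverage()` scores repressive-mark depletion: the fraction
of a domain covered by the union of peak intervals, the mean coverage of
its two flanking windows (100 kb each by default), and their ratio.
Interval unions are computed with IRanges; the tests check 1,000 random
peak sets against a hand-written sweep-line union oracle. The ratio is
reported as `Inf` when flanks are bare but the domain is covered, and 0
when the domain is bare.

## qPCR validation

`fit_standard_curve()` regresses Ct on log10 relative input over a cDNA
dilution series; the amplification efficiency is `E = 10^(-1/slope) − 1`
(ideal slope −1/log10(2) ≈ −3.32, E = 1). `quantify()` inverts the curve
to relative copy numbers; undetermined wells propagate as `NA`. Ct values
are treated as already background-subtracted by the instrument software.
`normalize_geomean()` divides each target by the geometric mean of two
endogenous controls (Actb- and Gapdh-like), cancelling per-sample loading.
`compare_sexes()` reports the ratio of female to male mean normalized
expression with per-group standard errors and a two-sided unequal-variance
(Welch) t-test, starred at 0.05/0.01/0.001. The test runs on *linear*
normalized values, mirroring the ratio-of-means presentation; running it
on logs would be equally defensible, and the choice is recorded here as a
convention.

## What the simulator emulates — and what it does not

`generate_annotation()` realizes a genome with one ~166 Mb X, one Y, and
configurable autosomes. The X carries four coding/non-coding template
pairs laid out with the characteristic arrangements of the known escape
domains — a head-to-head pair separated by 33 kb, a lncRNA inside an
intron of its coding partner, a tandem pair 2.6 kb downstream, and a
head-to-head pair separated by 9.7 kb — plus a partner-less coding
escapee, an X-inactivated control locus, four Y-linked paralogues and one
autosomal female-biased gene. The Xist-like locus carries two probes, as
the sex QC expects. Remaining probes are placed uniformly at random.

`generate_expression()` draws per-probe baselines from N(8, 2) on the
log2 scale (matching the standardized shape of the real data), adds
planted effects — female-positive for the escapee templates, uniform in
log2(1.1)..log2(2) because most real sex-bias effects sit between 1.1-
and 2-fold; male-positive for Y probes; ~13.3 log2 units (~10^4-fold) for
Xist — and Gaussian noise. Y-linked probes in females and Xist-like
probes in males emit floor-level signal (default log2 intensity 2) rather
than missing values, because arrays report an intensity for every probe.
Label mislabeling flips only the *recorded* sex; Xist-like and Y signals
follow the true sex, which is exactly what makes mislabels detectable.
`noise_sd` has no external anchor and defaults to 0.5 log2 units, chosen
so that planted 1.1–2-fold effects are detectable but not trivial at
40–60 arrays per sex.

One wrinkle: a *global-null* data set (no effects anywhere) is
incompatible with always-planted templates, so `sim_config()` exposes
`plant_templates`; with `plant_templates = FALSE` and
`frac_sex_biased = 0` every true effect is zero, which is the
configuration the FDR-calibration suite uses.

The simulator does **not** emulate probe-level raw data, normalization
artefacts, cross-probe correlation, batch structure, platform-specific
probe content, or per-tissue effect heterogeneity: a gene's planted
effect is shared across tissues. Passing tests therefore demonstrate the
correctness and calibration of the analysis chain on data with the
*assumed* statistical structure, not robustness to the full messiness of
real arrays.

`generate_peaks()` tiles the X with ~800 bp peaks at 1 kb spacing
(coverage ≈ 0.8) while leaving the escapee domains bare, so depletion
scores have a known answer; `generate_qpcr()` builds dilution series with
the ideal slope plus Ct noise and encodes planted female/male ratios on
top of a per-sample loading factor that the geometric-mean normalization
must remove.

## Numerical choices and degenerate inputs

* Standardization errors on constant columns, naming the sample.
* `xist_sex_check()` errors when a recorded-sex group is empty or all
  Xist values are identical (thresholds undefined).
* p-values are floored at the smallest positive double so they stay in
  (0, 1]; `bh_adjust()` rejects values outside (0, 1].
* `compare_sexes()` on two noiseless groups returns p = 1 for identical
  means and the smallest positive double otherwise (an infinite t in the
  limit).
* Sub-seeds for pipeline stages are derived deterministically from the
  global seed and the stage name, so `run_pipeline()` is bit-reproducible
  and any stage can be re-run in isolation with the same randomness. All
  derived seeds stay below 2^31 − 1.

## Problem sizes used by the test suite

The suite favours designs large enough to be informative and small enough
to run comfortably on a laptop: FDR calibration uses 200 null replicates
of 1,000 probes at 43 vs 43 arrays; power checks use planted 2-fold
effects at 60 vs 60; QC recovery uses 100 replicates at 15 vs 15 with 10%
mislabels; the permutation-vs-analytic grid uses 4,000 permutations per
point; the coverage oracle uses 1,000 random peak sets. The end-to-end
ground-truth recovery run screens four tissues (43/43/60/60 arrays per
sex) over 600 probes under a pinned seed: with planted effects as small
as 1.1-fold, single-tissue detection of every escapee is not guaranteed —
genes drawn near the low end of the effect range fall below the power of
a rank test at these sample sizes — so the multi-tissue union is the
realistic route to full domain recovery, just as multiple tissues were
screened in the motivating design.

## Known limitations

* Gene "intervals" in the simulator are probe-sized for filler genes;
  only template genes have realistic extents. Pairing distances are
  therefore exact by construction rather than subject to annotation
  noise.
* The permutation null treats probes as exchangeable points; real probe
  placement is clustered by gene density, which would make the null
  conservative or liberal depending on where anchors sit.
* The Welch test on linear normalized qPCR values can be heavy-tailed for
  strongly expressed targets; log-scale testing is a one-line change if
  preferred.
* The curated known-genes list is a fixture, not a database lookup, and
  should be edited for organisms or assemblies other than the one
  emulated here.
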