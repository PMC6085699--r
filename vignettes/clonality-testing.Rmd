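---
title: "Classifying tumour pairs as clonal or independent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumour pairs as clonal or independent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpair)
```

## The problem

When a breast cancer patient presents with a second invasive tumour — in
the opposite breast (bilateral) or the same breast (ipsilateral), shortly
after the first diagnosis (synchronous) or years later (metachronous) —
the clinical question is whether the second tumour is a *clonal
recurrence* of the first or a *new independent primary*. The two
scenarios call for different treatment: a recurrence signals failure of
the first therapy, an independent primary does not. Histopathology alone
(histological subtype, ER/HER2 status, molecular subtype) is a weak
instrument for this question, so molecular profiles of both tumours are
compared instead: two tumours that grew from one progenitor cell must
share that progenitor's early driver aberrations — copy-number changes
with the *same breakpoints*, the *same* point mutations and fusion
breakpoints — on top of whatever each clone acquired privately during
subclonal drift.

The catch is that two *independent* tumours are not molecularly
unrelated either: aberrations recurrent in the tumour-type population
(e.g. gains on 1q, 8q, 16p, 17q, 20q and losses on 1p, 8p, 11q, 13q, 16q
in breast cancer) will be shared by chance. Every test in this package
therefore calibrates its statistic against an empirical null built from
**artificial pairs**: all cross-patient combinations of two tumours from
the same cohort. For $n$ patients with two tumours each there are $n$
true pairs and $2n(n-1)$ artificial pairs.

## The similarity index family

Probe-level profiles are first discretized into three states. All
thresholds are strict — a value exactly at a cut-off stays in the
neutral class:

| platform | states | cut-offs |
|---|---|---|
| copy number (aCGH log2, methylation intensity, SNP LRR) | loss / normal / gain | $< -0.3$ / $> +0.3$ |
| expression log2 ratio | under / neutral / over | $< -0.58$ / $> +0.58$ (1.5-fold) |
| methylation beta | U / H / M | $< 0.2$ unmethylated, $> 0.8$ methylated, else hemi-methylated |

For two discretized copy-number (or expression) profiles, each common
probe is classified as a **shared** change ($N_S$: both aberrant, same
sign), a **unique** change ($N_U$: aberrant in exactly one), an
**opposite** change ($N_O$), or neutral in both. The similarity index is

$$SI = \frac{N_S}{N_S + N_U + N_O} \in [0, 1].$$

Probes neutral in both tumours are deliberately excluded: sharing the
*absence* of an aberration carries no evidence of common origin. When no
probe is aberrant in either tumour the SI is undefined and the pair is
reported `not_evaluable` rather than 0 or 1.

Methylation has no biologically neutral state (neither methylated nor
unmethylated plays the role that two-copy neutrality plays for DNA), so
the methylation variant $SI_{met}$ is simply the fraction of common
probes with an identical three-level state — hemi-methylated matches
included — and is always defined.

Two p-like quantities accompany the SI, both computed from the
artificial-pair null:

* $P_{SI} = \max\!\big(0,\; 100\,(SI - \overline{SI}_{null})/SI\big)$,
  the percentage of the pair's similarity not attributable to recurrent
  aberrations or chance. This formula is a reconstruction: the original
  description of the index delegates $P_{SI}$ to earlier software
  without printing a formula, and we adopted the form above because a
  single cohort-wide null mean then reproduces SI/$P_{SI}$ value pairs
  reported for the index in the literature consistently within
  rounding.
* an add-one empirical p-value
  $p = (1 + \#\{SI_{null} \ge SI_{obs}\}) / (1 + \#null)$, one-sided
  (large SI = evidence of clonality). The pseudo-count avoids exact
  zeros; the smallest attainable p with $m$ artificial pairs is
  $1/(m+1)$. The clonality call uses $p < \alpha$ with $\alpha = 0.05$.

## The other pair tests

* **Euclidean distance** over common probes; a true pair is clonal when
  its distance lies at or below the empirical 5th percentile of the
  artificial-pair distances. Percentiles use the linearly interpolated
  empirical quantile (R type 7).
* **Dendrogram cherry**: single-linkage hierarchical clustering of all
  samples on Euclidean distances; a pair is clonal when its two samples
  form a cherry, i.e. their first merge joins exactly those two leaves.
  Samples are sorted lexicographically before clustering so merge-order
  ties resolve deterministically; when more than two samples merge at
  identical height the pair counts as a cherry only if its merge node
  has exactly the two leaves as children. Under single linkage a pair is
  a cherry if and only if the two samples are mutual nearest neighbours
  strictly closer to each other than to any third sample — we use this
  equivalence as an independent test oracle.
* **Shared segments**: in segmented copy-number profiles, a segment is
  shared when both tumours have a segment with the exact same start and
  end breakpoints and the same direction (both gain or both loss);
  normal segments never count. The call is clonal when the count is
  strictly *above* the 95th percentile of the artificial-pair counts —
  note the deliberate asymmetry with the distance rule (at-or-below),
  mirroring the wording of the respective decision rules. A breakpoint
  tolerance (default 0 bp) is available for cross-platform grids.
* **Shared mutations**: variants identical on (chrom, pos, ref, alt),
  optionally restricted to a user-supplied panel of mutation-spot
  regions first; same 95th-percentile rule. The panel itself is not
  distributable and must be provided as a region file.
* **Fusion overlap**: fusions with identical 5′ and 3′ partner
  breakpoints. Exact breakpoint coincidence between unrelated tumours
  is essentially never observed, so the reported rule is descriptive:
  clonal iff at least one fusion is shared.

Segment status, when absent from a SEG file, is re-derived by
thresholding the segment mean at ±0.3 — the same cut-offs as the probe
discretization.

## Consensus across methods

Per-method calls are assembled into a patient × method matrix.
Agreement between two callers is unweighted Cohen's kappa on the two
categories clonal/independent,
$\kappa = (p_o - p_e)/(1 - p_e)$, with `not_evaluable` entries dropped
pairwise; constant-and-equal call vectors leave $p_e = 1$ and $\kappa$
undefined (`NA`). The per-patient consensus tally reports
clonal-calls / evaluable-methods. The summary treats the copy-number SI
as the headline label — it is the method designed for the question and
the easiest to interpret — with all other methods reported alongside.

Clinical concordance (histology, ER, HER2, molecular subtype, with
`ND` = not determined excluded from denominators) is reported next to
the molecular calls but never merged into them: concordant
histopathology is not evidence of clonality.

## The synthetic cohort generator

No patient-level molecular data could be redistributed with the
package, so testing rests on a seeded generator whose defaults encode
the study conditions the analyses assume:

* a genome of 22 autosomes (10^8 bp each) partitioned into `n_blocks`
  candidate aberration blocks; every event occupies whole blocks, so
  two tumours share exact breakpoints precisely when they carry the
  same event — the property the shared-segment test keys on;
* **hotspots**: ten recurrent regions (the arms listed above) each
  carried with population frequency 0.3. A clonal pair inherits its
  progenitor's hotspot draws; independent tumours draw independently,
  so they share hotspot events at rate $f^2$;
* **founder events** (default 8) drawn once per clonal patient and
  present in both tumours; **drift events** (default 3) private to each
  tumour; segment means ±0.6, safely beyond the ±0.3 cut-offs;
* probe log2 ratios are block means plus Gaussian noise (default SD
  0.15); beta values are generated on the logit scale with a per-probe
  population mean and a tumour-level effect shared within clonal pairs;
* variants are drawn from a pool of recurrent polymorphic sites, so
  unrelated tumours share variants at rate
  $n_{variants}^2 / pool$ (germline-like chance sharing); clonal pairs
  additionally share a founder fraction (default 0.5). Fusions are
  private except for a configured shared count in clonal pairs;
* clinical features flip between the two tumours with probability 0.05
  (clonal) vs 0.3 (independent) — loosely coupled on purpose, because
  clinical concordance and molecular clonality are distinct phenomena
  and the package must not conflate them.

Output is bit-identical for a fixed config and seed (one sequential RNG
stream; reordering patients changes the stream, so reproducibility is
claimed for a fixed config only). What the generator does *not*
emulate: wave artefacts and GC bias of real arrays, segmentation errors
(breakpoints off by a few probes), subclonal fractions and tumour-cell
content, linkage between neighbouring probes beyond block structure,
and realistic site-frequency spectra for variants. Tests passing on
synthetic cohorts therefore validate the statistical machinery — null
calibration, ranking, decision rules — not platform-specific
preprocessing, which is assumed done upstream.

## Calibration design

Three presets freeze the study conditions used by the package's own
validation:

* `sim_config_null()` — 20 independent patients, 500 probes, and
  deliberately *diffuse* chance-sharing distributions: a dense block
  grid (4400 blocks, 2000 drift events per tumour) and germline-scale
  variant lists (3000 variants over 15000 sites). The reason is
  statistical: the segment and mutation tests reject when a count is
  strictly above the interpolated 95th percentile, so the attainable
  type-I level is quantised by the probability mass function of the
  null count. With a null SD around 20 the quantisation step is a few
  tenths of a percent and the empirical level can be meaningfully
  compared with the nominal 5%; with sparse counts (null mass
  concentrated on 0–3, as in a realistic low-burden cohort) the strict
  rule is conservative by construction and its level is not a useful
  diagnostic. The distance statistic is continuous and calibrates in
  either regime.
* `sim_config_strong()` — 8 founder events, noise SD 0.05, half the
  patients clonal: the regime where the SI should essentially recover
  ground truth (accuracy ≥ 0.9 over seeds).
* `sim_config_twin()` — no drift, no noise, everything shared: both
  tumours identical, SI exactly 1, sensitivity must be 1.

One empirical caveat found while validating the generator: the mean SI
of clonal pairs is monotone decreasing in probe noise only while the
noise SD stays at or below the ±0.3 discretization threshold. Beyond
it, random miscalls dominate and concordant random calls push the SI
back up towards its chance floor ($p/(2(1-p))$ for tail probability
$p$), so the monotonicity property is only asserted on the
signal-dominated grid.

## Numerical choices and degenerate inputs

* Strict threshold inequalities everywhere; boundary values are
  neutral/hemi-methylated.
* Empirical quantiles with linear interpolation (type 7).
* Fewer than 20 artificial pairs make any percentile test
  `not_evaluable` (with a warning) rather than silently unstable.
* Undefined SI (no aberrant probe in either tumour) propagates as
  `not_evaluable`.
* Pair operations use the intersection of probe identifiers and error
  below 2 common probes.
* Coordinates are 1-based with inclusive ends (SEG convention);
  chromosome names are normalised by stripping any `chr` prefix. Sex
  chromosomes are kept in I/O but excluded by default from
  population-frequency summaries.
* No multiplicity correction is applied across patients by default;
  each pair is a separate clinical question.
* Metachronous means an interval strictly greater than 183 days (six
  months); the packaged cohort has no interval near the boundary, so
  the day-level convention is observationally neutral there.

Problem sizes used by the shipped validation suite — 500 zero-signal
cohorts of 20 patients × 500 probes for null calibration, 50
strong-signal seeds for recovery, 200 random cohorts for the cherry
oracle, 1000 random state-vector pairs for the SI oracle — were chosen
as the smallest sizes at which the Monte-Carlo bands are tight enough
to be informative (3 Monte-Carlo SDs around the nominal level).

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config_strong(seed = 1))
run <- run_clonality(co$manifest, co$profiles,
                     segments = co$segments, variants = co$variants,
                     fusions = co$fusions, clinical = co$clinical)
run$call_matrix[1:4, ]
run$kappa$mean_kappa
head(run$tally)
recover_labels(co, "si")[c("accuracy", "sensitivity", "specificity")]
```

## Known limitations

* The $P_{SI}$ formula is a documented reconstruction (see above), not
  a re-implementation of the original software.
* The likelihood-ratio clonality test of the external "Clonality"
  package, array normalisation, segmentation algorithms and
  fusion/variant calling from reads are all out of scope; inputs are
  taken as already normalised and segmented.
* Whether the artificial-pair null should include the true pairs
  themselves is ambiguous in the literature; this package uses
  artificial pairs only.
* The cherry rule makes the clustering call depend on the whole cohort
  (adding one sample can break a cherry); that cohort dependence is a
  property of the method, not of the implementation.
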