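---
title: "Methods: signature scoring, subtype assignment and composition correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring, subtype assignment and composition correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosig)
```

# Scope

`prosig` classifies bulk expression samples of prostate tissue into
molecular subtypes by correlating per-sample gene-set signatures against
reference subtype profiles, corrects those signatures for the benign-tissue
component of heterogeneous samples, and quantifies cohort structure
(patient, grade, composition) in signature space. This vignette records
the statistical model, every tunable that matters, the design decisions
taken where the design was genuinely open, and the limits of what the
accompanying tests demonstrate.

# The signature model

## Running-sum scores

For one sample, genes are ranked by expression after each gene has been
mean-centered across the cohort (centering removes gene-specific baselines;
what remains is the sample's deviation profile). For a gene set $GS$ with
$S$ of the $N$ scored genes, the walk statistic adds $d_{in}$ when passing
an in-set gene and $d_{out}$ otherwise:

$$d_{in} = \sqrt{\tfrac{N-S}{S}}, \qquad d_{out} = -\sqrt{\tfrac{S}{N-S}}.$$

These are the classic unweighted Kolmogorov–Smirnov increments: they
satisfy $S\,d_{in} + (N-S)\,d_{out} = 0$, so the partial sum returns to 0
at the end of the list and the running-sum maximum (Score$^+$) and minimum
(Score$^-$) are meaningful measures of concentration at the top and bottom
of the ranking. A variant with increments $(N-S)/S$ and $-S/(N-S)$
(`variant = "literal"`) is retained behind a flag; its walk terminates at
$N - 2S$, which systematically inflates small sets, and it is not
recommended.

Two score reductions are available:

* `score_type = "total"`: Score$^+ - $ Score$^-$. Direction-blind — a set
  whose genes pile up at the *bottom* of the ranking scores as high as one
  piled at the top.
* `score_type = "signed"` (default in `fit_subtypes()`): whichever of
  Score$^+$ and $|$Score$^-|$ is larger, with its sign, so depleted sets
  get low values after normalization.

The signed default is a deliberate design decision. In a cohort that mixes
tumor and benign tissue, every sample is *depleted* of the programs it
lacks, and under the direction-blind total that depletion masquerades as
enrichment. Two parts of the method only make sense direction-sensitively:
depleted chromatin-repressor target sets should read as *low* signature
values, and the normal-signature subtraction (below) must push a
contaminated signature *away from* the normal profile, which requires
contamination to have moved it *toward* that profile in the first place.
We verified the latter empirically: with the direction-blind total the
measured signature-space contamination coefficient on the average normal
signature is negative over the realistic composition range, and the
subtraction then degrades assignments; with the signed score it is positive
and monotone in the normal fraction. `gsea_walk()` itself defaults to the
symmetric total so its three walk scores remain the primitive quantities.

Ties in the ranking are broken by input gene order (a stable radix sort),
so results are reproducible across platforms. Sets are intersected with the
matrix genes before scoring; a set retaining fewer than `min_set_size = 5`
genes triggers a warning (tiny sets make fragile walks), and an empty set
is dropped with a warning.

## Normalization

Raw totals are not comparable across samples or sets, so three
normalizations are offered (`normalize_signatures()`):

* `per_sample` (default): min–max rescaling of each sample's scores onto
  $[0,1]$. Chosen as default because it resembles the clinical situation —
  a fixed panel of gene sets evaluated on one new patient at a time.
* `per_set`: min–max across samples within each set.
* `random_set_pvalue`: empirical $p$-value of each score against `B`
  random gene sets of the same size drawn from the scored genes, with
  add-one smoothing, $p = (1 + \#\{\text{random} \ge \text{obs}\})/(B+1)$,
  so $p$ is never exactly 0.

A constant score vector cannot be min–max scaled; it is mapped to 0.5 with
a warning rather than aborting a cohort run, and the downstream correlation
step then fails explicitly (and only) for that sample.

# Subtype assignment

Each sample signature is Pearson-correlated with each row of a reference
matrix (subtypes × gene sets, values in $[-1,1]$; such matrices are
typically digitized by eye from published heatmaps, so the package treats
them as editable configuration — a clearly synthetic template ships in
`inst/extdata/`). The $n$ in all tests is the number of gene sets entering
the correlation (15 by default), not the number of genes or samples.

Correlations that share the sample vector are compared with Steiger's test
of dependent correlations, pinned to the averaged-correlation covariance
variant: with $z = \operatorname{atanh}(r)$ and
$\bar r = (r_{jk} + r_{jh})/2$,

$$s = \frac{r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{kh}^2)}{(1-\bar r^2)^2},
\qquad Z = \frac{\sqrt{n-3}\,(z_{jk} - z_{jh})}{\sqrt{2 - 2s}}.$$

The published family of dependent-correlation statistics has several
variants; one must be fixed for reproducibility, and this is the one
implemented. The test is **one-sided** by default (upper tail, "$j$
correlates better with $k$ than with $h$") because the assignment criterion
is directional and a threshold of $\alpha = 0.5$ — the loosest level the
assignment rules accept — is only coherent one-sided. $Z$ is antisymmetric
under swapping the two candidate references, so $p$ and its swap sum to 1;
this is what makes exclusive assignments unique and bad/good prognosis
calls mutually exclusive for $\alpha \le 0.5$ (alphas above 0.5 are
refused). Preconditions: $n \ge 4$ (the $\sqrt{n-3}$ factor), $|r| < 1$
(finite Fisher transform); samples violating them are reported
unassignable, not silently dropped.

Assignment modes:

* **exclusive** — assigned to subtype $X$ only if $p(r_X > r_Y) < \alpha$
  for every other subtype $Y$;
* **prognosis** — called *bad* if some bad-prognosis subtype beats both
  good-prognosis subtypes at $\alpha$ (the two bad subtypes need not differ
  from each other), *good* by the mirror rule, else unassigned.

No multiple-testing correction is applied across samples: thresholds are
interpreted per sample, and cohort-level error control is out of scope.

# Composition correction

With $SE_{AVG}$ the element-wise mean signature of all pure-normal samples
and $frac$ the histological fraction of normal tissue in a cancer sample:

$$PR_{corrected} = PR - SE_{AVG}\cdot\frac{frac}{1-frac}.$$

The correction is applied to *normalized* signatures, and corrected values
may leave $[0,1]$; they are deliberately not renormalized, since
renormalizing would destroy comparability between samples. It is the exact
algebraic inverse of additive signature-space contamination
$PR_{obs} = PR_{true} + SE_{AVG}\cdot frac/(1-frac)$ (the tests verify
recovery to machine precision). $frac$ is the fraction of **normal**
tissue; metadata supplied as `percent_cancer` is converted explicitly,
because silently confusing the two is the classic failure mode of this
formula. $frac \ge 1$ is undefined and $frac > 0.95$ is refused — the
subtraction factor $frac/(1-frac)$ diverges, and a "cancer" sample that is
19 parts normal has no usable cancer signature (0.9, factor 9, is the
strongest factor intended for real use, including the control analysis
that applies it to normal samples via `include_normals = TRUE`).

# Cohort analyses

Within/between-group correlation reports enumerate each unordered sample
pair exactly once (self-pairs excluded) under four groupings: patient and
Gleason (cancer samples only), sample type (within = cancer–cancer and
normal–normal, between = cancer–normal), and normal-vs-cancer by patient
(normal–cancer pairs split by shared patient). Group location is compared
with the two-sided Mann–Whitney rank-sum test: correlations are bounded and
non-normal, so a rank test is the safe default; the underlying values are
returned so any other comparison can be substituted.

Hierarchical clustering uses correlation distance $1 - r$ and **single
linkage** by default — the default of the standard hierarchical-clustering
routine in the scientific-Python stack, which this analysis mirrors —
configurable to average/complete/Ward. Leaf order (left-to-right dendrogram
order) is the exported sample/set ordering. The cluster-neighbor statistic
counts samples whose immediate left or right neighbor in leaf order comes
from the same patient (the strictest reading of "shares a cluster
neighbor"), compares the count to its permutation null (labels fixed,
positions shuffled), and reports the add-one-smoothed upper-tail $p$.

# The synthetic cohort generator

`simulate_cohort()` produces, per gene $g$ and sample $i$,

$$x_{gi} = (1-f_i)\,c_{gi} + f_i\,m_g + \varepsilon_{gi},$$

with $c_{gi}$ the cancer component (an `effect_size` shift on the genes of
the sample subtype's characteristic sets, plus a per-patient Gaussian
gene-level shift shared by the patient's samples), $m_g$ a fixed
normal-tissue program, $f_i$ the normal fraction, and
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. noise. Pure normal samples are
$m_g + \varepsilon$.

Defaults (one sentence of rationale each):

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 500 | enough background for stable walks at desk-scale runtimes |
| `set_sizes` | 15 × 15 | fifteen sets mirror the reduced signature panel; 15 genes keeps set-level sampling noise realistic |
| `n_patients`, `samples_per_patient` | 40, 3–4 | a prostatectomy cohort of ~140 samples from 40 patients with repeated sampling |
| `subtype_prevalences` | .40/.30/.17/.13 | bad-prognosis-dominant, as observed in radical-prostatectomy cohorts |
| `effect_size` | 3 (units of noise SD) | a strong but not deterministic program shift |
| `patient_effect_sd` | 1.5 | reproduces pronounced within-patient signature homogeneity |
| `noise_sd` | 1 | reference scale |
| `good_overlap` | 0.8 | benign prostate tissue resembles the good-prognosis profile, which is why contamination dilutes bad-prognosis calls and why normals classify as good |
| `frac_normal_range` | U(0, 0.6) | histological normal fractions of cancer samples |
| `p_normal_sample` | 0.25 | roughly a quarter of samples are pure benign tissue |

The normal program is set-structured: an `effect_size` shift on its own
characteristic sets (one fifth of the panel) plus `good_overlap ×
effect_size` on the good-prognosis sets and a residual gene-level
$N(0, 0.5^2)$ profile. This matters: an unstructured normal program has far
less gene-set-level spread than the tumor programs, which makes the
$frac/(1-frac)$ subtraction wildly over-scaled; benign tissue in reality
carries a coherent expression program of comparable strength, and modeling
it that way is what gives the correction a correctly-scaled target.

`subtype_by = "patient"` (default) draws one latent subtype per patient —
the within-patient homogeneity the analysis is designed to detect. The
`"sample"` option draws subtypes independently per sample and exists as the
negative control: together with `patient_effect_sd = 0` it removes *all*
patient-level structure, so within- and between-patient correlation medians
must coincide. (With per-patient subtypes, setting the patient effect to
zero alone is not a clean control — shared subtype is itself a patient
effect.)

`make_reference_from_truth()` scores one noise-free prototype per subtype
(its pure characteristic-set shift) through the standard pipeline and uses
the normalized prototype signatures as reference rows. With disjoint
characteristic sets the rows are near-orthogonal, standing in for a
digitized published reference matrix.

**What the generator does not emulate:** probe-level microarray noise,
batch effects, correlated gene–gene covariance within sets, non-linear
mixing, gene-set overlap with curated redundancy, survival outcomes, or any
association between Gleason score and subtype (scores are drawn
independently, matching the reported absence of such an association).
Passing recovery tests on these cohorts therefore demonstrates the
*pipeline's* correctness under its stated model, not clinical performance
on real tissue.

One consequence observed and accepted: under linear expression-space mixing
with these effect sizes, the subtraction step increases bad-prognosis calls
(and never removes one) but does not increase the *total* number of
assigned samples — the marginal good-prognosis calls it costs are not fully
offset, because rank-based signatures render contamination with a smaller
coefficient than $frac/(1-frac)$. The direction of the Table-style effects
(bad calls rescued, initially-bad calls retained, good calls thinned,
within-patient similarity sharpened) is reproduced and asserted by the
tests; a net gain in assigned samples is not asserted.

# Numerical choices and degenerate inputs

* Walk-score agreement with brute-force enumeration is asserted at
  $10^{-12}$; zero-termination of the weights at $10^{-9}$ (values
  accumulate over up to 500 increments).
* Min–max of a constant vector → 0.5 with a warning (see above).
* Constant signatures and $n < 4$ raise a classed condition
  (`prosig_unassignable`); cohort drivers convert it to an `unassigned`
  call with a warning rather than aborting.
* Degenerate covariance in the dependent-correlation test
  ($2 - 2s \le 0$, possible only for jointly inadmissible correlation
  triples) is an error, not an NaN.
* Empirical p-values and permutation p-values use add-one smoothing.
* All stochastic steps (generator, random gene sets, permutation nulls)
  take explicit seeds; a seeded run is bit-reproducible.

Problem sizes used by the test-suite: the default cohort (500 genes, ~140
samples), a 250-gene/10-set small cohort for unit tests, 4000 replicates
for the type-I calibration of the dependent-correlation test, a 2401-point
grid for the mutual-exclusivity check, and 10^4 permutations for the
neighbor statistic. These sizes were chosen to make the Monte-Carlo bands
tight relative to the assertions they support.

# Known limitations

* The reference-matrix values for real analyses must be supplied by the
  user (digitization of published heatmaps is inherently approximate); all
  shipped numbers are synthetic.
* The correction operates in signature space after per-sample
  normalization; whether to subtract before or after normalization is not
  identifiable from the method description it follows, and the
  after-normalization choice is fixed here and documented.
* One-sided testing and the specific covariance variant of the
  dependent-correlation statistic are pinned choices among published
  alternatives.
* The 21→15 related-set grouping used with curated panels is user input
  (`mapping=`); no grouping is invented by the package.
* No survival modeling: "bad"/"good" prognosis labels are inherited from
  the reference matrix, not estimated from outcomes.
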