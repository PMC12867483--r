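---
title: "Methods: median-effect synergy scoring and pan-cancer prioritization"
author: "SynergyScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: median-effect synergy scoring and pan-cancer prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynergyScreen)
```

# Scope

SynergyScreen implements the computational core of a drug-combination
screening study: an epigenetic-inhibitor panel combined with a PARP
inhibitor in HR-proficient ovarian/breast cancer cell lines, scored by the
Chou–Talalay combination index; a five-feature priority score for ranking
the panel; a formula-defined siRNA impact score; directional pan-cancer
meta-analyses of expression and survival; dependency summarisation,
hallmark-signature correlation ranking, and enrichment testing; and
rule-based BRCAness gene-catalog assembly. A seeded simulator generates
every input with planted ground truth, so each stage can be validated by
parameter recovery rather than by re-downloading the original cohorts.

# The median-effect model and the combination index

A single agent's dose–response is summarised by the median-effect equation

$$\frac{fa}{fu} = \left(\frac{D}{D_m}\right)^m, \qquad fu = 1 - fa,$$

where $fa$ is the fraction affected (1 − normalized viability), $D_m$ the
median-effect dose (the IC50), and $m$ the sigmoidicity slope.
`fitMedianEffect()` estimates $(m, D_m)$ by ordinary least squares on the
linearization $\log(fa/(1-fa)) = m\log D - m\log D_m$, reporting the
linear correlation $r$ as the usual conformity diagnostic. Fractions
affected are clipped into $[10^{-6}, 1-10^{-6}]$ before the logit —
clipped, not dropped, with a per-fit count — because plate readouts
routinely produce $fa \le 0$ (growth stimulation) or $fa \ge 1$ at the top
dose, and dropping those points would bias the slope. A fitted $m \le 0$
is flagged as a non-monotone curve and kept with a warning status so a
74-inhibitor screen does not abort on one bad well series.

For a drug pair dosed at $(d_A, d_B)$ producing effect $fa$, the two-term
(mutually exclusive) combination index is

$$CI = \frac{d_A}{D_{x,A}(fa)} + \frac{d_B}{D_{x,B}(fa)},
\qquad D_x = D_m\left(\frac{fa}{1-fa}\right)^{1/m},$$

computed pointwise at each observed dose pair — no interpolation grid is
used, because the screen evaluates five fixed constant-ratio dose pairs.
The three-term mutually-nonexclusive variant is deliberately not
implemented: the screen reports a single CI per dose point. A combination
is summarised by the *median* of its per-point CIs over points with $fa$
strictly inside $(0,1)$; the source description says "medium CI value",
which we read as median (a mean summary is available behind
`center = "mean"`). Classification uses the screen's printed thresholds —
synergism below 0.83, additive in the closed interval $[0.83, 1.2]$,
antagonism above 1.2; both boundaries belong to "additive" because the
printed interval is closed.

The universal correctness check is the sham combination: a drug combined
with itself at any dose split must give $CI = 1$ under Loewe additivity.
The test suite asserts this to $10^{-9}$ over random fits and splits.

# The synthetic screen

`simulateSingleAgent()` evaluates the median-effect curve and adds
additive Gaussian noise on the $fa$ scale, clipped to $[0,1]$. The noise
model is a convention, not a claim about crystal-violet readouts (the
source states none): additive on the viability scale matches how
absorbance noise propagates through per-plate normalisation, and clipping
keeps the median-effect inverse defined. The default screen conditions are
five-point serially constant twofold dilution designs centred at half the
fitted IC50 of each agent (`constantRatioDesign()`), three replicates, and
noise SD 0.02 on the viability scale.

`simulateCombination()` *inverts* the CI definition: given single-agent
fits and a planted interaction level $\alpha > 0$, the noiseless $fa$ at
each dose pair is the unique root of
$d_A/D_{x,A}(fa) + d_B/D_{x,B}(fa) = \alpha$. The left side is strictly
decreasing in $fa$, so bracketed root finding on $(\varepsilon,
1-\varepsilon)$ is robust; we use Brent's method to tolerance $10^{-12}$
(a guarded-bracket refinement of bisection, chosen over Newton iterations
for the same robustness reason). By construction the true CI at every
point equals $\alpha$, giving the CI estimator a recovery-style oracle:
noiseless recovery to $10^{-6}$, and under the default noise the median
CI over 100 simulated pairs stays within $\pm 0.1$ of $\alpha \in
\{0.5, 1, 1.5\}$ with at least 95% correct classification at the
0.83/1.2 thresholds.

Seeding is hierarchical: one global seed is split deterministically per
dataset label, so adding a dataset to a pipeline never perturbs the random
streams of the others, and equal configurations are bit-identical across
platforms (no reliance on unordered iteration).

# Five-feature priority score

Each inhibitor is scored on five features: median CI across screened lines
(lower better), single-agent efficacy as fitted IC50 (lower better), mean
dependency gene-effect of its target (lower better — a lower effect score
means stronger cancer-cell reliance on the gene), tumor expression
dysregulation as the up-direction meta-z (higher better), and
genomic-alteration recurrence (higher better). Features are min–max
normalised after orientation so 1 is always most favorable
(`normalizeFeature()`); the score is the weighted sum. The source states
that five weighted features were used but not the weights or the
normalisation, so weights default to equal (0.2 each), are configurable,
and are recorded in output metadata — consequently the originally
published ranking is not promised to be reproduced exactly. Inhibitors
missing a feature are imputed at the least-favorable value (0) with a
warning rather than dropped, because the screen ranks the full panel; an
all-equal feature is uninformative and maps to 0.5 with a degeneracy flag.
Ranking is a stable descending sort with deterministic lexicographic tie
breaking.

# siRNA impact score

For each candidate gene $g$, with treatment expression $exp(t)_g$,
control expression $expC_g$, knockdown IC50 $IC50(k)_g$ and control IC50
$IC50C$:

$$Fexp(t)_g = \log_2 exp(t)_g - \log_2 expC_g, \qquad
FIC50(k)_g = \frac{IC50(k)_g}{IC50C},$$

$$F'IC50(k)_g = \frac{FIC50(k)_g - FIC50(k)_{min}}
{FIC50(k)_{max} - FIC50(k)_{min}}, \qquad
Score_g = F'IC50(k)_g \cdot \sum_t Fexp(t)_g.$$

`impactScore()` ships two variants side by side. The **literal** variant
computes exactly this arithmetic. It has a structural quirk: min–max
scaling maps the panel's *strongest* sensitizer to $F' = 0$, so the gene
with the strongest combined repression-plus-sensitization signal gets
score exactly 0. The **corrected** variant replaces $F'$ with $1 - F'$
and ranks $(1-F')\cdot(-\sum_t Fexp)$ descending, so strong repression
combined with strong sensitization ranks first; it is the default for
ranking, and both scores and both ranks are always reported. The intended
reading of the published formula cannot be reconciled with its published
outcome (the top gene "had the highest impact score"), so neither variant
is asserted as the original intent — the discrepancy is documented rather
than silently resolved. The sum over treatments runs over exactly the
treatment columns present (two PRMT-inhibitor arms in the motivating
screen), unweighted; no significance cutoff is applied to $Fexp$ before
summation. Genes with missing inputs are flagged and excluded from
scaling and ranking, never silently dropped.

# Directional pan-cancer meta-analysis

Per cancer type, tumor-versus-normal differential expression uses
one-sided t-tests in both directions. We use the Welch unequal-variance
form (the source says only "one-sided t-test"); tumor and adjacent-normal
cohorts have no reason to share a variance, and Welch is the safer
default. Cancers with fewer than three normal samples are excluded, per
the stated inclusion rule, and the exclusion list is reported. For
protein-style cohorts with tumor/normal pair linkage the paired one-sided
t-test is used instead. A zero-variance stratum with equal means returns
$p = 0.5$ for both sides; with unequal means the shift is treated as
infinitely significant (floored at $10^{-300}$), a case the source does
not address.

Per direction, p-values are combined by Fisher's method,
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$, with inputs floored at
$10^{-300}$ for numeric safety, and the direction with the smaller meta-p
is reported. The signed summary is
$\text{meta-}z = \Phi^{-1}(1 - \text{meta-}p_{chosen})$, negated for the
down/protective direction — the source plots meta z-statistics without
defining the transform, so this normal-quantile convention is ours; it is
zero exactly at meta-p $= 0.5$ and positive for up-regulation/risk. Ties
between directions resolve deterministically to the first (up/risky)
label with a flag. Both directions are reported uncorrected: whether the
original analysis adjusted for testing two directions is unstated, and
under the global null each direction separately rejects at the nominal
rate while the chance that *either* direction rejects is doubled — users
combining the two directions should account for that.

Survival analysis fits per-cancer Cox proportional-hazards models
(`survival::coxph`, Efron ties) of overall survival on z-scored log2
expression — the covariate scale is unstated in the source; per-SD
hazards make the z-statistics comparable across cancers. The Wald z feeds
upper/lower-tail directional p-values (risky/protective), combined
exactly as above; positive meta-z means poor outcome with high
expression. Strata with fewer than 10 samples or 3 events, constant
covariates, or non-convergent/separated fits are excluded with a logged
reason. The implementation is cross-checked against a hand-rolled
Newton–Raphson partial-likelihood maximiser on a tie-free worked dataset
to $10^{-6}$.

Signature scoring is the per-sample mean of member genes' z-scored log2
expression — a deliberately simple convention, flagged in the output;
rank-based scorers (ssGSEA/GSVA) are out of scope, and constant genes
contribute z = 0. Hallmark correlation ranking uses Pearson correlation by
default (Spearman behind a flag; the original statistic is unstated) and
maps p-values to $\text{rank01} = (K - \text{rank})/(K-1)$ with mean ranks
on ties, so 1 marks the most significant of the $K$ signatures. Dependency
summarisation averages gene-effect scores within each cancer type and then
averages the type means, so each type counts once regardless of its
cell-line count. Enrichment testing is one-sided Fisher's exact with
Benjamini–Hochberg control across the supplied family.

# Catalog assembly

`voteAssemble()` implements $\ge k$-of-$n$ membership voting over source
gene lists ($k=1$ union, $k=n$ intersection, monotone in $k$);
`unionAssemble()` takes provenance-tracked unions.
`buildBRCAnessCatalog()` wires the published assembly: HR/FA pathway
genes are those annotated by at least two of three databases; PARPi
sensitivity genes are the union of a review list and a
literature-search list; the BRCAness set is the union of the two. Gene
identifiers are uppercased and whitespace-stripped before comparison;
HGNC alias resolution is out of scope, and fully disjoint sources trigger
a note since that usually signals an identifier-scheme mismatch. The
actual database contents enter as user-supplied files (GMT or
one-gene-per-line); reproducing the published 73- and 247-gene sets
therefore requires the original supplementary lists.

# Simulation defaults and what the tests do (and do not) show

The generator defaults encode the screen's stated conditions: five-point
twofold constant-ratio designs, planted interaction levels
$\alpha \in \{0.5, 1, 1.5\}$ spanning the three synergy classes, cohorts
of 10 cancer types with 20 tumor / 10 normal samples and planted log2
shifts of +2, survival strata of n = 200 with planted per-SD log-hazard
+0.5, and 13-candidate siRNA panels with one planted driver (log2
repression −2 under both treatments, IC50 fold change 0.25) at log-scale
noise SD 0.1. Where the source states no value — expression residual SD
(1.0 log2 units), censoring structure (uniform administrative censoring
at a 30% target rate), viability noise (SD 0.02) — the defaults are
field-typical conventions chosen once and documented here, not tuned
quantities.

Problem sizes in the checks are chosen to keep the full suite fast while
leaving comfortable statistical margins: 100 simulated pairs per
interaction level, 50 noisy refits, 1000 null genes for calibration
(simulated as independent genes in batches of 100, which is equivalent to
1000 single-gene replicates because gene-level noise is independent), 100
survival and siRNA replicates, and 10,000 random Fisher inputs.

Passing these tests shows that the estimators recover what the simulator
plants under its assumptions: Gaussian viability noise, exact
median-effect single-agent curves, log-normal-ish expression,
proportional hazards with exponential baselines, independent genes. Real
screens violate most of these — heteroscedastic and correlated plate
noise, model misfit at extreme doses, batch structure across cohorts,
correlated genes, non-proportional hazards — so recovery here validates
the *arithmetic and its calibration*, not robustness to real-data
pathologies.

# Numerical choices and degenerate inputs

* fa clipping at $\varepsilon = 10^{-6}$ before the logit; p-value floor
  $10^{-300}$ before logs and quantiles.
* Combination-surface inversion by bracketed Brent root finding, tolerance
  $10^{-12}$; the bracket always exists because the CI expression
  diverges as $fa \to 0$ and falls below $\alpha$ as $fa \to 1$, and a
  missing sign change is reported as an unattainable-effect error.
* All-equal inputs: min–max and feature normalisation return 0.5 with a
  degeneracy warning; zero-variance dose–response fits fail loudly.
* Single p-value Fisher combination returns the p-value itself exactly
  (bypassing the chi-square evaluation avoids a one-ulp wobble in the
  identity).
* Ties: direction ties go to up/risky with a flag; ranking ties break
  lexicographically; hallmark rank ties share the mean rank.

# Known limitations

* No CI confidence intervals, dose-reduction indices, isobolograms, or
  alternative synergy models (Bliss/HSA/ZIP).
* Exact numerical agreement with the originally used commercial software
  is not promised — only agreement with the median-effect formulas it
  implements (its point-weighting scheme is unpublished).
* The meta-analysis assumes independent cancer-type strata and ignores
  cross-direction multiplicity (reported, not corrected).
* Univariate Cox models only; no stratification, batch correction, or
  competing risks.
* Catalog assembly is identifier-literal; synonym mapping is the user's
  responsibility.

# Session info

```{r}
sessionInfo()
```
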