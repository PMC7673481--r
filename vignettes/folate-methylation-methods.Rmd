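---
title: "Models and methods behind foltile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foltile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foltile)
library(dplyr)
```

# Scope

`foltile` implements the analysis stack of an intergenerational
folate-diet study design: reduced representation bisulphite sequencing
(RRBS) of offspring placenta and brain cortex across four diet groups
(control, 7-fold folate-deficient, 10-fold and 20-fold folic-acid
supplemented), targeted methylation assays (LUMA, imprinted-gene
pyrosequencing), maternal-allele inheritance classification against
sperm / germinal-vesicle oocyte (GVO) / inner-cell-mass maternal allele
(ICMm) reference tracks, and litter-level reproductive toxicology
statistics. The pipeline starts at per-CpG methylated/unmethylated
count tables; alignment and methylation extraction are out of scope.
Because no public accession exists for the original sequencing data,
the package ships a first-class synthetic-data generator that emulates
the study design, so every stage is exercised end to end and scored
against planted truth.

# Tile-based differential methylation

## Aggregation and filtering

CpGs are assigned to 100-bp step-wise tiling windows (0-based
half-open; 1-based input positions are converted exactly once at the
reader boundary). A tile enters testing for a given two-group contrast
only if, in *every* sample of the contrast, it contains at least 2 CpGs
and has summed CpG coverage of at least 10 reads. The per-sample tile
methylation level is the *unweighted mean* of its per-CpG methylation
fractions. A stricter mode (`coverage_mode = "cpg"`) requires every
single CpG to reach the coverage floor; whether the original analysis
filtered before or after tiling is not documented, so filtering is
applied at the tile level after aggregation, which retains more data.

## The test

For a tile with per-sample counts $(m_i, u_i)$ and a two-level group
factor, we test the binomial logistic regression
$\mathrm{logit}(p_i) = \beta_0 + \beta_1 \cdot \mathrm{group}_i$
by likelihood ratio against the intercept-only model. With a single
binary covariate the maximum-likelihood fit of each model is the
coverage-weighted pooled proportion (per group, and overall), so the
deviance difference has the closed form

$$G = 2\left[\ell(M_c, C_c) + \ell(M_t, C_t) - \ell(M_c + M_t, C_c + C_t)\right],
\qquad \ell(M, C) = M\log\tfrac{M}{C} + (C-M)\log\left(1 - \tfrac{M}{C}\right),$$

with $M$, $C$ pooled methylated counts and coverages, and
$p = \Pr(\chi^2_1 > G)$. This is computed vectorised across all tiles;
unit tests assert equality with an explicit
`glm(cbind(m, u) ~ group, binomial)` fit. When either group has exactly
one sample the likelihood-ratio test has no replication to lean on and
a two-sided Fisher exact test on the pooled 2x2 table is used instead
(verified against full hypergeometric enumeration to 1e-10).

The group effect `delta` (treatment minus control, percentage points)
is computed from the coverage-weighted pooled counts, which is the
quantity the test sees; the unweighted means of the per-sample tile
levels are reported alongside (`mean_meth_*`), since the averaging rule
defines the tile level but no group statistic is prescribed.

## Multiple testing and DMT calling

p-values are adjusted by the Benjamini-Hochberg step-up procedure
(`stats::p.adjust`); a tile is a differentially methylated tile (DMT)
when $q < 0.01$ **and** $|\Delta| > 10$ percentage points. Both
inequalities are strict: a tile at exactly $q = 0.01$ or
$|\Delta| = 10$ is not called. DMTs carry a direction (hyper = gain in
the treated group) and a magnitude bin with boundaries at 15 and 20
percentage points. Each treated diet is contrasted against control
independently per tissue; there is no omnibus test.

## Overdispersion

The default test assumes binomial sampling within groups, matching the
behaviour of the early methylKit release this design mirrors. Under
between-replicate overdispersion the likelihood-ratio test is
anti-conservative: with a beta-binomial replicate correlation $\rho$
and per-sample tile coverage $n$, the statistic is inflated by roughly
$1 + (n-1)\rho$. `test_tiles(..., overdispersion = TRUE)` divides $G$
by a per-tile Pearson dispersion estimate (floored at 1) before the
chi-square comparison; it is off by default. For well-behaved inbred
biological replicates (the regime the generator emulates, see below)
the uncorrected test keeps the realised false-DMT rate far below the
q-threshold because the 10-point delta gate removes almost all
remaining nulls.

# Genomic annotation and cross-tissue conservation

Tiles are assigned exactly one of promoter / exon / intron /
intergenic. Assignment is precedence-first (promoter > exon > intron;
anything untouched is intergenic): a tile overlapping an exon by 40 bp
and an intron by 60 bp is exonic. Within the winning feature class the
gene with the largest overlap supplies the gene id. Promoters default
to 2000 bp upstream to 500 bp downstream of the transcription start
site, configurable, since no promoter definition is standard across
annotators. Enrichment of a category among DMTs relative to all tested
tiles is a two-sided Fisher exact test on the category-vs-rest 2x2
table, reported with the sample odds ratio.

DMT sets from the two tissues are intersected by exact tile
coordinates (both live on the same 100-bp grid). A shared tile is
*concordant* when the methylation change has the same sign in both
tissues, and *high magnitude* when at least one tissue changes by more
than 20 percentage points.

# Maternal-allele inheritance classification

Regions that normally inherit methylation from the oocyte are defined
on the 100-bp grid as sperm methylation $\le 10\%$ with **both** GVO
and ICMm methylation $\ge 25\%$. The conjunction is a deliberate
reading of "GVO/ICM $\ge$ 25%": an either-only rule would admit regions
with no maternal methylation left in the embryo. Regions missing from
any track are dropped, not imputed. Each retained region is classed by
its GVO-to-ICM dynamics with an inclusive 10-point boundary: *gain*
when ICMm − GVO $\ge$ 10, *loss* when GVO − ICMm $\ge$ 10, otherwise
*stable*; `gvo_high` flags GVO $\ge 75\%$. Intersection with a DMT set
cross-tabulates dynamic class against DMT direction with row and grand
totals, the layout used for germline-inheritance tables, and the
per-class counts always reconcile (hyper + hypo = all; class totals =
grand total), which the tests assert.

# Targeted assays

LUMA percent methylation is
$100\,[1 - (\mathrm{HpaII/EcoRI}) / (\mathrm{MspI/EcoRI})]$ with
duplicate digestions averaged *before* the formula; the printed form of
this formula is ambiguous about bracketing, and the standard
ratio-of-ratios reading is implemented. Results are clipped to
[0, 100] with a warning. Pyrosequencing summaries are per-sample,
per-gene means over the assayed CpGs of each imprinted germline DMR
(H19, Snrpn, Kcnq1ot1, Peg1, Peg3); in somatic tissue these sit near
50% because exactly one parental allele is methylated.

Group comparisons are classical one-way ANOVA; sex differences are
two-tailed t-tests, Welch's form by default since equal variances are
not guaranteed (the pooled-variance form is available; both coincide
when variances and group sizes match). `compare_assay_groups()`
encodes the pooling convention: sexes are combined for the diet
comparison when the sex t-test is non-significant at 0.05, otherwise
each sex is analysed separately. Degenerate inputs follow explicit
conventions: all-identical data give F = 0, p = 1; distinct
zero-variance groups give p = 0.

# Reproductive outcome statistics

Per litter: pre-implantation loss is corpora lutea minus implantation
sites, floored at zero with a warning because a CL miscount can make
it negative (implantations exceeding CLs warn rather than fail for the
same reason). "Post-implantation loss" is reported as the resorption
count by default; the printed definition (implantations minus
resorptions) equals the *viable* count, not a loss, so that literal
reading is also computed (`postimplantation = "literal"`) but not the
default — the original intent is not guessed beyond exposing both.

Growth classification: each control litter's mean embryo weight is
computed, then the mean $\mu$ and SD $\sigma$ of those litter means; an
embryo is growth-restricted below $\mu - 2\sigma$ and growth-enhanced
above $\mu + 2\sigma$ (strict inequalities; boundary weights are
normal). The classifier is translation-equivariant, which the tests
assert.

A litter is *abnormal-flagged* when its resorptions plus abnormal
growth classes exceed one; how multiple abnormal outcomes combine is
not stated anywhere, so they are counted additively. The
control-versus-pooled-treated comparison is Fisher's exact test. The
two-sided p sums all tables at most as probable as the observed one;
the one-sided `alternative = "greater"` variant tests for an excess in
the treated arm. On the observed study counts (4/10 control vs 24/34
treated flagged litters) the two readings give 0.13 and 0.083
respectively; the published 0.08 corresponds to the one-sided test,
which is why the reproduction script uses it, while the function
default remains two-sided as the safer convention.

Dunnett many-to-one comparisons use the single-step adjustment over
the joint multivariate-t distribution of the contrast statistics
(`multcomp::glht` with a fixed internal seed for its quasi-Monte-Carlo
integration); adjusted p-values are bounded below by the per-contrast
raw p and above by the Bonferroni bound, which the tests check against
an independently computed contrast t.

# The synthetic-data generator

The generator is the package's substitute for the study's (unavailable)
raw data and defines the conditions under which all statistical claims
are tested.

* **Genome and CpG landscape.** Two toy chromosomes of 1 Mb at ~10
  CpGs/kb by default. CpGs are laid in MspI-fragment-like clusters so a
  covered tile holds 1 + Poisson(2) CpGs — small enough for desk-scale
  runs, large enough for Benjamini-Hochberg behaviour to be realistic.
  Tests that need more tiles (e.g. false-positive-rate runs at >20,000
  testable tiles) scale `chrom_len` up, not the density.
* **Counts.** Per-tile baseline methylation is Beta(0.8, 0.8)
  (bimodal, as in real methylomes). Each sample's tile-level fraction
  is a beta draw around the baseline with intra-class correlation
  `rho = 0.005`; per-CpG coverage is negative binomial (mean 30, size
  5, floored at 1) and methylated counts are binomial. The small
  default `rho` encodes near-binomial biological replicates — inbred
  same-tissue animals — which is also the regime the study's own
  binomial-likelihood test presumes; raising `rho` to 0.02 makes the
  uncorrected test visibly anti-conservative (see Overdispersion),
  which is reproducible with the exposed config.
* **Planted effects.** 60 planted DMTs per tissue by default, deltas
  10-25 percentage points, 78% methylation gains, 9% of planted tiles
  shared between tissues with concordant sign — matching the reported
  magnitude spectrum, hyper/hypo balance and ~7-11% cross-tissue
  overlap. Baselines of planted tiles are drawn with headroom so the
  shifted methylation stays inside [0, 100]; a configuration whose
  delta cannot fit is rejected.
* **Reference tracks.** Sperm/GVO/ICMm tracks on the tile grid with a
  designated maternally inherited subset built with explicit margins
  away from every threshold (sperm < 9.5, GVO/ICMm > 26, gain/loss
  differences of at least 12, stable differences at most 8), so the
  classifier must recover the generated classes *exactly*; a fraction
  of non-maternal regions is deleted from one track to exercise the
  drop-if-missing rule.
* **Litters.** Corpora lutea are Poisson (mean 11); implantations lose
  a binomial 12% pre-implantation fraction; resorptions are binomial
  per implantation at diet-dependent rates (5% control, 8% in the
  deficient and 10-fold groups, 22% in the 20-fold supplemented group,
  emulating the reported excess); embryo weights are normal
  (1.22 ± 0.07 g within, 0.06 g between litters) with no diet effect on
  weight, as observed. Litters per diet default to 10/12/12/10, giving
  the 10 control vs 34 treated litters of the published exact test.

What the generator does **not** emulate: genomic sequence context,
coverage biases along fragments, 5-hydroxymethylcytosine confounding,
correlated neighbouring tiles, or outlier litters. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artefact of real RRBS data.

# Numerical choices and tie-breaks

* Strict inequalities at the q, delta, growth and high-magnitude
  cutoffs; inclusive inequalities at the maternal-region gates and the
  10-point gain/loss boundary (the table-footnote wording "$\ge$ 10%").
* CpG dyads on opposite strands are *not* merged by default (the
  original processing is silent on this); `destrand_cpgs()` merges
  adjacent positions by summing counts when wanted.
* Magnitude bins partition $|\Delta|$ at 15 and 20; exactly 15 and
  exactly 20 fall into the lower bin of each boundary.
* Fisher's two-sided rule is the sum of all tables with point
  probability at most that observed (the `fisher.test` convention);
  mid-p is not used.
* NA p-values are excluded from the Benjamini-Hochberg test count and
  returned as NA.
* Tile p-values from the Fisher path are clamped to [0, 1] against
  floating-point overshoot.

# Problem sizes used by the checks

The shipped verification runs use desk-scale sizes chosen to make the
statistical claims sharp without waste: false-positive-rate runs use
two-chromosome genomes sized to exceed 20,000 testable tiles (10 seeds
in the test suite); recovery runs plant 300 tiles of +20 points among
~10,000; the 1v1 oracle covers 1,000 random tiles; the permutation
oracle uses 20,000 label permutations over 6v6 designs on 50 tiles with
p in [0.01, 0.9] — the range a 6v6 permutation null (924 distinct
splits) can resolve. Per-tile agreement between an asymptotic and a
permutation p is intrinsically noisy (the permutation reference
conditions on 12 exchangeable samples), so calibration is asserted on
the ensemble: no systematic bias beyond 2-fold and per-tile scatter
within the oracle's own noise floor.

# Known limitations

* The likelihood-ratio test ignores overdispersion by default; for
  noisier designs enable the correction or expect inflated
  significance at unchanged delta.
* The annotator supports the four-category taxonomy only
  (promoter/exon/intron/intergenic); CpG-island or TSS-proximal
  subcategories would need an extended gene model.
* Dunnett adjustment relies on multivariate-t integration with a fixed
  seed; adjusted p-values are reproducible to quasi-Monte-Carlo
  accuracy (~1e-4), not bit-exact across BLAS builds.
* The pipeline tests each treated diet against control independently;
  no dose-response or omnibus modelling is attempted.
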