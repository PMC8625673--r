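---
title: "Methods: lithium-response phenotyping, CHAID trees and candidate-gene association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lithium-response phenotyping, CHAID trees and candidate-gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldaphen)
```

## Scope and model

`aldaphen` operationalizes retrospective lithium-response ratings from the
Alda scale and examines how the choice of phenotype changes candidate-gene
association signals. The scale has two parts: an A subscale (0–10, clinical
benefit while on lithium) and five B items (0–2 each) scoring circumstances
that make the A rating harder to trust — few or infrequent episodes before
lithium, short treatment duration, poor adherence, and polypharmacy. All
phenotypes are deterministic functions of these ratings except the
best-estimate pair, which requires fitting a model:

* **TS** = max(0, A − ΣB). The zero floor means the subtraction never
  produces a negative "response".
* **Alda categories**: GR iff TS ≥ 7 (boundary included).
* **A/Low B**: the raw A score, defined only where ΣB < 4; high-confounding
  subjects are excluded rather than down-weighted.
* **GRp / Algo**: a classification tree is trained on the five B items with
  a provisional label (good A-scale response, A ≥ 7), each leaf stores its
  fraction of good responders, GRp is the leaf fraction a subject routes
  to, and Algo calls GR when GRp **strictly** exceeds 0.62. The strict
  inequality follows the published cutoff's wording; at the default
  threshold the distinction only matters when a leaf fraction equals 0.62
  exactly.

The provisional label deserves a note: the original best-estimate algorithm
was trained on a large multi-site consortium sample and its exact rule set
is not published alongside the study this package models, which explicitly
sanctions refitting the model de novo on the local sample. We use A ≥ 7 as
the training label so that the tree learns how B-item configurations
modulate the apparent A-scale response. Whether the A score itself should
also enter as a predictor is left out deliberately: the published trees
enter only B items, and using A both as label source and predictor would
make the leaves trivially pure.

## The CHAID engine

The tree builder is a from-scratch CHAID implementation for binary targets.
At each node, for every candidate predictor:

1. admissible groupings of the predictor's observed categories are
   enumerated — every contiguous grouping for ordinal predictors, every set
   partition for nominal predictors (we cap the exhaustive nominal search at
   6 categories, beyond which the classic greedy merge heuristic,
   `merge_categories()`, supplies the grouping; no predictor in this domain
   comes close to the cap);
2. groupings that would create a child below `min_child` are discarded;
3. each surviving grouping's groups × classes table is scored by the
   Pearson chi-square, and the p-value is multiplied by the Bonferroni
   factor B(c, r): the Stirling number of the second kind S(c, r) for
   nominal predictors, `choose(c − 1, r − 1)` for ordinal ones, capped so
   the adjusted p never exceeds 1;
4. the grouping with the smallest adjusted p represents the predictor, and
   the predictor with the smallest adjusted p wins the node (ties break
   alphabetically by predictor name, and among groupings by enumeration
   order — ties below the p = 1 cap imply identical grouped tables, so the
   choice is cosmetic).

The node splits when the winning adjusted p is ≤ `alpha_split` (default
0.05), the node has at least `min_parent` rows, the node is not pure, and
`max_depth` has not been reached. Nodes are numbered breadth-first.

**Why an exhaustive grouping search rather than the classic greedy merge?**
Kass's original algorithm merges the most similar pair of categories
iteratively and tests the resulting grouping. The greedy path is a
1970s-era economy: it examines a single grouping per predictor and can lock
in a suboptimal pool, so its selected split need not minimize the adjusted
p — in our own experiments on small random instances the greedy grouping
differs from the optimum most of the time, and occasionally changes which
predictor wins. At this package's category counts (genotypes: 3; sex: 2; B
items: 3; binned age: ≤ 10 ordinal, i.e. ≤ 512 contiguous groupings) the
full search costs microseconds, is deterministic, and is exactly
reproducible by an independent enumeration oracle — which the test suite
exploits. The greedy merge remains available as `merge_categories()` (it is
the right tool for inspecting which categories are statistically
indistinguishable, and the fallback for high-cardinality nominal
predictors). Note that the Bonferroni factor B(c, r) is the classic
within-size correction; with the exhaustive search the selection also
ranges over r, so the adjustment is mildly anti-conservative in principle —
measured null split rates for a single three-category predictor at
α = 0.05 stay near 0.05 (see the calibration test), because the tests
across r are strongly correlated. No correction is applied **across**
predictors, as in standard CHAID; with several noise predictors the
per-node false-split rate compounds accordingly.

Other conventions: continuous predictors (age) are discretized into at most
`age_bins` (default 10) quantile bins treated as ordinal, matching common
CHAID tooling; missing predictor values form their own `"(missing)"`
category, and a predictor carrying one is handled as nominal so the missing
group can pool with any other; categories merged to a single group offer no
split; the adjusted p is stored per node together with the raw p, χ², df
and multiplier, so rendered trees (`render_tree()`, text and Graphviz DOT)
carry the full audit trail.

Default node-size minima are `min_parent = 30` and `min_child = 10` —
deliberately smaller than the 100/50 defaults of large-sample tools,
because the reference design has 164 subjects and published nodes of ~34.
`max_depth = 3` matches the shallow trees the method is used for here.

**Cross-validation** (`cross_validate()`) refits the tree on k − 1 folds
(default `cv_folds = 10`), stratified by the target and seeded from the
settings, and scores held-out subjects by their leaf's majority class. A
training fold that loses a class triggers a re-draw with a warning. A
held-out subject whose category reaches no child group (possible when a
rare category sits entirely in the test fold) is routed to the largest
child — inside cross-validation only; user-facing prediction and GRp fail
loudly on unrouteable records rather than imputing, since silent imputation
would quietly distort concordance estimates.

## Genotype quality control and SNP selection

QC follows the conventional candidate-gene filter set, applied in a single
pass over the input table: SNPs need MAF ≥ 0.05 (boundary included), call
rate ≥ 0.97, and (optionally, off by default) a Hardy–Weinberg p above a
chosen floor — HWE departures are always *reported*, via both the 1-df
chi-square test against expectations at the observed allele frequency and
an exact test that enumerates the conditional distribution of heterozygote
counts given the allele counts. Samples need call rate ≥ 0.90 and a
heterozygosity rate within mean ± 3 sd of the sample distribution. The
"average 90%" call-rate criterion in the source methods is ambiguous; we
read it as the per-sample threshold conventionally paired with a per-SNP
97% rule, and both thresholds are configurable. Dosages are always
re-expressed as counts of the empirically minor allele on reading
(`read_genotypes()`, TSV or VCF v4.2 via `vcfR`), so QC never depends on
file allele order; an exact 0.5 frequency keeps the file coding.

Per-gene SNP selection reproduces the published procedure: prune SNP pairs
with LD r² > 0.05 (keeping the member more associated with the Total
Score), then return the SNP with the smallest non-parametric association
p-value (Kruskal–Wallis across codominant dosage groups). Selecting for
maximal significance is selection-biased by construction; the procedure is
implemented because it is the one being studied, not because it is
recommended. Whether the original analysis pruned before or after testing
is not fully determined by its description; we prune first, following the
printed order of steps.

## Association tests and multiple-testing tiers

The source analysis names only "a non-parametric approach"; we map this to
the standard assumption-light choices and record the test used in every
result row so alternatives can be swapped in: Pearson chi-square without
continuity correction for categorical phenotypes (the uncorrected statistic
reproduces the published root-split value of 21.1), switching to the
two-sided Fisher exact test for 2×2 tables with any expected count below 5;
the Wilcoxon rank-sum test for continuous phenotypes against two genotype
groups — exact by full enumeration of group assignments (valid under ties)
when both groups have ≤ 10 observations, else the tie-corrected normal
approximation without continuity correction — and Kruskal–Wallis for three
groups. A phenotype that is single-class in a given cohort (a constant
Algo, for instance) makes the test undefined; the scan emits an explicit
`degenerate` marker row rather than a fabricated p-value.

Significance is reported as −log10(p) with two strict tiers:
p < 0.017 (correcting for 3 genes) and p < 0.003 (3 genes × 5 phenotypes).
Both thresholds are configurable arguments of `association_scan()`.

## Concordance

`compare_phenotype_pairs()` performs the three published comparisons with
the original rating as gold standard: Alda categories vs Algo; TS vs GRp;
and, within the low-B subsample, A/Low B vs GRp. The continuous pairs are
dichotomized at their published cutoffs (7 on the A/TS scale, 0.62 on GRp)
because predictive values require binary classes; by construction the TS
comparison then shares its gold labels with the categorical comparison, and
the suite asserts this on every run. Predictive values with empty
denominators are reported as `NA`, never coerced to 0 or 1, and
accuracy + discordance = 1 holds exactly.

## Power

`t_test_power()` computes the exact power of the pooled two-sample t test
from the noncentral t distribution with noncentrality
d·√(n₁n₂/(n₁+n₂)) and n₁+n₂−2 df. The exact distribution matters here: the
designs of interest sit at ~0.81 power against a 0.80 benchmark, inside
normal-approximation error. The default pipeline contrasts are the
genotype-defined group sizes of the reference sample (110 vs 46 and 102 vs
53 at d = 0.5). A two-group contrast for the third gene is not uniquely
determined by its three-genotype distribution, so it is exposed as a user
choice; the default pools heterozygotes with minor homozygotes (122 vs 34
at d = 0.6).

## The synthetic cohort generator

No case-level data accompany the reference study — only aggregate tables —
so every downstream stage is exercised on synthetic cohorts whose
**marginals** match the published aggregates: n = 164, 60% female,
age ~ N(44.70, 12.29), latent A ~ N(6.33, 2.99) rounded half-away-from-zero
and clipped to 0–10 (the scale is an integer continuum; base R's
round-half-even would bias the discretization), B-item prevalences from the
published 0/1/2 counts, and Hardy–Weinberg genotypes at the published
allele frequencies (minor-allele frequency 0.5 for the first gene, 125/310
for the second, 47/312 for the third — the second gene's printed genotype
counts sum to 155 against a stated N of 156; we keep the printed counts).
Planted effects shift the latent A score additively per minor allele before
discretization, using the true genotype even when the emitted call is
masked missing, since missingness is a genotyping artifact, not a
biological one. All draws come from named sub-streams of one global seed,
so any component is stable when unrelated parameters change.

Two aspects of real Alda data are deliberately **not** emulated. First, B
items are drawn independently of the A score, whereas in real cohorts
confounder items correlate with apparent response; consequently the de-novo
best-estimate tree fitted to a stock synthetic cohort is usually a single
node with a constant GRp. Tests that need a non-degenerate Algo therefore
plant a B-linked response signal explicitly. Second, only one SNP per gene
is simulated and no LD structure between SNPs within a gene, matching the
post-selection state of the reference analysis rather than raw chip data.
Passing tests on these cohorts validate the pipeline's statistics and
bookkeeping, not the clinical realism of any joint distribution.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs in a few minutes on one
CPU while keeping Monte-Carlo bounds meaningful: 500 random instances for
the exhaustive split-search oracle; 100 null cohorts (n = 164) for the
scan's type-I error; 100 cohorts of n = 500 for recovery of a planted
two-level tree topology (three-level genotype root, second-gene split
inside the heterozygote branch only, with the good-response rates of the
published nodes: 9%/47% in the homozygote branches, 20% vs 43% inside the
heterozygote stratum); 10⁶ simulated t statistics for the Monte-Carlo power
oracle; 1000 random genotype triples for the exact-HWE cross-check. The
exact HWE and exact rank-sum tests agree with their chi-square/normal
counterparts closely in the decision-relevant tail; in the center of a
discrete conditional distribution a probability-ordered exact p can sit far
above the asymptotic p (it is 1 at the mode), which is expected behaviour,
not error — the suite asserts tail agreement only.

## Limitations

The best-estimate model here is a de-novo refit, not the consortium-trained
rule set, so its leaves and GRp values are sample-specific by design. CHAID
split p-values are selection-biased (as are all tree methods' split
statistics) and the per-gene best-SNP selection optimizes observed
significance; neither should be read as an unbiased effect estimate. The
generator's independence assumptions mean concordance levels measured on
stock synthetic cohorts are not calibrated to the published ones — the
suite checks orderings and invariants instead of matching those aggregate
percentages.
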