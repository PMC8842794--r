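---
title: "pertnet: models, defaults, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pertnet: models, defaults, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pertnet` chains a drug-perturbation expression screen to pathway,
network, cohort, and survival evidence. This vignette is the package's
account of the statistics it implements, the defaults it ships, and the
places where a genuinely open design choice had to be made. Everything
empirical stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Differential expression

**Intensity designs** (log2-scale arrays, small n). Per gene we use the
classical pooled-variance two-sample Student *t*, two-sided. The linear
fold change is `2^(mean_treated − mean_control)` of the log2 values, so
a +1 difference in log2 means is exactly FC = 2. The DEG filter is
*p* ≤ 0.05 **and** (FC ≥ 1.5 or FC ≤ 1/1.5), both inclusive. Two
deliberate choices here:

* The 1.5 cutoff is applied on the **linear** scale and symmetrically in
  both directions, because screens of this kind report both up- and
  down-regulated genes; the threshold is a `fc_min` argument, not a
  constant.
* **Zero-variance genes** never produce infinite statistics: equal group
  means give *t* = 0, *p* = 1; unequal means with zero variance are
  flagged `degenerate`, excluded from calling, and counted in a message.
  With 3 samples per group this case is real, not hypothetical.

**Probe collapse.** When rows are array probes, each gene keeps its
single most significant probe (smallest raw *p*). Ties are broken by
larger |log2FC|, then by lexicographically smallest probe id, so the
output is a deterministic function of the input. Unmapped probes are
dropped with a logged count rather than guessed.

**Count cohorts** (large tumor/normal designs). Counts are normalized to
counts-per-million, transformed as `log2(cpm + 0.5)`, and compared with a
Welch (unequal-variance) *t*-test; calls use Benjamini–Hochberg FDR
≤ 0.05. This is a deliberately transparent procedure — a documented
logCPM + Welch + BH chain rather than a negative-binomial GLM. With
hundreds of samples per arm the Welch test on logCPM is well calibrated
(the suite verifies a ~0 false-call rate on null cohorts), and every step
is inspectable. Moderated-variance empirical-Bayes testing and exact
count GLMs are out of scope by design.

`bh_fdr()` fronts `stats::p.adjust(method = "BH")`; the test suite pins
it against a brute-force implementation of the step-up definition on
1,000 random vectors, so the surface is guaranteed to mean what it says.

## Over-representation and preranked GSEA

**Hypergeometric ORA.** For a universe of `N` measured genes, a set with
`K` members in the universe, and `n` DEGs, the p-value is the upper tail
P(X ≥ k) of Hypergeometric(N, K, n) (`stats::phyper`; the suite checks it
against exhaustive enumeration of all draws for every parameter
combination with N ≤ 12). The universe defaults to **all genes measured
on the platform**, not all annotated genes — using the annotation
universe anti-conservatively inflates enrichment when the platform is a
subset. Sets with DEG overlap below `min_overlap = 5` are excluded
*before* testing (and before FDR adjustment), so the adjustment is not
diluted by untestable sets. Two significance modes exist because
practice differs by collection: `"fdr"` (BH-adjusted p < 0.05) and
`"raw"` (p < 0.05), both strict.

**Preranked GSEA.** Genes are ordered by log2 fold change, largest
first. For a set S in a ranking of N genes, the running sum adds
`|r_i|^w / Σ_{S} |r|^w` at each hit and subtracts `1/(N − |S|)` at each
miss; the enrichment score (ES) is the signed maximum deviation, with
`w = 1` by default (the classic weighted statistic; `w = 0` gives the
unweighted Kolmogorov–Smirnov form). The null is `n_perm = 1000` random
same-size gene sets under a fixed seed. NES divides ES by the mean |ES|
of **matching-sign** null scores, and the p-value is the add-one tail
proportion among matching-sign nulls — the standard preranked
convention, stated explicitly here because several variants circulate.
Degenerate sets are skipped with a message rather than scored: fewer
than 2 ranked members, or a set covering the entire ranking (the miss
increment 1/(N − |S|) is undefined at |S| = N). A worked consequence of
the definition, pinned in the tests: a 2-gene set occupying the top two
positions of a 5-gene ranking climbs 3/5 then 2/5 with no intervening
miss, so its ES is exactly 1.

## Network module significance

The module test asks whether a pathway-DEG group is wired into the DEG
neighbourhood more densely than topology alone explains. Two statistics:

* **cross-PPI count** — edges with one endpoint in the pathway group and
  one in the other-DEG group (the groups must be disjoint; "other DEGs"
  means all DEGs minus the pathway group);
* **LCC** — the order of the largest connected component of the subgraph
  induced by the pathway group.

Both are recomputed on `n_random = 1000` randomized networks with the
**node groups held fixed** — the network, not the gene labels, is the
random object. The default null is degree-preserving Maslov–Sneppen
double-edge swaps (10 × |E| attempted swaps; swaps creating loops or
multi-edges rejected), the standard null for module-connectivity claims
because it controls for hubness; `label_shuffle` (uniform relabelling)
is available for comparison and is the sharper contrast when group
degrees themselves carry the signal. The empirical p uses the add-one
rule (1 + #{null ≥ obs})/(1 + n): it can never be 0, its floor at 1,000
randomizations is 1/1001, so "p < 10⁻³" is exactly the strongest
attainable statement and is what the acceptance run reproduces on a
planted module. The result object retains both full null distributions
for density plots, plus the scheme and seed.

A behaviour worth knowing: under the degree-preserving null, a *small*
group of high-degree nodes induces a fairly dense null subgraph, so LCC
significance weakens on small graphs even when the module is real. The
acceptance-scale check therefore runs on a 2,000-node background, where
the planted 40-node, density-0.5 module is decisively separated; the
unit tests exercise the small-graph regime under label shuffling.

## Survival screening

`cox_univariate()` fits the proportional-hazards partial likelihood via
`survival::coxph` with **Efron** tie handling (more accurate than
Breslow when event times tie; the suite verifies the fitted coefficient
against a grid search of the partial likelihood, |Δ| < 10⁻³, on 50 small
cohorts). The covariate enters as **continuous standardized expression**
(hazard ratios per SD) for screening; the median split is reserved for
Kaplan–Meier display — mirroring the common dual use. Whether cohort
expression should enter raw, log-scaled, or dichotomized is genuinely
underdetermined; standardized-continuous is the default and
`standardize = FALSE` exposes the alternative. Survival-related
classification uses a **strict** p < 0.05, in contrast to the inclusive
DEG thresholds — the two conventions are kept exactly as stated, not
harmonized. Monotone-likelihood fits (no finite MLE) are returned with
`converged = FALSE` rather than hidden. `km_median_split()` puts samples
strictly above the median in the high group, requires ≥ 2 samples per
group, and reports the log-rank test as the Kaplan–Meier companion
p-value.

## Integration

`intersect_concordant()` reports both bookkeeping modes because
cross-cohort narratives mix them: `common_down`/`common_up` always count
same-direction genes, while the `concordant` set is mode-dependent —
`"same"` (default; reproduces the usual common-DEG accounting) or
`"reversal"` (drug pushes tumor-up genes down). `|concordant| +
|discordant| = |common|` always holds, and discordant genes are reported
explicitly rather than silently dropped. The survival × drug-altered
2×2 uses the one-sided Fisher exact test (equivalently, the matching
hypergeometric upper tail — the suite asserts the cross-module identity)
with the sample odds ratio. Candidate nomination is a pure four-rule
filter — Cox p < 0.05, HR > 1, tumor-up, drug-down — with no invented
scoring; a regulator missing from any evidence table is "not evaluable"
and excluded with a message.

## Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of its parameters and one integer
seed (internal RNG scoping restores the caller's random state), and
returns a `SimulationTruth` alongside the data.

* `simulate_perturbation()` — log2 intensities: per-gene Uniform(6, 12)
  baseline + group shift + Gaussian noise (sd `sigma = 0.5`). Defaults
  emulate a small inhibitory drug screen: 3 vs. 3 samples, 6.5% DE
  fraction, |log2FC| = 2, and a 76/24 down/up sign split (a parameter,
  not a constant). The planted |log2FC| is deliberately constant at
  `lfc_location` so sensitivity has a crisp definition.
* `simulate_cohort()` — negative-binomial counts, log-normal baseline
  means (median 200), common dispersion 0.4, `2^lfc` tumor multiplier.
  Defaults 526 tumor / 59 normal emulate a large public tumor cohort
  with a small adjacent-normal arm; the DE fraction defaults high (0.6)
  as tumor/normal comparisons typically are.
* `simulate_survival()` — exponential event times with rate
  `base_hazard · exp(Σ β·z)` and administrative censoring: the simplest
  model in which proportional hazards is exactly true, which is the
  point — Cox recovery failures then indicate implementation error, not
  model misspecification. Weibull shapes are intentionally not offered.
* `simulate_network()` — Barabási–Albert preferential attachment
  (heavy-tailed degrees, as real PPI networks have) plus a planted
  module wired internally to a target density. Note the planted *extra*
  edges make module nodes hubs too, which is exactly what the
  degree-preserving null controls for.
* `simulate_gene_sets()` — uniform background sets plus enriched sets
  drawing a stated fraction of members from the planted DE genes.

Not emulated, by design: probe-level array artifacts, batch structure,
library-size or GC biases, clinical covariates beyond time/event, and
edge directionality (interactions are collapsed to undirected because
both network statistics are orientation-free). Passing tests on these
generators show the *statistics are implemented and calibrated
correctly*; they do not show robustness to the real-data pathologies the
generators omit.

## Problem sizes and runtime posture

The suite and the acceptance script size their simulations to what the
checks need, as the package's own choice: DEG calibration at 400–2,000
genes over 50 seeds; Cox recovery at n = 500 over 50–100 seeds; the
network check at a 2,000-node background with 1,000 randomizations
(≈ half a minute); oracle equivalences at N ≤ 12 (hypergeometric) and
n ≤ 8 (Cox grid search). Full determinism is asserted by hashing every
pipeline output from two runs at one seed.

## Known limitations

* The count-DE stage is a two-group Welch test: no covariates, no paired
  designs, no shrinkage — adequate for large arms, underpowered at very
  small n.
* GSEA permutes gene labels (preranked mode); phenotype permutation is
  not implemented and small sample designs cannot support it anyway.
* The network test treats the input graph as complete truth; interaction
  databases are noisy and ascertainment-biased, and no edge confidence
  weighting is applied.
* Identifier matching is exact and case-sensitive everywhere, on
  purpose: silent case-folding hides mapping bugs, but it does mean
  upstream symbol harmonization is the user's job.
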