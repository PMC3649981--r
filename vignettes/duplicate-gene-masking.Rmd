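---
title: "Duplicate-gene masking and essentiality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplicate-gene masking and essentiality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupmask)
```

`dupmask` implements a pipeline for measuring phenotype masking between
duplicate gene pairs and for relating essentiality to the evolutionary
dynamics of duplication. This vignette documents the models, the parameter
choices that matter, the numerical conventions, and what the synthetic
benchmark does and does not demonstrate.

## The masking model

Let $w$ denote fitness measured on a scale where 1 means indistinguishable
from controls, and let $s_i = 1 - w_i$ be the fitness reduction of
knocking down gene $i$ alone. Under a multiplicative model of genetic
interaction the expected fitness of the double knockdown is

$$ w_{1,2} = (1 - s_1)(1 - s_2) = w_1 \, w_2 . $$

Masking is an observed double-knockdown fitness *below* this expectation:
the pair interacts synergistically, which for paralogs is interpreted as
overlap in function — one gene had been compensating for loss of the
other. The call is *full* masking when neither single knockdown shows any
penetrant phenotype, *partial* otherwise.

Fitness is estimated per quantitative measure (brood size, embryonic
viability, post-embryonic viability, fraction of morphologically normal
animals) as the replicate value divided by the mean of the control wells
(`normalize_fitness()`). All measures are oriented so that larger means
healthier — morphology enters as the fraction of *normal* animals — and
normalised values may exceed 1.

### The rank test and its expected sample

The paper-level rule is a one-sided Mann-Whitney U test of whether the
double-knockdown replicates $w_{1,2}^{(i)}$ are stochastically smaller than
the multiplicative expectation, at $p < 0.05$ per measure, with any
significant measure triggering a masking call (no multiplicity
correction — a deliberately sensitive screen-style rule).

How the *expected sample* is formed from single-knockdown replicates is a
genuine design choice, and we examined two constructions:

* **paired** (default): $\{w_1^{(i)} w_2^{(i)}\}_{i=1..n}$ — $n$ mutually
  independent products;
* **cross-products**: $\{w_1^{(i)} w_2^{(j)}\}_{i,j}$ — $n^2$ products that
  share factors and are therefore strongly dependent.

The rank test assumes independent observations within each sample. With
the cross-product construction that assumption fails badly: simulated
under an exactly multiplicative null (5 replicates, 10% coefficient of
variation) its type-I error is ~9% at nominal $\alpha = 0.05$. The paired
construction measures ~4.5%, which is what the discrete exact test can
attain: with 5 vs 5 observations the achievable p-values are multiples of
$1/\binom{10}{5}$, the largest rejection region below 0.05 has size
$12/252 = 0.0476$, and the product sample's slightly higher spread
($\mathrm{CV}\approx\sqrt2\cdot10\%$) nudges the test conservative from
there. The package therefore defaults to the paired construction and
keeps `null = "cross-products"` available for comparison. The residual
deviation from nominal size is in the conservative direction.

Exact p-values are used when the combined sample has at most 20
observations and no ties; otherwise the normal approximation with tie
correction. A sample in which every value is tied (possible with
noise-free synthetic data) is reported as $p = 1$.

### Candidate gating

Quantitative masking tests are run only for pairs whose double knockdown
shows at least one penetrant qualitative call
(`require_double_phenotype = TRUE` in `pair_masking_result()`). This
mirrors the two-stage screen design — an apparent double-knockdown defect
first, quantitative retesting second — and is what keeps per-measure,
uncorrected testing from accumulating false masking calls across the large
majority of pairs whose double knockdown is indistinguishable from
controls (four measures at $\alpha = 0.05$ would otherwise mislabel
roughly one pair in six). With the gate, false masking calls are confined
to pairs that already show a real defect, where they can at worst turn
"partial" on, never manufacture an essential pair out of a clean one.

### Qualitative escalation

For phenotypes scored qualitatively, masking is inferred when the double
knockdown's call strictly exceeds the stronger single-knockdown call in a
lexicographic order: first by severity class (the package ships a default
severity ranking of the screen vocabulary in `phenotype_vocabulary()`,
placing lethality above sterility above morphological/behavioural
classes), then, within the same class, by developmental stage — larval
lethality at L1 is more severe than at L3. The severity table is a package
default, not a biological constant; it is an argument wherever it is used.

## Screen scoring rules

* Sterile (`Ste`): fewer than 10 F1 progeny. Low brood (`Lbd`): at least
  10 but fewer than 30 — the nested thresholds make the two calls
  mutually exclusive, with `Ste` taking precedence.
* Embryonic lethal (`Emb`): at least 10% of the brood failed to hatch,
  evaluated only when at least 10 progeny were scored (`min_brood_for_emb`,
  configurable) so that tiny broods cannot generate spurious calls.
* Penetrance: a phenotype is called when **any** replicate reaches 10%
  penetrance in the F1 population, or 50% among P0 mothers. Penetrance
  denominators are carried by the reader as precomputed fractions; the
  package does not re-derive them from raw animal counts.
* A pair is *essential* when its double knockdown has an obvious defect:
  either member carried a phenotype in prior single-gene screens, or the
  pair shows masking. "Essential" here is operational — an observable
  knockdown defect under screen conditions — not evolutionary
  indispensability.

## Protein divergence (Ka)

`ka_pair()` implements Li's 1993 protocol. Each codon position is
classified as nondegenerate (no synonymous single-base change), twofold
(one or two synonymous changes — this folds in the isoleucine third
position) or fourfold (all changes synonymous). Differences are counted
position-wise as transitions or transversions; when the two sequences
assign a site to different classes, the site and its difference contribute
half weight to each class. Per class, the Kimura two-parameter components

$$ A = -\tfrac12\ln(1 - 2P - Q) + \tfrac14\ln(1 - 2Q), \qquad
   B = -\tfrac12\ln(1 - 2Q) $$

correct for multiple hits, and the nonsynonymous distance is the unbiased
combination

$$ K_a = A_0 + \frac{L_0 B_0 + L_2 B_2}{L_0 + L_2}, $$

with the synonymous companion $K_s = B_4 + (L_2 A_2 + L_4 A_4)/(L_2+L_4)$
reported alongside.

Numerical conventions, stated because implementations genuinely diverge
here:

* gapped, ambiguous or stop-containing codons are dropped pairwise (the
  conservative standard; the protocol itself does not fix gap handling);
* multi-difference codons are counted position-wise, with no pathway
  averaging — this is the site-based protocol, not the pathway-counting
  family of estimators;
* the arginine/leucine first-position irregularities are carried by the
  degeneracy rule itself (they classify as twofold); the known convention
  that their transition/transversion synonymy is then approximated can
  shift Ka in the third decimal;
* a non-positive logarithm argument marks the estimate *saturated* (`NA`)
  rather than erroring;
* the evolutionary rate of a duplicate pair across species
  (`ka_cecb()`) is the arithmetic mean of its two ortholog Ka values.

Pairs with $K_a \ge 1$ are conventionally excluded from divergence-trend
analyses; the exclusion is applied by the caller (it is a filter on the
analysis, not on the estimator).

## Duplication-age dating

A pair's duplication node is its lowest common ancestor in a rooted gene
tree; its age class is the taxonomy label of the LCA, in a species
taxonomy, of all species below that node — `Celegans` (focal lineage,
after the last speciation), `Caenorhabditis`, `Bilateria` or `Eukaryota`,
a totally ordered scale. Unrooted input trees are midpoint-rooted with a
warning.

Confidence rules:

* **multi-release agreement**: at least two of the three most recent tree
  releases give the same class;
* **strong support**: in the most recent release, the LCA has bootstrap
  ≥ 70% and every internal node on both leaf-to-LCA paths has bootstrap
  ≥ 70% *or* is a speciation node at which no genes have been lost;
* **family split**: genes in different families are dated `Eukaryota`
  when both families contain the deep taxa (human, Drosophila, and a
  yeast or Arabidopsis outgroup);
* otherwise `Unknown`.

Because curated duplication/speciation annotations are not an input,
speciation nodes are reconstructed by the species-overlap criterion
(children with disjoint species sets), and "no genes lost" is
operationalised as the node's species set equalling the full taxonomy
leaf set under its taxon. Both are documented proxies: species overlap
never misses a duplication but can call a duplication where parallel
losses occurred, and the completeness proxy is stricter than curated
annotation would be. Ortholog inference keeps cross-species leaf pairs
whose LCA is a supported speciation node, restricted to one-to-one cases.

## Aggregate statistics

* `rate()` keeps exact ratios; percent presentation rounds half-up to one
  decimal, and the rounded value never feeds back into computation.
* `contingency_test()` defaults to the Yates-corrected chi-squared for
  2×2 tables, with the uncorrected variant and Fisher's exact test
  selectable; which chi-squared variant a given report used is often
  unstated, so both are available and the method is recorded. Fisher's
  p-values equal exact hypergeometric enumeration (verified against a
  brute-force oracle in the tests).
* `binned_rate_curve()` sorts by the predictor (stable order, so boundary
  ties are deterministic), makes contiguous bins whose sizes differ by at
  most one, assigns the remainder to the lowest-predictor bins, and
  summarises each bin at its median predictor value. Trend inference is
  never done on the bins: `logistic_trend()` fits unbinned data and
  reports the Wald slope p-value, flagging separation instead of
  reporting a meaningless p.
* `expression_controlled_rate_model()` fits
  $\ln(d_N + 1) \sim \log_2(\text{expression}) + \text{class}$, after a
  pretest of the expression-by-class interaction: the class comparison is
  only valid as an analysis of covariance when the interaction is not
  significant. The $\ln(d_N+1)$ transform keeps zero rates finite; an
  exactly collinear fit returns `NA` validity rather than a fabricated
  test.

## The synthetic-data generator

`sim_params()` defaults encode the study conditions the generator
emulates:

| parameter | default | meaning |
|---|---|---|
| `p_essential` | 0.177 | genome baseline single-knockdown phenotype rate |
| `duplication_bias` (β) | 5 | non-essential : essential duplication-fixation rate ratio |
| `retention_bias` (γ) | 3 | non-essential : essential per-epoch loss rate ratio |
| `loss_rate_essential` | 0.15 | per-epoch loss probability of an essential pair |
| `epoch_events` | 500 × 4 | duplication events per age epoch |
| `replicate_count` | 5 | replicate wells per condition (screen used 3–5) |
| `noise_cv` | 0.10 | replicate coefficient of variation |
| `n_controls` | 111 | control wells for normalisation |
| `masking_decay` | 4 | decay rate of masking with divergence, $P(\text{masked}) = e^{-\lambda K_a}$ |
| `masking_strength` | 0.3 | multiplier below the multiplicative expectation for masked doubles |

Expression is log2-normal with class-specific means (11.66 for essential,
8.60 for non-essential genes — an 8-fold difference), and divergence
scales with age and inversely with expression, reflecting the standard
negative expression–rate relationship. The age-epoch divergence scales
(0.05 / 0.15 / 0.45 / 0.80) were chosen once so that most young pairs sit
well below $K_a = 1$ and the oldest classes brush saturation, which is the
regime the estimator must handle.

Because a duplication event picks an essential parent with probability
$p/(p + \beta(1-p))$ and survival over $e$ elapsed epochs is
$(1-l)^e$ versus $(1-\min(\gamma l, 0.99))^e$, the essential fraction
among survivors of each age class has a closed form
(`essential_fraction_expectation()`): 4.1% for the youngest class rising
to 13.7% for the oldest under the defaults. These analytic values — not
any empirical dataset — are what the end-to-end tests compare the
pipeline's output against.

Structural choices worth knowing when interpreting benchmark results:

* masked pairs are generated as *fully* masked (clean singles, double at
  $m \cdot w_1 w_2$), and unmasked essential pairs carry their defect on
  exactly one single, so the double equals the multiplicative expectation
  exactly; real screens also contain partially masked pairs and pairs
  with two independently defective singles, whose qualitative calls can
  escalate under pure multiplicativity — adjudicating those requires the
  quantitative stage and is where the uncorrected per-measure testing
  shows its false-positive rate;
* each pair's defect is expressed in one randomly chosen quantitative
  measure, with the remaining measures at control level;
* the e-value map in the emitted hit table
  ($\log_{10} E = -150(1-d) + \text{jitter}$, clamped to $[-180, -12]$) is
  arbitrary but fixed and monotone — only the ordering matters to
  reciprocal-best-hit and isolation logic;
* emitted gene trees are minimal (3–5 leaves) and topologically identical
  across releases; they exercise the dating rules, not tree inference;
* sequence content is random sense codons; the generator makes no attempt
  at realistic codon usage or genome structure.

Consequently, passing the end-to-end tests shows that the pipeline's
inference chain — screening, masking statistics, dating, aggregation —
recovers the generative model's biases at realistic noise levels; it does
not validate the biological assumptions of that model against real screen
data.

## Numerical and edge-case conventions

* E-values of exactly 0 (underflow) are clamped to $10^{-180}$ before
  logs; isolation values are clamped to $[0, 1]$ (a third hit more
  significant than the pair hit clamps at 1).
* "Best hit" ties break by larger bitscore, then lexicographic subject
  id; the pair e-value is the smaller of the two directed e-values;
  multiple HSPs per direction reduce to the best single HSP, whose span
  defines coverage against the longest-isoform protein length.
* The shared-hit e-value between a gene and a third gene is the minimum
  over the two directions when both are present.
* Missing bootstraps on nodes that are not complete speciation nodes fail
  the support rule rather than passing silently.
* All generator outputs are deterministic given `seed`; emitting functions
  derive their streams from `seed` plus a fixed offset per artefact.

## Problem sizes in the shipped tests

The test suite exercises: null calibration of the masking test at 10,000
simulated trials; Ka recovery over 200 alignments of 500 codons (target
0.1, tolerance ±0.01 on the mean); oracle equivalence of the
reciprocal-best-hit search, Fisher test, LCA search and degeneracy table
against brute-force enumerations; and an end-to-end run of 2,000
duplication events through screening, masking calls, tree dating and rate
aggregation, compared to the closed-form expectations within three
binomial standard errors plus a 1% allowance for detection loss. These
sizes were chosen to make the Monte-Carlo comparisons meaningful at the
stated tolerances.

## Known limitations

* The expected-sample construction for the rank test is a reconstruction;
  the original analysis may have compared against a scalar expectation.
  The paired default is the calibrated choice among the faithful
  candidates (see above).
* Li-1993 implementation conventions (half-site weighting, irregular
  codon handling) differ in the third decimal across published tools;
  this package's conventions are stated above and frozen by tests.
* TreeFam-style curated speciation/duplication and gene-loss annotations
  are approximated by species overlap and species-set completeness.
* The human-ortholog presence/absence analysis and GO enrichment are out
  of scope; the generic logistic-regression and ANCOVA contracts they
  rely on are provided in the aggregate-statistics module.
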