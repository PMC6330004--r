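---
title: "Detecting SNP-SNP interactions with tree learners: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SNP-SNP interactions with tree learners: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistree)
```

## The problem

Genome-wide association studies are built around additive, single-marker
effects, but part of the genetic architecture of complex traits may be
epistatic: the joint effect of two or more loci deviates from the sum of
their marginal effects. `epistree` is a simulation workbench for asking a
specific methodological question: *can rule-based tree learners detect
epistatic SNP pairs and triples in a quantitative trait, and do they keep
doing so when a strong polygenic background is present?* Two learners are
compared:

* a **C4.5/C5.0-style rule learner**: an entropy-driven decision tree on
  binary (dominant/recessive) SNP predictors, collapsed into conjunctive
  rules, simplified by pessimistic pruning, predicting by weighted voting;
* **logic regression**: a linear model whose regressor is a Boolean tree
  (AND/OR/NOT over the same binary predictors), fitted by greedy
  hill-climbing on the residual sum of squares and judged by a
  100-permutation randomisation test.

Both are evaluated replicate-by-replicate for power (all simulated
interacting SNPs recovered) and type I error (any detection on a pure-noise
phenotype).

## Genotype model

Genotypes are additive minor-allele counts \(g \in \{0,1,2\}\) drawn from
Hardy-Weinberg genotype frequencies \((1-q)^2, 2q(1-q), q^2\) at minor
allele frequency \(q\). Two panel regimes are provided:

* **linkage equilibrium** (the "pruned" condition): independent SNPs.
  After LD pruning at \(r^2 > 0.1\) real panels are close to this state,
  and in LE the power of both learners is governed by \(n\), the MAFs and
  the effect sizes — not by which particular markers surround the causal
  ones. This is what makes desk-scale reproduction of the pruned-condition
  results meaningful.
* **block LD** (the "unpruned" condition): a latent Gaussian copula with
  AR(1) correlation \(\rho\) (default 0.9) inside consecutive blocks
  (default 10 SNPs), thresholded at the HWE quantiles so marginals are
  untouched. This emulates the *qualitative* features of unpruned data —
  tight local correlation, independence across blocks — but not the
  long-range, irregular LD of a real chromosome, so unpruned-condition
  numbers are treated as qualitative checks only.

Map positions sit on a uniform grid (1 SNP / 2 kb) purely so that the
window arithmetic of PLINK-style pruning (50 kb window, 5 kb step,
\(r^2 > 0.1\), squared Pearson correlation of genotype codes) is
exercised; no real genetic map is implied. When a pruning pair must lose a
member we drop the lower-MAF SNP (tie: the later position) — any fixed
rule satisfies the pruning contract; this one is deterministic and keeps
the more informative marker.

Causal SNPs are always drawn from the high-MAF pool (observed MAF in
[0.4, 0.5]), which equalises statistical power across simulations. By
default the causal draw is repeated per replicate, which averages the
power estimate over the arbitrary choice of causal markers;
`fix_causals = TRUE` restores a single draw per condition.

## Phenotype models

All phenotypes are linear in the *unstandardised* additive codes with a
single noise draw \(\varepsilon \sim N(0, 1)\):

* **polygenic**: \(y = \sum_{j=1}^{200} \beta_j g_j + \varepsilon\), each
  SNP explaining the same variance share \(R^2_j = 1.5\times10^{-3}\)
  (total 0.3). The betas are MAF-dependent,
  \(\beta_j = \sqrt{R^2_j\,\sigma_y^2 / (2q_j(1-q_j))}\) with
  \(\sigma_y^2 = 1/(1 - 0.3)\), so the target share is met exactly under
  HWE.
* **2-SNP interaction**: \(y = \beta_1 g_1 + \beta_2 g_2 + \beta_3 g_1 g_2
  + \varepsilon\) with (\(\beta_{1,2}\), \(\beta_3\)) = (0.2, 0.24)
  *strong*, (0.125, 0.15) *intermediate*, (0.07, 0.09) *weak*.
* **3-SNP interaction**: three mains, all three pairwise products and the
  triple product; (mains, pairs, triple) = (0.05, 0.1, 0.2) *strong*, half
  that for *weak*, and (0, 0, 0.4) for the *pure* interaction.
* **combined**: polygenic + interaction signal over disjoint causal sets,
  with one shared \(\varepsilon\) (two draws would deflate the stated
  variance shares).
* **null** (\(y = \varepsilon\)) and a **main-effect control** (two mains
  at 0.2, no product term) used to verify that interaction detections are
  not driven by strong marginal effects.

Interaction regressors are products of the additive codes, on the same
symbols as the mains; dichotomisation is input preparation for the
learners, not part of the generating model. One deliberate consequence:
the analytic full-model \(R^2\) of these conventions (about 16% for the
strong 2-SNP model) is what the package reports; published per-model
\(R^2\) tables for this design are not reconcilable with \(\beta = 0.2\),
MAF 0.4-0.5 and unit noise under any single convention we tried, so those
table values are treated as descriptive.

**Fidelity audit.** Before any power claim, `assess_fidelity()` refits the
true generating model by OLS across replicates: the bias of the
coefficient-sum estimate should be ~0 and the 95% CI for the sum should
cover the truth ~95% of the time (the strong 2-SNP preset audits at ~95%,
`analysis/01_fidelity_audit.R`). Note the coverage of a t-interval is
scale-free, so it stays at its nominal level even as noise vanishes —
the audit's "exact recovery" limit shows up in the bias, not the coverage.

## The rule learner

Growth chooses, at each node, the binary predictor maximising the **gain
ratio** — information gain divided by the split's own entropy — among
predictors whose gain is positive and at least the node-average positive
gain (the classic C4.5 eligibility rule; ties go to the lowest column
index). `min_cases = 2` and rule-pruning confidence `cf = 0.25` are the
C4.5 defaults. Each root-to-leaf path becomes a conjunctive rule;
conditions are deleted greedily while the rule's **pessimistic error** (the
Clopper-Pearson-style upper binomial bound at confidence `cf` on its
training error) does not increase; rules that do not beat the default
class's pessimistic error, and duplicates, are dropped. Matching rules
vote with weight `cover - errors + 1`; ties and unmatched rows go to the
default class.

**The significance guard.** A learner screening thousands of binary
markers will always find a chance split that looks informative on training
data: with \(n = 5000\) and ~1000 predictors, the best-of-panel chance
split genuinely reduces training error, and a cf = 0.25 pessimistic bound
on a rule covering ~2500 cases cannot push its error estimate back above
the default's. Growth therefore includes a per-node multiplicity
correction: candidate splits must be significant after Bonferroni
adjustment for the number of predictors examined at the node (vectorised
chi-square screen; the chosen split is then confirmed with Fisher's exact
test), at family-wise level `sig_level = 0.01`. This is what gives the
learner its conservative profile — type I error ~1% on a 500-SNP panel,
no false-positive SNPs in interaction rulesets — while leaving strong and
intermediate interaction power untouched (the true splits carry p-values
tens of orders of magnitude below the threshold). `sig_level = 1` disables
the guard and restores literal C4.5 growth; the unit tests of growth
mechanics (e.g. the XOR recovery oracle) run in that mode.

One known consequence of the guard's calibration: on the polygenic-only
phenotype the learner flags the best of the 200 real (if individually
tiny) polygenic effects in a substantial fraction of replicates at desk
scale. How often a commercial C5.0 build does the same depends on
undocumented internals; only the null-phenotype type I error is part of
the acceptance surface.

Because C5.0 is a classifier, the quantitative phenotype is discretised —
by default a median split into low/high (ties to low), exposed as a config
knob (`discretize_outcome()`, with an equal-frequency k-quantile
alternative). Strong-signal results are insensitive to this choice; it
mainly scales the weak-signal power.

"A tree was constructed" (the detection/type-I accounting unit) means the
pruned ruleset contains at least one rule with at least one condition, so
a single main-effect rule counts as a detection but not as power (power
requires *all* interacting SNPs among the rules' predictors).

## Logic regression

The model is \(y = \beta_0 + \beta_1 L_1(+\dots)\) with \(L\) a Boolean
tree over the dominant/recessive predictors; the score is the OLS residual
sum of squares. Defaults: one tree, at most 8 leaves (a cap, not a forced
size — though at these sample sizes fitted models essentially always fill
it), best-improvement greedy search from a uniformly random starting
leaf, at most 25 accepted moves. The move set is the standard
logic-regression neighbourhood: alternate a leaf's predictor, toggle its
negation, alternate an operator, grow a leaf into `op(leaf, new leaf)`,
prune an operator node to either child. A move is accepted only if it
lowers the RSS by more than a relative tolerance of 1e-9 (guards against
floating-point ping-pong); the accepted-move trajectory is therefore
strictly decreasing. For single-tree models every candidate in the
neighbourhood is scored exactly through a closed-form update (one matrix
cross-product per round); the literal enumerate-and-refit engine is
retained and tested to take identical search paths. Degenerate designs
(constant or collinear tree columns) get the minimum-norm OLS solution
rather than an error.

**Randomisation test.** The fitted score is compared with 100 refits on
permuted phenotypes (fresh random start each, permuting `y` only, design
fixed). The model passes when its score is strictly below at least 95% of
the permuted scores; a permuted score exactly equal counts against the
model. The exact level of this rule is 6/101 ≈ 5.9%, which is the type I
error a valid implementation shows empirically.
Because each permutation carries its own derived seed, permuting can stop
as soon as the fail verdict is decided (expected ~12 permutations under
the null) without changing any verdict; power-condition replicates still
evaluate all 100.

## Evaluation harness

`run_condition()` builds the panel once, then per replicate draws causal
SNPs, simulates the phenotype, runs the learner and persists a
`replicate_outcome`; power and type I error are exact functions of those
outcomes (`summarize_outcomes()` recomputes them without re-running
anything). Selected non-causal SNPs are classified by `fp_accounting()`
as *in LD* (max \(r^2 > 0.25\) against a causal SNP — the threshold
chosen for consistency with the pruning threshold) or *spurious*.

**Problem sizes.** The full study design is 500 replicates per condition
on a 1705-SNP pruned panel. The package's default profiles are desk-scale
choices: \(n = 5000\) (the study's sample size), \(m = 500\) LE SNPs for
the rule learner, \(m = 300\) for logic regression (whose cost per
replicate is ~101 fits), 100-120 replicates for type I error and 25-50 for
power conditions — in LE, power depends on \(n\), MAF and betas, not on
\(m\), while runtime scales with \(m \times\) replicates. Conditions that
include the 200-SNP polygenic background use \(m = 1705\) (the study's
pruned panel size): a 500-SNP panel with uniform MAFs has only ~100 SNPs
in the 0.4-0.5 causal band, too few to supply 200 polygenic plus the
interacting SNPs.

## Numerical choices and edge cases

* Entropy uses \(0\log 0 = 0\); gain ratio returns 0 when the split
  information is 0; empty partitions contribute nothing.
* The pessimistic bound is the exact Clopper-Pearson upper limit
  `qbeta(1 - cf, errors + 1, cover - errors)` (C4.5 uses a normal
  approximation of the same bound; the exact form is monotone and
  well-defined down to zero errors, where it equals
  \(1 - cf^{1/\mathrm{cover}}\)).
* Median imputation rounds half-down (0.5 → 0, 1.5 → 1) so imputed values
  stay in the code alphabet; imputing additive codes and then
  dichotomising agrees with the reverse order whenever the additive median
  is integral *and* the implied binary medians are untied.
* \(r^2\) uses pairwise-complete individuals; monomorphic columns are an
  error naming the SNP.
* All randomness flows from one master seed through `derive_seed()`
  (an affine fold over a 31-bit modulus), so any replicate or permutation
  is reproducible in isolation and all artefacts are byte-identical across
  reruns.
* Tie-breaks are deterministic everywhere: lowest column index (splits),
  first-in-enumeration-order (logic moves), ties-to-low (median split),
  later-position-dropped (pruning).

## What passing tests do and do not show

The generator reproduces HWE marginals, a narrow high-MAF causal band,
block-wise LD and the exact effect-size grid of the study design; it does
not reproduce real LD structure, allele-frequency spectra, missingness
patterns, relatedness or population stratification. Desk-scale agreement
on the pruned-condition surface (type I errors, strong/pure power,
coverage) therefore supports the *methods* — the learners and the test —
under the stated generating models, not any claim about a particular real
cohort. Applications to real (access-controlled) cohort data are out of
scope, as are boosting/winnowing features of commercial C5.0 and annealing
search for logic regression.
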