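---
title: "Methods: Y haplogroup case-control association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y haplogroup case-control association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yhapassoc)
```

## The model

The male-specific region of the Y chromosome does not recombine, so the
binary markers on it accumulate on a perfect phylogeny: every man carries
the derived allele at exactly the markers on the path from the root of the
haplogroup tree to his haplogroup, and the ancestral allele everywhere
else. Cutting any branch of the tree therefore bipartitions a cohort into
carriers and non-carriers of the mutation on that branch, and a
case-control comparison of those two groups is an allelic association test
for that branch. Because each man is hemizygous, the "allelic" odds ratio
is identical to the carrier odds ratio and allele frequencies are
frequencies over men.

`yhapassoc` implements that analysis as a pipeline:

1. **Tree model.** `read_haplo_tree()` loads a TSV specification of nodes,
   parent links and defining markers (`NAME:ANC>DER[:rsID[:POS]]`).
   Positions are metadata only; no genome arithmetic is done. Nodes
   without a defining marker are *display classes* (for example combined
   leaf groups such as `R1b1b+R1b*`): they can receive frequency mass but
   are never cuttable branches, because no mutation defines them.

2. **QC.** `apply_qc()` excludes samples with call completion strictly
   below 80% or with two or more heterozygous calls — an impossible
   diploid-style call on the hemizygous Y, used as an error signal. Sample
   exclusions come first; markers monomorphic among the *retained* samples
   are then dropped from the association set. Their calls are kept,
   because an all-ancestral marker still proves its branch empty, which
   the imputation and redundancy steps rely on. Surviving isolated
   heterozygous calls become missing rather than being coerced to an
   allele. QC is idempotent by construction (a QC'd object is returned
   unchanged); re-deriving completion after the het-to-missing conversion
   could otherwise push a borderline sample over the threshold on a
   second pass.

3. **Branch assignment.** `branch_status()` scores typed branches from
   their markers (derived if any attached marker is derived and none
   ancestral; discordant equivalent markers give missing), blanks
   tree-inconsistent pairs (derived below an ancestral ancestor: both
   statuses set missing — the conservative choice, since the data cannot
   say which call is wrong), and fills untyped branches by the
   parent-and-siblings rule: carrier iff carrier at the parent and
   non-carrier at every sibling. The rule is iterated to a fixpoint, so a
   chain of nested untyped branches flanked by typed sisters (a superclade
   together with its internal subclade) all become imputable; a single
   pass would stop at the outermost one.

4. **Redundancy.** An imputed branch whose derived frequency differs by
   less than 0.001 (configurable) from a directly genotyped direct parent
   or child defines essentially the same bipartition and is dropped by
   `redundancy_filter()`. Directly genotyped branches are never dropped —
   nested genotyped branches with near-identical frequencies are all
   reported, which matches how published tables list, e.g., a clade and
   its dominant subclade side by side. The frequency used is the
   derived-allele frequency in pooled controls; the comparison is exact on
   complete data, and with missingness the two frequencies are estimated
   on slightly different denominators, so the filter should be fed
   adequately sized strata (or noise-free frequencies where available).

5. **Association.** For each branch and case subgroup,
   `branch_association()` fits the null logistic model (covariates only)
   by IRLS and computes the 1-df Rao score statistic for adding the binary
   carrier indicator:
   \(U = \sum_i x_i (y_i - \hat p_i)\),
   \(V = x^\top W x - x^\top W X_0 (X_0^\top W X_0)^{-1} X_0^\top W x\),
   statistic \(U^2/V\) with \(W = \mathrm{diag}(\hat p_i(1-\hat p_i))\).
   With no covariates this equals the Pearson chi-square of the 2x2 table
   (verified to 1e-8 in the tests); with covariates it matches
   `anova(glm(...), test = "Rao")`. The odds ratio and 95% Wald interval
   (z = 1.959964) come from the fitted alternative model. Covariates are
   age in 10-year bins anchored at decade boundaries with "under 50" its
   own bin, study, and the first principal component; factor categories
   without cases (or without controls) are uninformative for the carrier
   effect and are dropped together with their samples, mirroring the
   footnote convention of the emulated study. When any carrier-by-outcome
   cell is zero, or the alternative fit separates, the method falls back
   to the Fisher exact test (`fisher_exact_or()`, wrapping the standard
   hypergeometric two-sided rule — probabilities not exceeding that of the
   observed table — with conditional-MLE OR and exact CI). The published
   exact interval convention is not stated in the emulated study; this
   package states its own (conditional exact, not mid-p) and does not
   claim to reproduce printed exact bounds. A branch with no carriers or
   no non-carriers is reported untestable.
   `case_group_difference()` runs the same score test case-only
   (aggressive vs non-aggressive); whether the original analysis used a
   case-only model or an interaction term is unstated, and case-only is
   the choice made here.

6. **Meta-analysis and power.** `fixed_effect_meta()` pools log odds
   ratios with inverse-variance weights \(w_i = 1/se_i^2\);
   `se_from_ci()` reconstructs \(se = (\ln\,\mathrm{hi} -
   \ln\,\mathrm{lo})/(2 \times 1.959964)\) from printed intervals, so
   published tables can be pooled without individual-level data. Studies
   printed with OR 0 (no carrier cases) have no finite log OR by this
   route and are excluded with a warning. Cochran's Q is reported
   descriptively; no random-effects modelling is offered because the
   analysis being emulated used fixed effects only. `allelic_power()` is
   the standard two-proportion normal approximation with pooled variance
   (both rejection tails included); disease prevalence is accepted as an
   argument but does not enter, because for an uncommon disease the
   control frequency approximates the population frequency — the analytic
   values match the published power triple without any prevalence
   correction. Nominal p-values are reported throughout; no
   multiple-testing correction is applied, because branch tests on one
   tree are strongly dependent.

## The synthetic cohort generator

`simulate_cohort()` draws, per study, each man's haplogroup leaf class
from a study-specific frequency vector, lays genotypes down
tree-consistently along the root-to-class path, assigns case status
prospectively from a logistic model
(`baseline_logit + study shift + sum of log allelic ORs over carried
effect branches + 0.35 per decade of age`), subsamples to the target
case/control counts (odds ratios are preserved under outcome-dependent
sampling), and finally injects missingness and spurious heterozygous
calls per call. Ages are truncated normal per study; substructure is a
two-cluster mixture in (EV1, EV2) with the AJ-like cluster at EV1 < 0,
EV2 > 0 and the main cluster constrained to EV1 > 0, so cluster
membership is recoverable exactly on noiseless data.

The default Stage-I-like configuration (`stage1_sim_config()`) uses four
profiles totalling 3,995 cases and 3,815 controls. Its anchor frequencies
are published values: the Finnish study at N1c 0.556, I1 0.276 and R1b
0.048; R1b1a2 above 0.5 in the non-Finnish studies; E1b1b1c near 1.1% of
pooled controls, absent from the Finnish profile, and at 15.4% inside the
embedded AJ-like clusters (about 3.5% of the non-Finnish samples). The
per-study case/control splits and the remaining frequency mass are
illustrative inventions — the real per-leaf vectors are unpublished — and
the defaults are stated once here, not tuned per experiment. Genotyping
noise defaults to 1% missingness and 0.1% heterozygous calls per call.

Two deliberate idealizations:

* The F\* and J\* paragroups carry no mass. The imputation identities the
  tree analysis relies on (e.g. "J1 = J minus J2") are exact only when
  the paragroup between an imputed branch and its typed relatives is
  empty; the generator realizes that operating assumption so that the
  simulate-assign round trip is exact. Real cohorts can violate it, in
  which case an imputed branch absorbs the paragroup men — a limitation
  of the method itself, not of the implementation.
* Haplogroup frequencies are drawn, not evolved: there is no coalescent,
  mutation or migration process, and no linkage to autosomal background.
  Passing tests therefore validate the statistical machinery on data
  satisfying the model's assumptions; they say nothing about, e.g.,
  cryptic substructure beyond the two-cluster emulation.

With the balanced baseline (`baseline_logit = 0`) the superpopulation is
roughly half cases, which makes subsampling efficient; a side effect is
that "controls" are not population-like, so for branches with non-null
effects control frequencies sit slightly off the population vector
(carriers of a protective branch are mildly over-represented among
controls). Null-model checks therefore compare control frequencies, while
effect-model checks compare odds ratios, which the design preserves.

## Operating characteristics measured here

`recovery_experiment()` re-runs the full pipeline (simulate, QC, assign,
adjusted association) per replicate. The packaged test suite runs, with
fixed seeds chosen before the outcomes were inspected:

* type-I error of the adjusted score test on 1,000 null cohorts of
  2,000 + 2,000 men at a ~19%-frequency branch, required to lie in
  [0.035, 0.065] at alpha = 0.05;
* recovery of a true allelic OR 0.5 on the ~1.1%-frequency E1b1b1c branch
  over 500 full-scale (7,810-man) replicates, mean estimated OR within
  0.1 of truth and 95% CI coverage at least 0.92, with coverage also
  tracked on a null ~14% branch;
* exactness of the noiseless simulate-assign round trip, and the
  score/Pearson identity over 1,000 random tables.

These sizes keep the whole suite within a few minutes while leaving the
Monte-Carlo error well inside the asserted bands.

## Numerical and degenerate-input choices

IRLS runs to epsilon 1e-12 (up to 100 iterations) and non-convergence is
an error, not a silent fallback. A score variance at or below machine
epsilon yields an untestable result rather than a division. The Fisher
fallback triggers on any zero cell or on |log OR| > 10 in the alternative
fit (separation guard). Ties in the two-sided Fisher rule follow the
standard implementation's relative tolerance. `se_from_ci()` rejects
degenerate intervals (`ci_low == ci_high`). Tree parsing rejects cycles,
duplicate markers, duplicate nodes, dangling parents and multiple roots
at load time, so downstream code can assume a valid rooted tree.

## Known limitations

* Adjusted per-branch odds ratios from the emulated study (e.g. the
  Stage I E1b1b1c OR of 0.51) require the individual-level cohort data
  and are reproduced only qualitatively, via simulation at matched scale.
* Pooling printed Stage II non-aggressive rows alone gives 0.70, not the
  published Stage II-only 0.68 — printed two-decimal ORs and CI bounds
  lose information, and the reproduction surface therefore targets the
  Stage I+II pooled values, which do reproduce. The discrepancy is
  documented rather than reconciled.
* The exact composition of the published tree figure beyond the named
  haplogroups is not enumerable from text; the packaged tree encodes all
  nodes named in the published tables plus the standard backbone, and
  annotations for the eight monomorphic backbone markers are placeholders
  flagged in the fixture documentation.
* Conflict handling (blank both ends of an inconsistent pair) is a stated
  policy of this package; how the original analysis resolved conflicting
  calls is unpublished.
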