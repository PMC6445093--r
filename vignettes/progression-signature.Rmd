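---
title: "Deriving plasma progression signatures: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving plasma progression signatures: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmasig)
```

# Overview

`plasmasig` implements a multi-stage procedure for finding plasma
proteins associated with metastatic progression in matched pooled-plasma
cohorts, organizing them into an interaction network under upstream
regulators, refining them against a murine progression model and a
tumor cell-line panel, and evaluating the resulting gene signature
against survival in an expression cohort. This vignette documents the
statistical model behind each stage, the tunable parameters with their
defaults and units, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the procedure leaves room
for interpretation.

# The measurement model

Pooled plasma proteomics produces, per cohort, one measured abundance
per peptide per pooled group (metastasized M, metastasis-free non-M).
Abundances are strictly positive intensities whose error is
approximately multiplicative. The generators therefore use a
**lognormal noise model**: an observed peptide abundance is

$$y = a \cdot \phi \cdot e^{\varepsilon}, \qquad
  \varepsilon \sim N\!\left(0,\ \log(1 + \mathrm{CV}^2)\right),$$

where $a$ is the protein's base abundance (lognormal across proteins,
`base_abundance_sdlog = 1.2`), $\phi$ a per-peptide ionization
efficiency (lognormal, `ionization_sdlog = 0.3`), and CV the
coefficient of variation of the measurement (`noise_cv`, default 0.2
for human cohorts, 0.1 for mouse). Because $E[\varepsilon] = 0$ on the
log scale, log fold changes are normally distributed and unbiased:
a planted M/non-M effect of `effect_fc = 1.6` has expected log fold
change exactly $\log 1.6$, and with zero noise every downstream filter's
outcome is exactly predictable from its threshold. Pooled samples are
simulated directly — one abundance per group — mirroring the pooling of
individual patient plasmas; per-patient plasma variation is not modeled.

No variance information is available for the original measurements, so
the noise defaults are free parameters chosen to be realistic for deep
plasma profiling, not estimates. They were fixed from a closed-form
power calculation **before** any test was run: with $k$ peptides per
protein the protein log-FC noise SD is roughly
$\sqrt{2}\,s/\sqrt{k}$ with $s = \sqrt{\log(1+0.2^2)} \approx 0.198$,
so at the default mean of 4.5 peptides the per-cohort probability that a
planted 1.6-fold protein clears the 1.25 cutoff is about 0.93–0.96,
giving an expected sensitivity near 0.95 for the full concordance rule.

**Planted effects sit on multi-peptide proteins only.** The zero-noise
contracts of the pipeline (planted truth must be recovered *exactly*)
would be unsatisfiable if a planted protein could be randomly assigned a
single low-score or ambiguously mapping peptide, which the retention
rules must discard. Single-peptide proteins (10% of nulls), peptides
with identification scores below 6.0 (25%), and multi-protein-mapping
peptides (3%) therefore occur among null proteins, where they exercise
the peptide rules without making the ground truth ambiguous.

# Differential selection rules

Within a cohort (`per_cohort_candidates()`):

* multi-peptide proteins: paired t-test across peptides on
  $\log_2 M - \log_2 \text{non-M}$, threshold `p_cutoff = 0.05`;
* single-peptide proteins: retained only with unique protein mapping
  and peptide score $\ge$ `score_cutoff = 6.0` (natural-log likelihood
  of the peptide-spectrum match), then selected on fold change alone;
* in all cases the protein fold change — the ratio of peptide-abundance
  **means** (configurable to medians; means match the additive pooling
  of peptide signal) — must pass `fc_cutoff = 1.25` strictly, in either
  direction. Ties at exactly 1.25 are excluded ("greater than").

Zero-variance differences need explicit handling because pooled
zero-noise data produce them legitimately: all-zero differences give
$t = 0, p = 1$; a nonzero constant difference is flagged degenerate and
reported at the smallest representable p, so a perfectly consistent
shift always passes a p screen but remains auditable via the flag.

Across cohorts (`concordant_progression_proteins()`), a protein is
progression-related when its FC clears the cutoff in at least
`min_cohorts = 3` of 4 cohorts, **no** cohort shows it beyond the cutoff
in the opposite direction (the opposite-direction veto: a protein up in
three cohorts but clearly down in the fourth is not "concordant"), and a
paired t-test across the cohort-level protein values has
`combined_p_cutoff = 0.1`. The pairing unit of this combined test is the
four per-cohort protein-level (M, non-M) pairs, computed on
**loess-normalized** log2 values; the within-cohort test pairs peptides.
Both thresholds are exposed because the original description does not
say whether they were applied to identically preprocessed values. No
multiple-testing correction is applied at either stage, matching the
source procedure; `geneset_enrichment()` (which BH-corrects across
terms) shows the package's preferred behavior where correction is
standard.

## Loess normalization

`loess_normalize()` removes smooth intensity-dependent bias per sample:
the deviation of each sample from the row-wise reference profile (the
per-protein median across samples) is regressed on the MA-style mean
abundance with `stats::loess` (degree 1, direct surface, default
`span = 0.3`), the fitted curve subtracted, and the sample re-centred so
its median equals the reference median exactly. Log base 2 is used for
all log-scale work. The span and the median reference are package
choices — the method name alone does not determine them; span 0.3 is a
common compromise between bias removal and overfitting at a few hundred
to a couple thousand proteins, and the constant-offset and linear-bias
behavior is pinned by tests.

# Network construction

Edges carry integer confidence on the 0–1000 scale; scored edges are
kept at confidence **strictly greater than** `min_conf = 500`, while
manually curated edges are exempt and carry confidence 1000 (curated
interactions are added without scores). Duplicate undirected edges keep
the highest confidence, curated provenance winning ties; self-loops are
dropped. The graph is undirected throughout; regulator edges keep any
direction annotation for reporting only.

Hub augmentation (`select_hubs()`) ranks candidates from two pools — by
default, proteins detected in all four cohorts and proteins with
FC > 1.25 in at least 3 of 4 (direction-specific; whether the original
second pool required direction concordance is unstated) — by the number
of **distinct** seed proteins they touch, ties broken lexicographically
(the procedure's description never encounters ties). The top two per
pool are taken after skipping an exclusion list (default `ALB`: albumin
connectivity in plasma reflects depletion chemistry and sheer abundance,
not progression biology); skipped candidates are reported with their
link counts rather than silently dropped.

Topology metrics follow the common network-analyzer conventions: local
clustering of nodes with degree < 2 is defined as 0 (one of the two
standard conventions, recorded here so it is auditable); average
neighbors is $2E/N$; characteristic path length averages over connected
ordered pairs only, because a network with isolated nodes — which these
seed networks have — would otherwise have infinite mean distance. The
original study's printed topology (0.145 / 2.444 / 2.920) depends on a
specific interactome snapshot and is not a reproduction target; the
report computes the metrics both before and after hub/regulator
augmentation since the original does not say which variant was printed.
Layers are minimal step sizes to the regulator set (`TGFB1`, `TNF`),
with unreachable nodes in a distinct bottom layer.

# Cross-species refinement

Mouse fold changes F10/S10 (prediagnostic 1 / baseline, fast and slow
tumor groups) and F20/S20 (prediagnostic 2 / baseline) are computed per
protein; selection uses `F20 > 1.3` strictly — F10, S10 and S20 are
reported but not filtered on. Human–mouse matching is case-insensitive
symbol equality; no orthology database is consulted (the shared-symbol
assumption is adequate for the gene-level symbols involved). "Expressed
in cell lines" is operationalized as spectral count $\ge 1$ in $\ge 1$
line in any compartment, both thresholds configurable, since the source
states only detected/not-detected. Secretome cutoffs are **inclusive**
($\ge 1.5$, $\le 0.67$), following the written `>=` convention of that
comparison, and a protein must qualify in both cell-line pairs.

`refine_signature()` encodes the final rule as a rule, not a gene list:
concordantly **up** in the human metastatic contrast, mouse `F20` above
cutoff, and tumor-intrinsic. The generators wire the planted truth so
the chain mirrors the original counts: 13 human–mouse common proteins
(6 up + 7 down), 4 undetected in the panel leaving 9 tumor-intrinsic,
and 3 concordantly-up detected signature genes. (In the original
narrative 13 common minus 3 undetected leaves 10, yet 9 are reported
tumor-intrinsic — one exclusion is unexplained; the synthetic truth uses
4 undetected so its arithmetic is consistent.)

# Survival evaluation

The risk score is the mean expression of the signature genes.
**Standardization before averaging defaults ON**: whether the original
z-scored genes is unstated, but an unweighted mean of genes on different
scales is dominated by the highest-expressed gene; the literal raw mean
is available via `standardize = FALSE`. The high-risk group is the top
`high_frac = 0.25` of scores — the threshold is the
$\lceil 0.25N \rceil$-th largest score and threshold ties go high, with
realized group sizes recorded (the original n = 40/170 split of 210
patients is not an exact quarter; the fraction is configurable for that
reason). Groups are compared by Kaplan–Meier curves and the two-group
log-rank test; hazard ratios come from Cox models with **Efron** tie
handling (more accurate than Breslow at tied event times; Breslow is
selectable), Wald 95% CIs matching the conventional reporting. The
default multivariate model contains the risk-group indicator and the
stage dichotomy, mirroring the fitted rows of the original multivariate
table (its menopause/grade/size rows are "n/d" there — dropped or
non-converged, unexplained — so they enter only the univariate models
here). Survival comparison is at the group level as in the source; a
continuous-score Cox fit is available by passing the score column as a
covariate. A per-gene Pearson correlation with a reference gene
(default `TGFB1`) completes the evaluation.

The survival generator draws signature-gene expression as standard
normal, computes the planted score with the same stratification rule,
and multiplies the exponential baseline hazard (`baseline_hazard =
0.08`/year, exponential chosen as the simplest proportional-hazards
baseline with closed-form behavior) by `true_hr = 1.8` for the planted
high group. Censoring is independent exponential with rate tuned from
the mean hazard so the expected censored fraction is `censor_rate`
(default 0.3); `censor_rate = 0` yields events for everyone.

# What the synthetic data do and do not show

A passing test suite on these generators demonstrates that the selection
rules, network operations and survival machinery are implemented
correctly (they agree with brute-force oracles and closed forms, recover
planted truth at the planted effect sizes, and hold nominal error rates
— log-rank type-I within its binomial band at $\alpha = 0.05$, Cox HR
recovery within 15% at the planted 1.8). It does **not** demonstrate
that real plasma data behave this way: the generators omit correlated
peptide noise, batch and depletion artifacts, heavy-tailed
contamination, missingness-not-at-random, shared biology between null
proteins, and real interactome structure beyond a preferential
attachment degree law. Conclusions about biological cohorts require the
real measurements.

# Problem sizes and numerical choices

Tests and the acceptance script run at the study's natural scale (1618
proteins, 4 cohorts, ~4.5 peptides/protein, n = 210 survival cohort) —
chosen to match the emulated design. Statistical-calibration checks use
1000–2000 null simulations and 100–200 recovery replicates, enough for
the binomial bands they assert. All generators draw from child seeds
derived deterministically from one master seed, so identical
configuration means byte-identical outputs; pipeline outputs contain no
timestamps for the same reason. Degenerate inputs are decided, not
accidental: zero-variance paired tests (above), all-identical risk
scores (stratification refuses: no quantile split exists), empty seed
mapping into the interactome (warning plus empty subnetwork), zero
events (log-rank refuses), constant covariates and zero-variance
correlation inputs (refused or flagged).

# Known limitations

* The concordance rule treats a protein missing or peptide-ineligible in
  a cohort as non-concordant there; proteins eligible in fewer than two
  cohorts cannot enter the combined paired test at all.
* Hub ranking counts direct seed links only; no centrality weighting.
* The mouse model shares the human symbol namespace by construction;
  real ortholog mapping is out of scope.
* Upstream-regulator identities are configuration inputs, not computed
  (the original used proprietary upstream-regulator scoring).
* The acceptance quantities are properties of the synthetic study; the
  original publication's headline numbers rest on unavailable raw data
  and versioned databases and are echoed in the documentation only for
  orientation.
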