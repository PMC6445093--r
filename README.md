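# plasmasig

Tools for deriving and evaluating **metastasis-progression protein
signatures from pooled plasma proteomics** in triple negative breast
cancer (TNBC) style study designs, and for stress-testing the full
analysis chain on synthetic data with planted ground truth.

## The problem and the method

Patients with newly diagnosed TNBC either develop metastasis (M) during
follow-up or remain metastasis free (non-M). Deep quantitative profiling
of pooled plasma from matched cohorts (menopausal status x tumor stage)
yields peptide-level abundance tables; the question is which plasma
proteins move with eventual progression, whether they form a coherent
regulatory network, and whether a compact gene signature derived from
them is prognostic in an independent expression cohort.

The pipeline implements the following chain:

1. **Within-cohort differential selection.** For proteins quantified by
   several peptides, a paired t-test across peptides (log2 M vs non-M)
   with p < 0.05; proteins quantified by a single peptide are kept only
   when that peptide maps to a unique protein and its identification
   score (natural-log likelihood of the peptide-spectrum match) is at
   least 6.0. In all cases the protein fold change
   FC = mean(M peptides) / mean(non-M peptides) must pass 1.25 (strict,
   either direction).
2. **Four-cohort concordance.** A protein is progression-related when
   FC > 1.25 in at least 3 of 4 cohorts with no cohort beyond the cutoff
   in the opposite direction, and a paired t-test across cohorts on
   loess-normalized protein-level log2 values has p < 0.1. Up and down
   sets are disjoint by construction.
3. **Interaction network.** Scored protein-association edges (STRING-style
   0-1000 confidence) are kept at confidence > 500 (curated edges are
   exempt); the progression proteins induce a seed subnetwork that is
   densified with hub proteins ranked by the number of distinct seed
   neighbors (two candidate pools; an exclusion list handles
   depletion artifacts such as albumin). Topology metrics (mean local
   clustering, average neighbors = 2E/N, characteristic path length over
   connected pairs) and hierarchical layers (minimal step size to the
   upstream regulators, TGFB1 and TNF by default) are reported, plus
   hypergeometric gene-set enrichment with BH correction.
4. **Cross-species refinement.** Mouse fast-progressor plasma fold change
   F20 (prediagnostic-2 / baseline) > 1.3 selects the murine progression
   set; its intersection with the human set, restricted to proteins
   detected in a TNBC cell-line panel (tumor-intrinsic) and concordantly
   **up** in the human metastatic contrast, is the refined signature.
   Conditioned-media (secretome) ratios across two metastatic /
   non-metastatic cell-line pairs (>= 1.5 up, <= 0.67 down, inclusive)
   give a supporting comparison.
5. **Survival evaluation.** Per-patient risk score = mean signature-gene
   expression (genes standardized by default); the top quartile is the
   high-risk group; groups are compared by Kaplan-Meier curves and the
   log-rank test, and by uni-/multivariate Cox proportional hazards
   models (Efron ties), plus Pearson correlation of the signature genes
   with TGFB1.

Because raw data of this design are not publicly deposited, the
`synthetic_data` generators emulate every input — peptide tables with
multi-/single-peptide proteins, mapping ambiguity and peptide scores,
lognormal measurement noise, planted fold changes, scale-free scored
interaction graphs, cell-line spectral counts, secretome ratios, and a
survival cohort generated under proportional hazards — with all planted
truth recorded, so every stage is testable end to end.

## Worked example

```r
library(plasmasig)

cfg <- run_config(sim = sim_config(seed = 3))  # 1618 proteins, 4 cohorts
res <- run_pipeline(cfg, outdir = "run3", quiet = TRUE)
writeLines(readLines(res$report_path))
```

```
plasma progression-signature pipeline report
seed: 3
proteins quantified: 1618
progression proteins: 41 up, 42 down
seed network: 72 nodes, 6 edges, clustering 0.0000, avg neighbors 0.1667, path length 1
augmented network (+hubs PROT0002/PROT0011/PROT0236/PROT0532 +regulators TGFB1/TNF): clustering 0.0000, avg neighbors 0.3333, path length 1.759
human-mouse common proteins: 13
tumor-intrinsic: 9
refined signature: PROT0165, PROT1033, PROT1261
high/low risk groups: 53/157
log-rank: chi-square 25.7759, p 3.834e-07
signature HR (multivariate): 2.4387
```

Reading the report: of 1618 simulated plasma proteins, 83 pass the
four-cohort concordance rules (40 + 40 were planted at fold change 1.6
under 20% measurement noise, so a handful of entries are false
discoveries). Thirteen of them are shared with the mouse fast-progressor
set, nine survive the cell-line detection filter, and the three
concordantly-up, tumor-intrinsic genes form the refined signature —
exactly the planted triple for this seed. In the 210-patient synthetic
cohort (planted hazard ratio 1.8 for the top-quartile risk group) the
recovered signature separates survival clearly:

```r
tidy(res$survival$cox_multi)
#>   model        term        beta    hr ci_lower ci_upper    p_value
#> 1 multivariate risk_high  0.891  2.44    1.69      3.53 0.00000221
#> 2 multivariate stage_high 0.205  1.23    0.880     1.71 0.227

res$survival$correlation   # Pearson r of each signature gene with TGFB1
#>   gene         r      p_value     n
#> 1 PROT0165 0.288 0.0000230      210
#> 2 PROT1033 0.367 0.0000000440   210
#> 3 PROT1261 0.382 0.0000000111   210

plot_km(res$survival$km)   # Kaplan-Meier curves of the two risk groups
```

The per-stage functions are ordinary verbs over data frames and can be
piped independently of `run_pipeline()`:

```r
study <- simulate_study(sim_config(seed = 3))
study$plasma$peptides |>
  per_cohort_candidates() |>
  concordant_progression_proteins()
```

In the original study this procedure yielded 43 progression proteins
(22 up, 21 down), a TGFβ-anchored layered network with topology
0.145 / 2.444 / 2.920 (clustering / average neighbors / path length on a
specific STRING + curated-edge snapshot), and the CLIC1, MAPRE1,
SERPINA3 signature; those literature values depend on unavailable raw
data and database versions and are quoted here for orientation only —
the package's own outputs are the synthetic-study quantities above.

## Package layout

- `R/simulate.R` — synthetic-data generators and planted ground truth
- `R/normalize.R`, `R/differential.R` — loess normalization, paired
  testing, per-cohort and cross-cohort selection rules
- `R/network.R` — interaction graph container, edge-file IO, hub
  selection, topology, layers, enrichment
- `R/cross_species.R` — mouse fold changes, species intersection,
  tumor-intrinsic filter, secretome comparison, signature refinement
- `R/survival.R` — risk score, stratification, KM/log-rank/Cox, TGFB1
  correlation
- `R/pipeline.R`, `R/io.R`, `R/plots.R` — orchestration, file dialects,
  ggplot2 figures
- `vignettes/progression-signature.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
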