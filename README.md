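# ariprofiles

Time-specific transcriptional profiles of acute respiratory illness (ARI)
in the nasal mucosa, across four clinical groups — healthy, allergic
rhinitis, asthma without exacerbation, and asthma with exacerbation —
sampled at an asymptomatic baseline (BL) and on days 2 and 6 (D2, D6) of
a naturally acquired cold. The package is written for transcriptomics
analysts studying how underlying airway disease reshapes the host
response over the peak (BL→D2), reduction (D2→D6) and resolution (D6→BL)
of illness.

## What it computes

1. **Blocked moderated differential expression.** Per-gene generalized
   least squares over the 12 group × timepoint cells under an
   equicorrelated within-subject covariance, with the consensus
   correlation ρ estimated as a trimmed mean of per-gene
   method-of-moments estimates on the atanh scale. Empirical-Bayes
   variance moderation: s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ), with (d₀, s₀²)
   moment-matched from the log residual variances, and moderated
   t̃ᵍ = bᵍ/(s̃ᵍ·√vᵍ) on d₀ + dᵍ df. The **ARI gene set** is the union
   over the three time contrasts (D2−BL, D6−D2, D6−BL) of genes with
   Holm-adjusted p < 0.05, with no fold-change filter.
2. **PCA signatures.** Covariance-matrix PCA of the ARI genes per group
   and transition; PC1 oriented so the symptomatic time point scores
   positive; per focal time point, the top-100 most positive (or most
   negative) PC1-loading genes form the group's signature profile; the
   profiles are intersected into **core / shared / distinct** classes
   with a full Venn region table.
3. **Kinetics.** Per-gene group × timepoint trajectories min-max scaled
   to [0, 1], transition log2 fold changes, and UPGMA (average-linkage,
   Euclidean) clustering as a portable merge table.
4. **Clinical statistics.** The a priori asthma-exacerbation adjudicator
   (care-seeking/steroid escalation, OR ≥10-point symptom increase for
   ≥2 days plus an objective change: ≥4 extra albuterol puffs ≥2 days,
   ≥10% FEV1 decline, or ≥20% PEF decline ≥2 days), plus the Friedman,
   Mann-Whitney (exact), Spearman (exact) and two-reference-gene qPCR
   (2^−ΔCt) utilities.
5. **Synthetic cohort generator.** A fully specified longitudinal
   simulator with planted core-D2 / shared-D6 / distinct-D6 signatures,
   within-subject correlation, missing visits and clinical diaries with
   planted exacerbations — every downstream stage is testable without
   any download.

## Worked example

```r
library(ariprofiles)

cfg <- cohortConfig(nGenes = 1000, nSubjectsPerGroup = 8,
                    coreD2N = 30, sharedD6N = 30, distinctD6N = 30,
                    seed = 7)
cohort <- simulateCohort(cfg)

rho <- consensusCorrelation(cohort)
rho
#> ConsensusCorrelation: 0.2963 (trim 0.15, 1000 genes)

de <- moderateStatistics(fitGeneModels(cohort, rho))
de
#> ContrastResults: 3000 rows (1000 genes x 3 contrasts), d0 = 2858, s02 = 0.3555

ari <- selectAriGenes(de, alpha = 0.05)
length(ari)
#> [1] 68

man <- runPipeline(cohort,
                   clinical = simulateClinical(clinicalSimConfig(seed = 7),
                                               cohort),
                   config = pipelineConfig(nTop = 40))
peak <- stageResults(man)$membership[["peak.D2"]]
peak
#> MembershipTable over Healthy/AllrgRhin/AsmNoEx/AsmEx: 57 genes, 30 core, 15 distinct

truth <- plantedTruth(cohort)
mean(truth$gene_id[truth$class == "core_d2"] %in% classGenes(peak, "core"))
#> [1] 1
```

Reading the output: the generating within-subject correlation (0.3) is
recovered at 0.296; the moderation prior found very little excess
variance dispersion (large d₀, strong shrinkage); 68 genes pass Holm
selection (the 30 all-group core genes and the 30 three-group shared
genes easily, the single-group distinct genes rarely — their pooled
contrast effect is diluted fourfold); at the peak transition the core
class is exactly the 30 planted core genes (recovery 1.0). The
adjudicator reproduces every planted exacerbation
(`stageResults(man)$clinical$calls`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ari-pipeline.R`
(`simulate`, `run`, `fetch-geo` subcommands). Reproduction from the
public expression accession is an optional documented path via
`fetchGeoSeries()` / `readSeriesMatrix()`; nothing in the package or
tests requires network access.

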