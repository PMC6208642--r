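# pneumotyper

Stratification of the transcriptionally active lung microbiome into
recurring community configurations — *pneumotypes* — and association of
those subgroups with clinical features, bacterial biomass, exacerbation
history and host gene expression.

## The problem

Metatranscriptome sequencing of bronchoalveolar lavage fluid (BALF)
captures both the transcriptionally active microbial community and host
gene expression in the same sample. Each sample yields a taxa-by-sample
table of microbial read counts (reads assigned to archaea, bacteria, fungi
and viruses, "ABFV reads"), and a taxon's *read abundance* — its fraction
of ABFV reads — proxies its transcriptional activity. Cohorts of such
profiles (e.g. COPD patients and controls) tend not to vary continuously
but to fall into a small number of configurations, each dominated by a
characteristic set of core genera. `pneumotyper` provides the full
analysis chain for discovering, validating and interpreting that
stratification:

1. **Abundance handling** — relative abundance, the inclusive "at least 1%
   in at least one sample" detection filter, Shannon/Simpson/richness
   alpha diversity, rarefaction of detectable taxa, and two-assay
   concordance (e.g. metatranscriptome vs 16S amplicon) by pooled and
   per-sample Spearman correlation.
2. **Taxonomic assignment** — MEGAN-style lowest-common-ancestor (LCA)
   assignment of reads from BLAST-tabular hits (Min Score 100, Top Percent
   10, e-value 1e-10, query coverage 60), with per-rank count tables and
   assignment-rate summaries.
3. **Stratification** — pairwise sample distances as the square root of
   the Jensen-Shannon divergence, d(i,j) = sqrt(H(m) − (H(p_i)+H(p_j))/2)
   with m = (p_i+p_j)/2 and natural-log entropy H; deterministic k-medoids
   (PAM) with the number of clusters chosen by the medoid-based
   Calinski-Harabasz pseudo-F; and, independently, a Dirichlet multinomial
   mixture (DMM) fitted by EM with the component count chosen by BIC.
   Cross-method agreement (optimal label matching + adjusted Rand index)
   and per-subgroup core microbes with their within/between correlation
   structure.
4. **Validation** — average silhouette width, prediction strength
   (half-split co-assignment stability; supported clusterings need
   PS > 0.8), and a simulation test: B community tables are drawn from a
   single-component Dirichlet multinomial fitted to the data (preserving
   library sizes and overdispersion) and the observed CH index is compared
   to that null (significant structure needs p < 0.05).
5. **Association** — from-scratch exact and rank tests dispatched by
   feature type: Fisher's exact r×c test (full fixed-margin enumeration)
   for categoricals, Kruskal-Wallis for continuous features, and a
   goodness-of-fit chi-square for event counts vs exposure
   (E_g = total·exposure_g/Σexposure), with Benjamini-Hochberg and Storey
   q-value control.
6. **Host linkage** — taxa-gene Spearman screens on
   log2(TPM + 1e-5)-transformed expression, nonparametric
   differential-expression screens across subgroups, targeted gene-set
   comparisons (a 13-gene Th17-differentiation set ships with the
   package) and cytokine comparisons.
7. **Synthetic cohorts** — seeded generators for count tables with K
   planted Dirichlet-multinomial components and lognormal library sizes,
   clinical covariates and Poisson exacerbation counts coupled to the
   component labels, and expression matrices with subgroup-shifted and
   taxon-linked genes. These drive every recovery and calibration test.

## Worked example

A bundled set of published cohort summaries reproduces the headline
association between pneumotype and COPD exacerbation frequency —
29 events over 4 years among 21 patients, split 5/10/14 across subgroups
of 12/5/4 patients:

```r
library(pneumotyper)
fx <- cohort_fixtures()
chisq_events(fx$exacerbations$events, fx$exacerbations$patients)
#> $statistic 22.47414   $df 2   $p 1.317659e-05
```

The chi-square of 22.47 on 2 df gives p = 1.3e-5: exacerbation events are
far from proportional to patient numbers, with per-patient frequencies of
0.4, 2 and 3.5 in subgroups I–III. Median bacterial DNA levels of
77.2 / 2.7 / 25.6 pg/ml likewise give the reported 28-fold and 9-fold
contrasts against the low-biomass subgroup:

```r
biomass_fold_change(fx$biomass_pg_ml, reference = "II")
#>   I III
#>  28   9
```

The full pipeline on a synthetic 34-sample cohort (subgroup sizes 20/10/4):

```r
out <- run_demo(seed = 1)
rep <- out$report
rep$pam$index_table
#>   k       CH     cost
#> 1 2 50.80234 9.031033
#> 2 3 58.52318 7.107771      <- CH peaks at the planted k = 3
#> 3 4 43.87065 6.715191
#> 4 5 32.71932 6.432808
#> 5 6 26.54347 6.159492
rep$dmm$chosen_K                     # 3 (BIC minimum)
adjusted_rand_index(rep$pam$labels, out$truth)   # 1: perfect recovery
rep$validation                       # ps 0.979, simulation_p 0.005 -> supported
rep$core_microbes                    # taxon_1+2 / taxon_3+4 / taxon_5
rep$associations[, c("feature", "test", "p")]
#>          feature           test            p
#> 1          smear   fisher_exact 4.023777e-06
#> 2 lymphocyte_pct kruskal_wallis 6.886204e-03
#> 3 macrophage_pct kruskal_wallis 9.307127e-03
#> 4  exacerbations   chisq_events 5.268291e-05
```

Both clustering routes find the three planted pneumotypes, validation
supports them (prediction strength 0.98 > 0.8, simulation p = 0.005
< 0.05), and the association screen flags every planted clinical
coupling. The host-link stage recovers the planted taxon-gene links and
subgroup-shifted genes (`rep$hostlink`).

A thin command-line wrapper for the same flows lives in
`inst/scripts/pneumotyper.R` (`simulate`, `run-all`, `demo` subcommands).

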