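---
title: "Pneumotype discovery: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pneumotype discovery: models, validation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotyper)
```

# The statistical model

`pneumotyper` treats a cohort of lower-airway metatranscriptome profiles
as draws from a small number of recurring community configurations. Two
complementary formalizations are implemented, and agreement between them
is part of the evidence.

**Geometric route (distance-based).** Each sample is its relative
abundance vector $p_i$ on the simplex. Pairwise dissimilarity is the
square root of the Jensen-Shannon divergence,

$$d(i,j) = \sqrt{H(m) - \tfrac{1}{2}\left(H(p_i) + H(p_j)\right)},
\qquad m = \tfrac{p_i + p_j}{2},$$

with $H$ the natural-log Shannon entropy and $0\log 0 \equiv 0$. This
form is finite for zero entries (no pseudocounts are needed), bounded by
$\sqrt{\log 2} \approx 0.833$, and a true metric — the standard choice
for community typing. k-medoids (PAM) partitions the distance matrix, and
the number of clusters is chosen by the Calinski-Harabasz pseudo-F
computed from medoids:

$$\mathrm{CH}(k) = \frac{\sum_c n_c\, d(m_c, \bar m)^2 / (k-1)}
                       {\sum_i d(i, m_{c(i)})^2 / (n-k)},$$

where $m_c$ is cluster $c$'s medoid and $\bar m$ the global medoid (the
sample minimizing total distance). A caveat worth knowing: the cluster
containing $\bar m$ contributes zero to the numerator, which biases the
index downward for the largest cluster's $k$; with very unbalanced
subgroup sizes (e.g. 20/10/4 at $n = 34$) the index can be marginal
between the true $k$ and $k-1$ even when the partition itself is exactly
right. The DMM route below does not share this weakness, and the package
reports both.

**Generative route (model-based).** Counts $x_i$ for sample $i$ with
library size $N_i$ follow a $K$-component Dirichlet multinomial mixture:
component $k$ has weight $\pi_k$ and Dirichlet parameter vector
$\alpha_k$, and

$$\log P(x_i \mid \alpha_k) = \log\Gamma(A_k) - \log\Gamma(N_i + A_k)
 + \sum_t \left[\log\Gamma(x_{it} + \alpha_{kt}) - \log\Gamma(\alpha_{kt})\right],
\qquad A_k = \sum_t \alpha_{kt},$$

with the multinomial coefficient omitted throughout (it is constant per
sample and cancels in responsibilities and in model comparison). The
mixture is fitted by EM: responsibilities via log-sum-exp in the E-step;
in the M-step $\pi_k$ becomes the mean responsibility and each $\alpha_k$
is updated by the digamma fixed-point iteration

$$\alpha_{kt} \leftarrow \alpha_{kt}\,
\frac{\sum_i r_{ik}\left[\psi(x_{it}+\alpha_{kt})-\psi(\alpha_{kt})\right]}
     {\sum_i r_{ik}\left[\psi(N_i+A_k)-\psi(A_k)\right]},$$

which maximizes a lower bound and keeps the observed-data log-likelihood
non-decreasing (asserted to 1e-8 slack in the tests). The component count
is chosen by BIC with $p = KT + (K-1)$ free parameters. BIC stands in for
the Laplace evidence approximation used by some DMM software; it is
simpler, deterministic, and flagged in the run report.

## Assumptions

- Samples are exchangeable given their component; library size is
  independent of component membership.
- Within a component, composition varies as a single Dirichlet — i.e.
  overdispersion but no further sub-structure.
- Rank-based association tests assume only exchangeability under the
  null; no distributional form is imposed on clinical features or
  expression.

# Cluster validation

Three independent checks guard against over-partitioning:

- **Average silhouette width** (ASW): cohesion vs separation per sample;
  singleton clusters score 0.
- **Prediction strength** PS($k$): 50 random half-splits by default; PAM
  on each half; test samples classified to the nearest training medoid;
  per test cluster (size ≥ 2) the fraction of member pairs co-assigned by
  the training classifier; the repeat statistic is the minimum over
  clusters and PS is the mean over repeats. Clusters of size < 2
  contribute 1 (they cannot contradict the classifier). The working
  threshold is PS > 0.8; $k = 1$ is defined as PS = 1.
- **Simulation test**: a single-component Dirichlet multinomial is fitted
  to all samples — a null that preserves the observed library sizes and
  within-cohort overdispersion, which a multinomial null would not —
  and $B = 199$ tables are simulated from it. The p-value is the add-one
  upper tail of the observed CH at the chosen $k$ against the null CH
  distribution, so $p \ge 1/(B+1)$ and is never 0. A clustering is
  "supported" iff PS > 0.8 and simulation $p < 0.05$.

# Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `filter_threshold` | 0.01 | fraction | inclusive "at least 1% in at least one sample" detection rule for transcriptionally active taxa |
| `k_range`, `K_range` | 2–6, 1–6 | clusters | cohort sizes of tens of samples cannot support more |
| `n_restarts` (EM) | 3 | — | one PAM-seeded start plus random soft starts; stabilizes EM |
| `tol`, `max_iter` (EM) | 1e-6, 500 | relative loglik | convergence well below parameter noise |
| `ps_repeats` | 50 | half-splits | SE of PS ≈ 0.02 at PS = 0.9 |
| `B` (simulation) | 199 | tables | p resolution 0.005 at modest cost |
| `q` threshold (clinical screen) | 0.1 | FDR | working threshold for feature discovery |
| `padj` threshold (DE screen) | 0.01 | FDR | thousands of genes tested |
| `p`/`q` thresholds (taxa-gene screen) | 0.01 / 0.01 | — | double gate against the large pair universe |
| LCA: Min Score / Top Percent / e-value / qcov | 100 / 10 / 1e-10 / 60 | bitscore, %, —, % | MEGAN-convention thresholds for BLASTN hits |

# What the synthetic cohorts emulate — and what they do not

`generate_community()` draws, per sample: a component label (categorical
with the configured mixing, or fixed labels), a composition from that
component's Dirichlet, a library size from
round(lognormal(meanlog = 9, sdlog = 0.5)) — median ≈ 8.1k microbial
reads, the scale typical of host-dominated lung metatranscriptomes — and
multinomial counts. The default design is 3 components over 30 taxa:
components 1 and 2 each carry an unequal co-dominant core pair
(Dirichlet mass 40 and 20 over a background of 1 per taxon; mean core
abundances ≈ 45% and 23%) and component 3 a single dominant core (mass
60, ≈ 70%), echoing communities led by *Streptococcus*/*Rothia*,
*Ralstonia*/*Escherichia* and *Pseudomonas* respectively. The total
concentration (≈ 88) keeps samples tight around their core configuration,
as pneumotypes present in ordinations of real cohorts; mixing defaults to
(0.5, 0.3, 0.2).

`generate_clinical()` couples a Bernoulli smear test, truncated-normal
lymphocyte/macrophage percentages (range [0, 100]) and Poisson
exacerbation counts to the component labels; default exacerbation rates
(0.4, 2, 3.5 events per patient over a 4-year follow-up) match the
per-pneumotype frequencies observed in a COPD cohort.
`generate_expression()` plants subgroup-shifted genes (configured log2
effect) and taxon-linked genes whose log2 expression is baseline +
slope × scaled taxon abundance + Gaussian noise, so a zero noise SD gives
an exactly monotone (Spearman 1) link.

Deliberately **not** emulated: raw reads and their QC/alignment, human
rRNA carry-over, reagent/bronchoscope contamination profiles, taxon-taxon
ecological interactions beyond compositional closure, batch effects, and
library-size dependence on biomass. Passing recovery tests therefore
demonstrates that the estimators work when their model assumptions hold
at realistic size and separation — not that real cohorts satisfy those
assumptions.

# Numerical choices

- **PAM determinism and small-instance exactness.** Instances with at
  most 2000 candidate medoid subsets are solved by exhaustive
  enumeration (the swap heuristic, like any local search, can stall even
  at $n = 5$); larger instances use BUILD + best-improvement SWAP. All
  ties break toward the lowest sample index, so results are
  reproducible byte-for-byte.
- **EM safeguards.** $\alpha$ entries floored at 1e-10 during fixed-point
  updates; responsibilities computed via log-sum-exp; non-finite
  likelihoods trigger a restart and only error after all restarts fail.
- **Exact-test conventions.** Fisher r×c: two-sided p as the total null
  probability of tables no more probable than observed (with a 1e-7
  relative tie tolerance), full enumeration for totals ≤ 300, else seeded
  Monte-Carlo with an add-one estimator. Mann-Whitney: exact enumeration
  for combined n ≤ 12 without ties, else normal approximation with
  continuity and tie corrections. Spearman: exact permutation p for
  n ≤ 7 without ties (the enumeration grows factorially and the pipeline
  never needs exactness beyond that), else the t-approximation.
  Kruskal-Wallis uses average ranks with the standard tie correction.
- **q-values.** Single-λ Storey estimator at λ = 0.5:
  $\hat\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))$ times the
  BH-adjusted p. With few tests that are all strongly significant
  $\hat\pi_0$ can reach 0; the BH column is always reported alongside.
- **Degenerate inputs.** Empty sample columns normalize to zero vectors
  with a warning; a zero contingency margin returns p = 1 with a note;
  constant genes/taxa are skipped and listed, never silently dropped.

# Design decisions that were genuinely open

- **Core microbes.** Defined here as: up to `top_m = 2` taxa per subgroup
  with the highest within-subgroup mean relative abundance, each ≥ 5%
  mean and attaining its across-subgroup maximum in that subgroup. The
  correlation structure over all samples (within-core positive,
  between-core negative, from compositional closure plus subgroup
  contrast) is reported with Spearman rho and p per pair. This is a
  documented stand-in for an unavailable reference definition.
- **Two-assay concordance.** The pooled correlation is computed over all
  (shared sample, union-of-taxa) pairs with absent taxa as 0, using
  Spearman throughout; zero→1e-6 substitution is applied only for
  log-scale display, never before correlating.
- **Event-count exposure.** The exacerbation chi-square uses per-subgroup
  patient counts as exposure (not person-years); with the bundled cohort
  fixture this reproduces the printed p = 1.3e-5 exactly to two
  significant figures.
- **DE method.** The differential-expression screen is nonparametric
  (Kruskal-Wallis / Mann-Whitney per gene with BH control) — defensible
  at 10–20 samples per subgroup without distributional assumptions, and
  flagged in the report header.
- **Biomass fold changes.** Ratios of medians truncated toward zero
  (floor), matching the convention of reporting "x-fold higher" medians
  (77.2/2.7 → 28-fold, 25.6/2.7 → 9-fold).

# Problem sizes used by the test suite

Recovery and calibration suites run at sizes chosen to exercise the
estimators meaningfully in pure R: k-selection recovery over 20 seeded
replicates at $n = 40$, $T = 30$, $K = 3$; DMM parameter recovery at
$n = 200$, $T = 10$, $K = 2$; simulation-test type-I calibration over 200
null replicates at $n = 30$, $T = 15$, $B = 99$; taxa-gene null screens
over 20 seeds at 40 taxa × 40 genes; rank-test type-I calibration over
5000 Gaussian replicates. The demo cohort is 34 samples with fixed
subgroup sizes 20/10/4.

# Known limitations

- The medoid-based CH index is marginal for very unbalanced designs (see
  above); at the 34-sample demo size it occasionally prefers $k = 2$
  while PAM's $k = 3$ partition and the DMM/BIC choice are correct.
  Reporting both routes plus validation is the intended safeguard.
- The simulation null is a *single* Dirichlet component; it tests
  "no structure at all", not "fewer clusters than chosen".
- Prediction strength with very small subgroups (< 4 samples) is noisy:
  half-splits may leave 1–2 members per side.
- `dmm_select_K` fits each K independently; for large tables this is the
  slowest stage (cost roughly linear in $K \cdot T \cdot n$ per EM
  iteration).
- The LCA module models the nucleotide (BLASTN/MEGAN) path only; no
  protein-route reconciliation, Min Support filtering, or weighted-LCA
  variants.
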