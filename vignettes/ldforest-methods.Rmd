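---
title: "Multilocus GWAS with latent-tree LD maps and embedded random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus GWAS with latent-tree LD maps and embedded random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP genome-wide association studies test each marker separately
against a binary affected/unaffected phenotype with contingency-table
statistics.  They ignore linkage disequilibrium (LD): nearby SNPs are
strongly dependent, travel in haplotype blocks of limited diversity, and
may jointly carry association signal that no single marker shows
clearly.  `ldforest` implements a multilocus alternative: a bagged
ensemble of *meta-trees* whose every node splits the sample on a whole
cluster of SNPs at once, and ranks SNPs by the split gain they
accumulate across the ensemble.

## The model

### Meta-nodes and the meta-variable

A meta-tree is grown like a classification tree, but a node (a
*meta-node*) does not split on one SNP.  Instead, `K` candidate clusters
are drawn from a cluster map; for each candidate an *extremely
randomized tree* (Extra-tree) is grown on the node's sample over the
cluster's SNPs: at each of its nodes, every non-constant candidate SNP
receives one uniformly drawn threshold in the (min, max) of its values,
and the cut maximizing the information gain

discriminatingScore(cut, D, c) = H(D/c) − w_l · H(D_l/c) − w_r · H(D_r/c)

is kept (entropies in bits; `w_l`, `w_r` the child-sample fractions).
Each Extra-tree leaf is labelled with its training case probability, and
the *meta-variable* ν assigns every observation the label of the leaf it
reaches.  The meta-node then scans the distinct values of ν (all but the
largest) as thresholds, keeps the candidate cluster whose best
`ν ≤ θ` split has maximal gain, and recurses on both sides.  Growth
stops when a node holds fewer than `S_n` observations, the node budget
`S_t` is spent, or no candidate yields positive gain.  Bagging over `T`
bootstrap samples gives the forest; predictions average the meta-leaf
case probabilities.

Per-SNP importance credits every split node of every *winning*
Extra-tree (losing candidates are discarded) with
`(n_node / n_train) · gain`, summed over the forest and normalized
(`sum`, `max`, or raw).

### Two cluster maps, one algorithm

With contiguous blocks of `B = 20` SNPs the ensemble is the classical
T-Trees method.  The hybrid method replaces the block map by the
layer-1 cluster map of a *forest of latent tree models* (FLTM) — a
tree-shaped Bayesian network whose leaves are SNPs and whose internal
nodes are discrete latent variables:

1. active variables are clustered with DBSCAN on the dissimilarity
   `1 − NMI` (normalized mutual information), with an edge allowed only
   between variables on the same chromosome within `δ` base pairs;
2. each cluster of size ≥ 2 becomes a latent class model (LCM) whose
   latent cardinality is `min(α + β·n_c, card_max)` (rounded, floor 2);
3. EM fits the LCM (best of `nb_em_restarts` random starts), the latent
   column is imputed by sampling the posterior `P(L | children)`;
4. the latent is *validated* iff its mean normalized MI with its
   children reaches `τ` (inclusive); validated latents replace their
   children and the loop repeats.

Because validation involves EM-fitted parameters, the layer-1 map is
more than a clustering: each cluster has passed a model-quality gate.

### The single-SNP baseline and QC

`single_snp_scan()` offers the 2-df Pearson genotype test (default) and
the 1-df Cochran–Armitage trend test; ties in p-value keep dataset
order.  Two QC presets exist: `simulated` (MAF < 0.05; exact HWE
p < 0.001) and `wtccc` (missingness > 5%; missingness > 1% with
MAF < 5%; exact HWE, trend and general-test p < 5.7×10⁻⁷).

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `T` | meta-trees | 1000 | `desk` preset: 50 |
| `S_n` | meta-leaf threshold (observations) | 2000 | `desk`: 250 |
| `S_t` | meta-tree split budget | ∞ | counted depth-first |
| `K` | clusters drawn per meta-node | 1000 | `desk`: 100 |
| `s_n`, `s_t` | embedded-tree leaf / split budgets | 1, 5 | `s_t` counts split nodes |
| `k` | SNPs drawn per embedded node | all in cluster | equal footing of maps |
| `B` | block size (T-Trees) | 20 | |
| `α`, `β`, `card_max` | latent-cardinality heuristic | 0.2, 2, 10 | cap reached at n_c ≥ 5 |
| `τ` | latent validity threshold | 0.3 | inclusive |
| `nb_em_restarts` | EM restarts | 10 | desk runs use 3 |
| `δ` | max clustering distance (bp) | 50 000 | inclusive |
| `R`, `N_min` | DBSCAN radius / core degree | grid, 2 | see below |

Taken literally, the cardinality heuristic `min(0.2 + 2·n_c, 10)` caps
at 10 states for any cluster of five or more SNPs; a slope/intercept
swap would behave differently, but the formula is implemented as stated.

### Choosing the DBSCAN radius

`select_R()` learns one FLTM per candidate radius and keeps the model
maximizing the mean per-SNP validation score, where SNPs never subsumed
by a validated latent score 0 (`Σ size·score / n_snps`).  A pure
quality criterion (mean score over validated latents only) is monotone
in favour of tiny, tight clusters and degenerates to an all-singleton
map; weighting by coverage gives an interior optimum.  Ties go to the
smallest radius.

## The synthetic-data generator

Real GWAS panels were not redistributable, so experiments run on a
block-haplotype simulator that reproduces the one property the
multilocus methods exploit — limited local haplotype diversity:

* the panel is cut into blocks of 5–15 SNPs; each block carries 5
  distinct 0/1 haplotypes with Dirichlet(1) frequencies; positions are
  laid at 1 kb spacing on one chromosome;
* a gamete carries a latent uniform that is redrawn with probability
  0.5 at each block boundary and is mapped through each block's inverse
  haplotype CDF — block marginals are exact while consecutive blocks
  remain correlated;
* causal SNPs are drawn among SNPs whose population MAF lies in the
  configured interval; the risk allele is the minor allele; penetrances
  `(f0, f1, f2)` solve `K = f0 (p0 + γ1 p1 + γ2 p2)` under HWE with
  relative risks `(γ, 2γ−1)` (additive), `(γ, γ)` (dominant) or
  `(1, γ)` (recessive);
* with several causal SNPs, relative risks combine multiplicatively
  across loci, `P(aff|g) = K · Π_i rr_{g_i}/E[rr_i]`, so each causal
  SNP keeps its configured *marginal* GRR and the unconditioned
  prevalence stays `K` — the convention of the standard retrospective
  case-control simulators this generator emulates.  (An
  independent-risks combination `1 − Π(1 − f_i)` was evaluated and
  discarded: with 10 causal SNPs it dilutes each marginal relative risk
  from 1.8 to ≈ 1.06, below detectability at desk sample sizes.)
* case/control status is rejection-sampled until the configured counts
  are reached.  Defaults are the reference conditions: 20 000 SNPs,
  2 000 + 2 000 individuals, 10 causal SNPs, prevalence 0.01.

What the generator does *not* model: recombination-map realism,
mutation, population structure and relatedness, genotyping error,
untyped causal variants.  Passing tests therefore demonstrate method
behaviour under idealized LD, not performance on real cohorts.

## Numerical choices

* Entropies and MI use base-2 logarithms; normalized MI is
  base-invariant.  `0 log 0 = 0` throughout.
* EM: tolerance 10⁻⁴ (nats) on the log-likelihood, at most 200
  iterations, restart `r` seeded `seed + r`; missing child values are
  marginalized out of the E-step; empty latent states re-initialize
  their CPT columns to uniform.
* Latent imputation samples the posterior with a dedicated seed;
  validation is computed on the imputed column (zero-entropy latents
  are invalid with score 0; constant children contribute 0).
* Extra-tree thresholds are drawn uniformly in the open (min, max), so
  both children are always non-empty; candidate ties keep the first
  drawn; meta-threshold ties keep the smallest θ.
* A meta-node whose best candidate has zero gain becomes a leaf
  (zero-gain splits cannot improve the ensemble and need not
  terminate).
* Missing genotypes are mode-imputed per SNP (ties to the smallest
  code) once before forest learning; prediction reuses the training
  modes.
* All randomness flows through R's RNG: `fit_forest` seeds tree `t`
  with `seed + t`; FLTM derives one seed per (layer, cluster) fit.  The
  implementation is serial, so results are independent of any worker
  count by construction.
* Monomorphic SNPs get `p = 1` in scans; degenerate contingency tables
  (a zero row, or a single observed genotype class) raise errors; the
  2-df test collapses its df when a genotype column is absent.

## Desk-scale experiment sizes

The packaged experiments (tests and `scripts/acceptance.R`) run the
full pipeline at 2 000 SNPs × (500 + 500) individuals, 5 replicates,
with `T = 50`, `K = 100`, `S_n = 250`, FLTM with 3 EM restarts, layer 1
only, and DBSCAN radius 0.6 — the package's desk preset.  `S_n`
shrinks with the sample so meta-trees keep several levels; prevalence
and effect-size calibration use 10⁵ and 2×10⁴ unconditioned draws.

## Known limitations

* The FLTM layer-1 map, not deeper layers, feeds the hybrid forest;
  deeper layers are built and retained for inspection only.
* `select_R` re-learns the full model per grid point; on large panels
  prefer a coarse grid or a fixed radius.
* The PLINK text reader supports biallelic `.ped`/`.map` only (no
  `.bed`, VCF or BGEN); writing collapses alleles to synthetic A/B
  labels, so round-trips preserve codes only when codes are
  minor-allele counts.
* Importance has no significance calibration; rankings are comparable
  between methods, not against a null threshold.
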