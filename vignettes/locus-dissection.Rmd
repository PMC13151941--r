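---
title: "Dissecting a GWAS risk locus from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a GWAS risk locus from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusdissect)
```

# Scope and model

`locusdissect` implements the statistical spine of an integrative dissection
of a single GWAS risk locus — the kind of analysis used to move from a
melanoma/nevus association signal to candidate causal variants, candidate
effector genes, and a downstream tumor-cohort characterization. Everything
operates on summary-level inputs (z-scores, an LD correlation matrix,
interval tracks, scored chromatin interactions, cohort tables), and a
synthetic-data module generates all of them with known ground truth, so every
stage is testable without access to restricted genotype or patient data.

## Fine-mapping

The fine-mapping engines work under the RSS (regression with summary
statistics) likelihood

$$ z \mid b \sim \mathcal{N}(\sqrt{n}\, R\, b,\; R), $$

where $z$ is the vector of marginal association z-scores, $R$ the LD
correlation matrix and $b$ the standardized causal effects.

* `single_effect_finemap()` assumes exactly one causal variant. With the
  Wakefield approximate Bayes factor
  $\log \mathrm{ABF}_i = \tfrac12\log\frac{V}{V+W} + \tfrac12 z_i^2
  \frac{W}{V+W}$ and a uniform causal prior, the posterior inclusion
  probability is $\mathrm{PIP}_i = \mathrm{ABF}_i / \sum_j \mathrm{ABF}_j$ —
  the exhaustive enumeration of the $m$ single-causal models.
* `susie_rss()` fits a sum of $L$ single effects (default $L = 5$) by
  coordinate-ascent variational inference on the sufficient statistics
  $(R, z)$: each effect is refit against the residual z-scores left by the
  others, yielding a per-effect inclusion vector $\alpha_l$ summing to one;
  $\mathrm{PIP}_i = 1 - \prod_l (1 - \alpha_{li})$. The evidence lower bound
  is computed each sweep and asserted non-decreasing; the fit errors out if
  that ever fails. Each non-null effect yields a credible set — the smallest
  variant set by descending $\alpha_l$ reaching the coverage target (default
  0.95). Purity (minimum absolute pairwise LD among members) is reported,
  and the purity filter `min_abs_corr` defaults to 0, i.e. no set is dropped
  for purity — matching how the locus was fine-mapped upstream.

Two parameter choices deserve comment.

*Prior effect variance.* By default each effect's prior variance is
re-estimated every sweep by maximizing the single-effect marginal likelihood,
with a null check that sets it to zero when the null fits better. This is
deterministic given the data, and it is what keeps spent effects from
spawning spurious diffuse credible sets: a zeroed effect has uniform
$\alpha$ and is excluded from set construction. `estimate_prior_variance =
FALSE` with a fixed `prior_variance` recovers the exact one-effect
equivalence with `single_effect_finemap()` (tested to $10^{-6}$).

*ABF variance convention.* For z-score input the sampling variance of the
standardized effect is taken as $V = 1/n$ and the prior variance defaults to
$W = 0.15^2$, the conventional quantitative-trait choice. Only the ratio
$W/(V+W)$ affects variant ranking.

## Credible-variant selection and union

Three selection rules mirror the locus-dissection procedure:

* `retain_credible_sets()` keeps only credible sets with cumulative PIP
  strictly above 0.85, then drops members with individual PIP at or below
  0.005. Both thresholds are strict, and the rule is a *post-hoc retention
  filter*, not the coverage parameter of set construction.
* `llr_select()` retains variants within a 1:1000 likelihood ratio of the
  lead. The underlying likelihood is not uniquely determined by that phrase;
  we adopt the normal approximation, under which the log-likelihood of a
  marginal association is $z^2/2$, so $\mathrm{LLR}_i = (z_i^2 -
  z_\mathrm{lead}^2)/2$ and the retention rule is $\mathrm{LLR}_i \ge
  -\log 1000$. At $z_\mathrm{lead} = 6$ the retention boundary sits at
  $|z| = \sqrt{36 - 2\log 1000} \approx 4.710$.
* `ld_supplement()` adds variants absent from the GWAS (e.g. unimputed
  indels) with reference-panel $r^2 > 0.8$ (strict) to the lead.

`union_ccv()` takes the union across any number of fine-mapping engines plus
the two auxiliary rules, tagging provenance per source and ordering
deterministically by position then id. External engines participate through
a documented long-format TSV (`write_finemap()` / `read_finemap()`), so
engines whose internals are out of scope here can still feed the union.

## Conditional association

`conditional_z()` implements COJO-style conditioning on the standardized
scale: for conditioning set $C$,

$$ z^{c}_j = \frac{z_j - R_{jC}(R_{CC} + \lambda I)^{-1} z_C}
  {\sqrt{1 - R_{jC}(R_{CC} + \lambda I)^{-1} R_{Cj}}}. $$

The ridge defaults to $\lambda = 10^{-8}$; variants whose conditional
variance falls below $10^{-10}$ are flagged collinear and excluded. With the
default ridge, a variant perfectly collinear with the conditioning set
instead survives with $z^c \approx 0$ — the behavior wanted when a gene's
sole predictor variant is conditioned away. Conditioning on the empty set is
the identity. The formula is validated against per-variant OLS with the
conditioned variant as a covariate on simulated genotypes ($r > 0.99$).

## Colocalization

`coloc_enumerate()` performs the five-hypothesis enumeration under at most
one causal variant per trait, entirely in log space:
$H_0$ no association, $H_1/H_2$ one trait only, $H_3$ distinct causals,
$H_4$ shared causal, with priors $p_1, p_2, p_{12}$. The shared-causal prior
(the analog of the upstream tool's "sigma") defaults to the stringent
$10^{-5}$, with $10^{-4}$ and $10^{-3}$ the other tested magnitudes.
Posterior $PP_4 > 0.8$ is read as strong evidence for colocalization and
$PP_4 < 0.2$ as evidence against. `coloc_per_signal()` extends this to
multi-signal loci: every retained single effect of each trait carries its
per-variant log-Bayes-factor vector, each effect pair is enumerated, and the
matrix plus maximum $PP_4$ is reported. The enumeration is tested against a
brute-force double loop over all configurations ($<10^{-12}$), and
planted-shared versus planted-distinct simulations separate cleanly across
the 0.8/0.2 band.

## TWAS, conditional and joint gene models

`build_weights()` trains per-gene predictor weights from eQTL summary
statistics alone (`top1`, `topk`, or `ridge` on $(R + \lambda I)^{-1} z$);
individual-level elastic-net training is out of reach of summary input, and
the scheme is recorded in the output. `twas_z()` computes
$Z = w'z / \sqrt{w' R w}$. `condition_gwas_on_genes()` treats each gene as a
pseudo-variant — SNP–gene correlation $R w_g / \sqrt{w_g' R w_g}$, gene–gene
correlation analogous, pseudo-z equal to the marginal TWAS statistic — and
reuses the conditional-association formula, so "condition the GWAS on
predicted expression" and "condition on lead eQTL SNPs" are the same
machinery applied to different conditioning sets. `joint_twas()` solves the
marginal statistics against the gene–gene correlation matrix (GLS), giving
per-gene joint statistics that reduce to the marginals for uncorrelated
genes and reject collinear gene models.

## Regulatory annotation and variant-to-gene nomination

All interval logic is 0-based half-open (BED convention) at the API, with
overlap computation delegated to GenomicRanges through a single conversion
point. `classify_state()` maps chromatin-state names to
enhancer/promoter/other using the melanocyte (primary, auxiliary, imputed)
and melanoma-cell vocabularies; unknown states map to `other` with a
warning. A variant is cis-regulatory when it overlaps an enhancer state, a
promoter state, *or* an ATAC peak — accessibility alone suffices.

For capture-HiC nomination, each variant is padded by ±500 bp
(`variant_window()`, clamped at the chromosome start), mapped to the
restriction fragments overlapping that window plus one adjacent fragment on
each side (`fragments_for()`; the width of "adjacent" is not externally
defined, so ±1 fragment is the default and configurable), and
`nominate_genes()` nominates a gene when an interaction with score strictly
above 5 links any of those fragments to a fragment containing the gene's
promoter, treating fragment pairs as unordered and deduplicating by maximum
score. `refine_regulatory()` upgrades candidates whose supporting variants
are cis-regulatory. An optional four-fragment pre-merge
(`merge_fragments()`) reproduces coarser aggregated-resolution calls.
`assign_probe_to_gene()` implements the methylation-probe rule: assignment
by feature overlap or TSS distance ≤ 1,500 bp, strand ignored.

## Tumor-cohort analyses

`model_spec()` encodes five nested mutant definitions: Model 1 uses hotspot
codons only (BRAF 600/601, NRAS 61/12/13, matched by position regardless of
the alternate residue); Models 2–5 require a driver-flagged mutation in a
growing gene set (BRAF/NRAS → +KRAS/HRAS → +NF1 → a pathway panel). The full
44-gene panel is an input; a 10-gene stand-in ships for testing. Cohorts
with partial sequencing classify over their assessed genes (configurably
`NA` instead). Nesting — mutant under Model $k$ implies mutant under Model
$k{+}1$ when hotspots carry driver flags — is asserted over fuzzed tables.

`expr_association()` regresses expression on a WT indicator plus available
covariates (age, sex, purity, ordinal stage); positive coefficients mean
higher expression in wild-type tumors. Covariates missing for a whole cohort
are dropped; samples missing an available covariate are dropped. Without
covariates the statistic equals the pooled two-sample t (tested
algebraically).

For survival, expression is dichotomized at the *full-cohort* median (ties
to "low", a deterministic convention the source analysis leaves open), stage
I tumors are excluded (missing stage is retained), and `firth_cox()` fits a
Cox model within the wild-type subgroup, maximizing the Firth-penalized
Efron partial likelihood $\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det
I(\beta)$ by Newton steps with step-halving. The Jeffreys penalty keeps
estimates finite under the monotone-likelihood configurations that small
WT subgroups produce; standard errors come from the curvature of
$\ell^*$ at the optimum (the penalty gradient and curvature are evaluated by
central finite differences, adequate for the low-dimensional covariate sets
used here). With rich data the estimate agrees with the unpenalized fit to
2%; under complete separation it stays finite where the unpenalized
estimate diverges.

`meta_z()` combines per-cohort z-scores with weights
$w_i = \sqrt{n_{\mathrm{eff},i} / \sum_j n_{\mathrm{eff},j}}$, where
$n_\mathrm{eff} = n^+ n^- / (n^+ + n^-)$ (any constant factor cancels after
normalization, which also absorbs the typographic ambiguity in the source's
printed formula). Since $\sum w_i^2 = 1$, $Z_\mathrm{meta} = \sum w_i z_i$
is standard normal under the null — verified by simulation. Group sizes are
mutant/WT for the expression meta-analysis and high/low expression (among
analyzed WT samples) for the survival meta-analysis; `run_cohort_panel()`
wires classification, per-cohort fits and per-treatment-stratum
meta-analysis together.

# The synthetic-data generator

The generator defines the study conditions the tests run under:

* **LD**: block-diagonal AR(1), $R_{ij} = \rho^{|i-j|}$ within a block. This
  is the simplest structure with tunable decay and closed-form entries
  (hence exactly checkable); it does not emulate recombination-map LD or
  long-range haplotype structure.
* **Z-scores**: one draw from $\mathcal{N}(\sqrt{n} R b, R)$. Default study
  conditions for recovery experiments are $m = 200$, $\rho = 0.95$, two
  planted causals with standardized effect $b = 0.05$ at $n = 50{,}000$
  (marginal $|z| \approx \sqrt{n}\,b \approx 11$), matching the scale of a
  well-powered GWAS locus.
* **Genotypes**: Gaussian copula — two latent haplotype draws from
  $\mathcal{N}(0, R)$ thresholded at the $1-\mathrm{maf}$ quantile and
  summed. Dosage correlation is a deterministic monotone attenuation of $R$,
  which is sufficient for the OLS cross-checks; it is not a population
  genetic model.
* **Tracks**: restriction fragments tile the chromosome between cut
  positions; planted interactions connect the fragment containing each
  enhancer to the fragment containing the target promoter at a chosen score;
  background interactions land on random fragment pairs.
* **Cohorts**: mutations are independent Bernoulli draws per (gene, protein
  change); expression is $\delta \cdot \mathbb{1}[\mathrm{WT}] + \gamma'
  \mathrm{covariates} + \varepsilon$; survival is exponential with hazard
  $h_0 e^{\beta \cdot \mathbb{1}[\mathrm{high}]}$ and independent
  exponential censoring, in days. The closed-form median $\log 2 / h_0$
  anchors the calibration tests.

Every generator is bit-for-bit reproducible from its spec and seed, and all
planted truth is returned alongside the data. Passing tests on these inputs
demonstrate correctness of the statistical machinery under the stated
models; they do not demonstrate robustness to real-data pathologies such as
mismatched LD reference panels, imputation error, batch effects in
expression, or informative censoring.

# Worked example

```{r finemap}
spec <- locus_spec(
  n_variants = 200, block_sizes = 200, rho = 0.95,
  causal_effects = list(gwas = list(c(50, 0.05), c(150, 0.05))),
  sample_sizes = c(gwas = 50000), seed = 42)
sim <- simulate_locus(spec)
fm <- retain_credible_sets(susie_rss(sim$stats$gwas, sim$ld, L = 5))
fm
lead <- sim$stats$gwas$id[which.max(abs(sim$stats$gwas$z))]
ccv <- union_ccv(list(fm), llr_select(sim$stats$gwas, lead),
                 character(), lead,
                 positions = setNames(sim$stats$gwas$pos, sim$stats$gwas$id))
head(ccv)
```

```{r coloc}
shared <- locus_spec(
  100, block_sizes = 100, rho = 0.95,
  causal_effects = list(gwas = list(c(50, 0.05)), eqtl = list(c(50, 0.05))),
  sample_sizes = c(gwas = 50000, eqtl = 50000), seed = 7)
sim2 <- simulate_locus(shared)
prior <- abf_prior(V = 1 / 50000)
coloc_enumerate(wakefield_log_abf(sim2$zscores$gwas, prior),
                wakefield_log_abf(sim2$zscores$eqtl, prior),
                coloc_priors(1e-4, 1e-4, 1e-5))
```

```{r cohort}
co <- make_cohort(cohort_spec(400, delta = 0.5, seed = 11))
expr_association(co, model_spec(1), cohort_name = "sim")[c("beta", "z", "p")]
```

# Numerical choices and degenerate inputs

* Credible-set construction breaks ties by ascending variant index
  (deterministic output).
* Non-positive-definite LD is regularized by adding $10^{-8}$ to the
  diagonal with a message, or rejected (`on_nonpsd = "error"`).
* The ELBO convergence tolerance is $10^{-4}$ with a 200-iteration cap;
  decreases beyond $10^{-6}$ abort the fit rather than silently continuing.
* All-zero z-scores are legal everywhere: uniform PIPs, no retained sets, a
  warned deterministic `top1` weight choice.
* All-equal expression dichotomizes to all-"low" with a warning; event-free
  survival data are rejected.
* Problem sizes used by the shipped tests (100-seed recovery at $m = 200$,
  5,000-draw calibrations, 10,000-panel meta null, 200-replicate Firth
  recovery at $n = 500$) were chosen as the smallest scales at which the
  binomial/Monte-Carlo bands in the checks are meaningful.

# Known limitations

* The fine-mapping engine assumes the z-scores and LD matrix come from the
  same population; LD-mismatch-robust estimation is out of scope (external
  engines can contribute through the TSV interface).
* Weight training is summary-based; FUSION-style penalized regression on
  individual-level expression is not implemented.
* CHiCAGO scores, read alignment and peak calling are upstream of this
  package: interactions arrive already scored.
* The survival generator uses exponential hazards; the Firth-Cox
  implementation itself is semiparametric, but its recovery tests inherit
  the proportional-hazards assumption.
* Driver annotation is an input (a flag on each mutation), not a calling
  procedure.
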