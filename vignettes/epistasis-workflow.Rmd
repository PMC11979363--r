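---
title: "Transcriptome-wide epistasis and starvation-survival statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-wide epistasis and starvation-survival statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When two genes are mutated singly and in combination, the pattern of
gene-expression changes in the double mutant relative to the single mutants
reveals how the genes interact. If the genes act independently, log2 fold
changes combine additively gene by gene; if they act in an unbranched linear
pathway, the double mutant phenocopies the epistatic single mutant. This
package implements a transcriptome-wide version of that logic for a bulk
RNA-seq design with four genotypes — wild type (`wt`), two single
loss-of-function mutants (`a`, `b`) and the double mutant (`ab`) — together
with the companion statistics such a study needs: gene-set concordance tests,
starvation-survival curve fits with half-life comparisons, nonparametric
factorial ANOVA for balancer-segregation proportions, and positional analysis
of peptide intensities around a protein cleavage site. Every stage can run on
synthetic data with known ground truth, so the whole pipeline is testable
without any external download.

## The epistasis model

For each gene $i$, let $\beta_{a,i}$, $\beta_{b,i}$ and $\beta_{ab,i}$ be the
log2 fold changes of the two single mutants and the double mutant against the
wild type. Under log-additivity (independent action) the expected
double-mutant coefficient is $x_i = \beta_{a,i} + \beta_{b,i}$. Writing the
observed deviation as $\Delta_i = \beta_{ab,i} - x_i$, the transcriptome-wide
epistasis coefficient $s$ is the slope of the through-origin weighted
regression of $\Delta$ on $x$ over the genes significant in all three
contrasts:

$$\hat s = \frac{\sum_i w_i x_i \Delta_i}{\sum_i w_i x_i^2},
\qquad w_i = \frac{1}{se_{a,i}^2 + se_{b,i}^2 + se_{ab,i}^2}.$$

Two identities anchor the interpretation: perfect additivity gives $s = 0$
($\Delta \equiv 0$), and an unbranched pathway in which both single mutants
share the pathway phenotype ($\beta_a = \beta_b = \beta_{ab}$ per gene) gives
$s = -1/2$ exactly ($\Delta = -v$, $x = 2v$). We use the deviation-versus-
expectation form rather than observed-versus-expected (slopes 1 and 1/2
there) because it makes the additive null a zero slope; the two forms carry
the same information.

### Measurement-error correction

Both $x_i$ and $\Delta_i$ are built from *estimated* fold changes, and the
single-mutant errors enter them with opposite signs, so the naive ratio is
biased: with $S = \sum w x^2$ over the true values and
$T = \sum w (se_a^2 + se_b^2)$,

$$E\left[\textstyle\sum w \hat x \hat\Delta\right] = sS - T, \qquad
  E\left[\textstyle\sum w \hat x^2\right] = S + T.$$

The default estimator therefore applies the method-of-moments
errors-in-variables correction
$\hat s = (\sum w \hat x \hat\Delta + T) / (\sum w \hat x^2 - T)$, which
reduces exactly to the plain ratio when standard errors vanish (so the exact
identities above are untouched). `me_correct = FALSE` gives the uncorrected
slope.

### Bootstrap and Bayesian model rejection

Uncertainty in $\hat s$ is assessed by a gene-resampling bootstrap (default
5,000 draws): each draw resamples genes with replacement, perturbs every
coefficient by a Normal draw with its standard error, and recomputes $\hat s$.
Three predefined interaction models are simulated with the *same* resampling
scheme, replacing $\beta_{ab}$ per draw by the model's prediction from
perturbed singles:

* **additive** — $\tilde\beta_a + \tilde\beta_b$;
* **linear activation** (a activates b, unbranched pathway) — the
  inverse-variance-weighted mean of $\tilde\beta_a$ and $\tilde\beta_b$;
* **linear suppression** (a suppresses b) — $\tilde\beta_b$.

The prediction is formed from one draw of perturbed singles, and then all
three coefficients — including the predicted double, perturbed by the gene's
double-mutant standard error — receive fresh perturbations before the
coefficient is recomputed. This two-stage scheme matters: if the model
prediction reused the very same perturbed singles that enter the regression,
the additive model's deviations would be identically zero, its bootstrap
distribution would collapse to a point mass, and the model comparison would
spuriously reject additivity whenever the data carry any noise. With the
two-stage scheme the model draws experience the same measurement-error
structure (and hence the same residual attenuation) as the parameter-free
draws they are compared against.

Each candidate distribution gets a Gaussian kernel density (Silverman
bandwidth); a model's likelihood is the mean of its density over the
parameter-free draws, the odds ratio is
$\mathrm{OR} = L(\text{free}) / L(\text{model})$ (reported as `inf` when the
model likelihood underflows), and a model is rejected when
$\mathrm{OR} > 10^3$ (strict inequality). A zero-variance draw vector is
treated as a point mass: infinite density on the mass, zero elsewhere.

```{r}
library(epiwide)
sim <- simulate_counts(sim_config(n_genes = 2000, interaction_model = "additive",
                                  seed = 1))
fit <- epistasis_pipeline(sim, n_boot = 5000, seed = 1)
summary(fit)
plot(fit)
```

## Differential-expression front ends

The epistasis stage consumes per-contrast tables of log2 fold change,
standard error and BH q-value. Three routes produce them:

1. **`deseq2_fc_tables()`** (default in `epistasis_pipeline()`): one
   negative-binomial GLM across genotypes with DESeq2, Wald contrasts per
   mutant, and apeglm-shrunken posterior fold changes. Shrinkage is not
   cosmetic here: shared-DEG selection (q < 0.1 in *all three* contrasts)
   preferentially retains genes whose estimation error pushed them across the
   threshold, and that selection-aligned error otherwise propagates into the
   regression and attenuates $\hat s$ by roughly 0.1 under our generating
   conditions. Posterior fold changes remove most of that inflation; the
   selection p- and q-values remain the unshrunken Wald tests.
2. **`fc_tables_vs_ref()`**: a fully transparent stand-in — per gene
   `log2(CPM + 0.5)` group means, pooled two-sample SE, two-sided t with
   pooled df, BH across genes. With three replicates this test has 4 degrees
   of freedom, and BH over its heavy-tailed p-values is so conservative that
   the three-way shared-DEG intersection is typically empty; the stand-in is
   therefore the calibration reference (its null p-values are uniform) and a
   reading aid, not the recommended epistasis front end.
3. **`read_fc_table()`**: externally computed tables in native, DESeq2- or
   edgeR-style columns (edgeR tables carry no SE; it is reconstructed from
   `|logFC| / qnorm(1 - PValue/2)` and flagged).

Counts are TMM-normalized (`tmm_factors()`, delegated to edgeR's
implementation of the trimmed mean of M-values: 30% M-trim, 5% A-trim,
precision weights, factors rescaled to geometric mean 1) and filtered to
genes with CPM > 1 in at least three libraries before any testing, mirroring
standard detection practice. The multi-genotype call behind the heatmap-style
cluster analysis is a per-gene one-way F test on log2 CPM (`anova_deg()`),
clustered by `cluster_order()` with Euclidean distance and complete linkage
(the linkage is configurable; complete is the choice where the method was
otherwise unspecified). Zero-variance genes z-score to all-zeros rather than
erroring.

## The synthetic-data generator

`simulate_counts()` emulates the four-genotype, three-replicate bulk RNA-seq
design. Defaults are fixed once and define the validation conditions:

* ~15,000 genes with baseline log2 expression Normal(5, 1.5) on a CPM-like
  scale, so nearly all genes pass the detection filter, as in a typical
  whole-organism bulk experiment;
* a fraction `pi_de = 0.3` of genes carry effects drawn Normal(0, τ = 1);
  at 2,000 genes this yields several dozen to a few hundred shared DEGs,
  commensurate with the hundreds of shared DEGs such studies report at full
  scale;
* NB dispersion φ = 0.1 (`Var = μ + φμ²`), typical for bulk RNA-seq;
* library sizes Uniform(0.8–1.2 × 10⁷) to exercise normalization;
* the interaction model fixes the double-mutant effect:
  `additive` (β_ab = β_a + β_b), `linear_activation`
  (β_a = β_b = β_ab = v), `linear_suppression` (β_ab = β_b with
  anti-correlated singles by default — the hyperactivated-target signature;
  the correlation is a knob), and `custom_s`
  (β_ab = (1+s)(β_a+β_b)) for recovery experiments.

What it does *not* emulate: GC/length biases, batch effects, outlier genes,
correlated gene modules, or count heteroscedasticity beyond the NB law. A
passing recovery test therefore shows the estimator chain is consistent under
the assumed error model, not that any real dataset satisfies that model.

`simulate_survival()` draws daily alive/plated counts from a logistic true
curve `p(t) = plogis(β0 + β1 t)` with `β0 = -β1 · half_life` (Binomial, or
Beta-Binomial under overdispersion). `simulate_peptides()` places random
7–25-residue spans with distinct starts along a protein (default length 961,
cleavage site 541) and shifts pre-site log2 intensities by the effect size in
the mutant condition. `make_overlapping_sets()` builds gene-set fixtures with
exact cardinalities.

## Survival statistics

`normalize_day1()` rescales each genotype × replicate series by its day-1
proportion (values above 1 are allowed — later plates can beat day 1 by
sampling — and are clipped into (0,1) only inside the link evaluation).
`fit_survival()` fits a quasi-binomial logistic regression of the normalized
proportion on days of starvation, weighted by animals plated (weights are the
binomial information choice; an unweighted option exists since the assay
convention leaves this open). The half-life is `-β0/β1`, defined only for a
negative slope; flat series are flagged, not errors. Convergence is declared
at a coefficient change below 1e-8 within 100 IRLS iterations, and the
quasi-binomial dispersion is Pearson χ²/df.

One estimand subtlety: day-1 normalization divides the curve by `p(1) < 1`,
which *rescales* the half-life of a short-lived genotype (a true 3.0-day
half-life with slope −1 fits to ≈3.4 days after normalization). Recovery
experiments against generator truth therefore use
`fit_survival_all(normalize = FALSE)` (raw proportions; recovers 3.0/6.0 to
well within a quarter day), while analyses of scored data keep the
normalization default, which is the assay convention and whose half-life is
invariant to the absolute day-1 survival level.

Half-life comparisons (`compare_halflives()`) gate variance pooling on a
homogeneity test — Bartlett, or Brown–Forsythe Levene with median centering —
at α = 0.05 (the gate's α is an assumption; it is configurable), then run a
two-tailed unpaired t test, pooled or Welch accordingly. Additivity of two
mutations' effects on survival is tested by a classical two-way ANOVA with
interaction (`interaction_anova()`; Type-II sums of squares by model
comparison, identical to the textbook decomposition for the balanced designs
used here). For proportions that violate normality, `art_anova()` implements
the aligned-rank transform: align the response for one effect at a time (cell
residuals plus that effect's estimated contribution), rank with average ranks
for ties, run the factorial ANOVA on ranks, and report only the aligned
effect. Note the documented non-invariance: a nonlinear monotone transform of
the response changes the alignment, hence the ranks — ART is not a rank test
of the raw data. `kruskal_test()` and `hatch_plateau()` (earliest timepoint
at which every genotype is at its own hatching maximum, tolerance 1e-9)
complete the module.

## Gene sets and peptides

Gene sets carry an explicit background universe (`gene_set()`), read and
written as standard GMT. `independent_targets()` is the set difference of
two DEG sets — e.g. targets of one regulator not shared with another.
`hypergeom_overlap()` reports the upper-tail enrichment p
(`P(X ≥ k)`, observed overlap included) and defines depletion as its exact
complement `1 − P(X ≥ k)`. `ks_shift()` compares a set's log2 fold changes
against **all detected genes including the set** (the convention when sets
are compared "against all detected genes"; this makes the null slightly
conservative because the set is part of its own reference — an exclusive mode
is available and is what the calibration test uses).
`intersection_counts()` tallies exclusive membership patterns for up to 8
sets; the counts partition the union.

`peptide_log2fc()` uses means of raw replicate intensities before the ratio
(intensities are not counts, so no pseudocount; zero-denominator peptides are
excluded and flagged). `split_by_site()` assigns peptides ending at or
before the cleavage site to "before", starting after it to "after", and
excludes spanning peptides (counted) — the cleanest reading of a
before/after partition; coordinates are 1-based inclusive residue positions
in the native protein, and any fusion-tag offset is the caller's
responsibility. `cleavage_shift_test()` reports Shapiro–Wilk normality and a
two-sided one-sample Wilcoxon signed-rank test against zero, exact for
n ≤ 25 without ties or zeros. Test units are peptides, not
replicate-averaged fragments.

## Pipeline, seeding and numerical choices

`run_pipeline()` orchestrates the stages from a YAML/list configuration
(exactly one of a simulation block or input paths per data kind, validated
before any computation), writes per-stage TSV artifacts plus a `summary.json`
and a `manifest.json` with MD5 hashes, and removes partial outputs on
failure. All randomness flows from one integer seed; sub-streams are derived
deterministically (`derive_seed()`), so identical configuration and seed give
byte-identical summaries.

Numerical conventions collected in one place: pseudocount 0.5 before log2
CPM; proportions clipped to [1e-6, 1−1e-6] inside the logistic link; KDE
bandwidth by Silverman's rule; odds-ratio rejection strictly above 10³;
degenerate bootstrap draws (all expectations zero) retried up to 10 times
then surfaced as errors; ties get average ranks throughout; BH capped at 1.

## Validation problem sizes

The shipped checks run the generator at 2,000 genes × 3 replicates with
τ = 1 and φ = 0.1 (20 seeds per model-selection condition, 10 per recovery
value, 1,000 bootstrap draws), 50 seeds of two-genotype survival recovery,
1,000 null simulations each for the two interaction-test calibrations, and
100 seeds of peptide power — sizes chosen so the full suite completes on a
single CPU in minutes while leaving the Monte-Carlo error well inside each
acceptance band.

## Known limitations

* The predefined model set is exactly the three models above; branched
  pathways are out of scope.
* The measurement-error correction uses the reported standard errors; if
  those are systematically understated the residual attenuation of $\hat s$
  is not removed (with raw MLE fold changes it is roughly −0.1 under the
  default conditions — use the shrunken front end).
* The t-test stand-in is intentionally simple: no dispersion shrinkage, no
  GLM offsets beyond TMM, no batch correction.
* The survival module is for interval-scored proportion data; there is no
  Kaplan–Meier or Cox machinery.
* Cleavage-site *prediction* is out of scope; the site is an input
  (default 541).
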