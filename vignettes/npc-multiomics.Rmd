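---
title: "Non-parametric combination of partially paired multi-omics studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-parametric combination of partially paired multi-omics studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcomb)
library(dplyr)
```

## The problem

Clinical multi-omics studies of small cohorts often profile several related
cell populations — here, sorted CD4+ and CD8+ T cells — from overlapping but
not identical sets of donors spanning disease groups (healthy controls `HC`,
relapsing-remitting `RR`, and secondary-progressive `SP` patients). Each
dataset alone is underpowered, yet many regulatory changes are expected to be
shared between the cell types. `npcomb` implements a permutation-based
non-parametric combination (NPC) of per-dataset differential tests that

* uses **all** samples, not just the donors present in every dataset,
* preserves the cross-dataset correlation induced by shared donors when
  building the permutation null, and
* rewards features whose evidence is consistent across datasets.

Downstream stages connect the selected genes to nearby differentially
methylated CpG probes (cis expression–methylation screening around the TSS)
and test gene sets by rank.

## The NPC procedure

For each dataset $d$ and feature $g$, a linear model is fitted with
treatment-coded disease group (baseline `HC`), mean-centered age, and a male
indicator. The partial-test statistic is the partial F for the joint nullity
of the `RR` and `SP` coefficients given the covariates (2 numerator degrees
of freedom):

$$F_{g,d} = \frac{(\mathrm{RSS}^{red}_{g,d} - \mathrm{RSS}^{full}_{g,d})/2}
                {\mathrm{RSS}^{full}_{g,d}/(n_d - p)}.$$

The null is built by permuting disease labels **at the individual level**:
the observed label multiset over distinct individuals is shuffled, and each
individual's permuted label is broadcast to every sample it contributes. An
individual measured in both datasets therefore always carries one label;
an individual measured in only one dataset receives its label independently
of any particular paired individual. Covariates never move — only the
disease labels do. This is a plain label shuffle (not a resample), so each
permutation preserves the observed group sizes over individuals.

With $B$ permutations, partial p-values use the pseudocount convention

$$p_{g,d} = \frac{1 + \#\{b : F^{(b)}_{g,d} \ge F_{g,d}\}}{1 + B},$$

with ties counted as exceedances. Partial p-values are combined with the
Liptak (Stouffer) function

$$T_g = \sum_d w_d\, \Phi^{-1}(1 - p_{g,d}), \qquad w_d = 1,$$

and the same combination is applied to each permutation's own partial
p-values (each permutation scored against the full $B$-permutation pool,
itself included — standard NPC practice). The global p-value is the
pseudocount exceedance probability of $T_g$ in that null, and
Benjamini–Hochberg q-values are computed over features. Features are
selected at global $p \le 10^{-3}$ and $q \le 0.1$ for expression, and
$q \le 0.2$ for methylation — the conventional thresholds for these two
modalities; both are plain arguments.

The Liptak function reinforces features supported by several datasets and
penalizes those significant in only one, which is the behaviour the
direction-group stage makes visible: selected features whose per-contrast t
statistics share signs across datasets fall into the four concordant
patterns `G1` (+,+), `G2` (+,−), `G3` (−,+), `G4` (−,−) over the
(`HC-RR`, `RR-SP`) contrasts, and everything discordant (or with an exactly
zero t) is `G5`.

### Design choices that were genuinely open

* **One 3-group model, not per-contrast models.** The permutation shuffles
  all three labels jointly, and the combined output is a single global
  p-value without direction; per-contrast t statistics from the same fit
  supply direction afterwards.
* **Covariates are not refitted or permuted.** Labels move, samples (and
  their age/sex) stay. A Freedman–Lane-style residual scheme was considered
  and rejected for the default because the plain label shuffle matches the
  stated procedure and keeps the null exact for exchangeable labels.
* **Variance moderation is off by default.** Permutation nulls are valid
  without shrinkage; enabling `moderate = TRUE` applies scaled-inverse-
  chi-square empirical Bayes (method of moments on $\log s^2$, trigamma
  inversion) inside every permutation, approximating a moderated-F
  analysis.
* **Equal Liptak weights.** Nothing in the two-dataset setting motivates
  unequal weights; they are exposed as an argument.
* **Default `B = 1000`.** The smallest attainable global p is
  $1/(B+1) \approx 0.001$, exactly at the expression selection threshold;
  smaller `B` makes that threshold unattainable.

### Numerical conventions

* Exceedance counts use a **relative tolerance of 1e-6**: permutations that
  are mathematically tied (label assignments spanning the same group
  subspace always give the same F) must count as ties regardless of the
  floating-point path, and near-degenerate statistics (residual sums of
  squares close to zero suffer catastrophic cancellation) agree across
  algebraically equivalent computations only to about 1e-9 relative. The
  tolerance sits far below any genuine gap between distinct permutation
  statistics of continuous data; counting in the tie direction is
  conservative.
* A feature whose group sum of squares is zero up to floating residue has
  **F defined as 0**, even when the residual variance is also zero.
* Before the normal quantile, p-values are clipped to
  $1 - 1/(2(B+1))$ so $T$ stays finite.
* Observed and permuted F statistics share one code path
  (Frisch–Waugh residualization against the fixed covariates, rank-safe QR
  so a degenerate permuted labeling cannot crash a run).

## The synthetic study generator

The generator produces the study structure the method assumes, plus ground
truth, so every stage is testable without any download.

* **Design**: three groups (defaults 10 `HC`, 10 `RR`, 8 `SP`), two
  datasets (`CD4`, `CD8`), a configurable paired fraction (default 0.7)
  applied per group with rounding; unpaired individuals are split across
  datasets as evenly as possible at random. Ages are uniform per group
  (`SP` shifted older, 35–65 vs 25–55), sex is Bernoulli with a 0.65
  female share — typical of autoimmune cohorts dominated by female
  patients.
* **Expression**: negative-binomial counts (dispersion 0.05, library sizes
  0.8–1.2 million reads, per-gene mean CPM log-uniform in 10–1000) under a
  log-linear model with monotone disease-stage shifts for DE genes, small
  per-gene age and sex effects, and a per-individual random effect shared
  across datasets for paired individuals. The individual effect's scale is
  set so it carries about 30% of the non-group log-scale variation — this
  is the mechanism behind the cross-dataset correlation that the pairing
  constraint preserves. Counts convert to log2 CPM; genes not exceeding
  1 CPM in every sample are dropped and reported.
* **Methylation**: Gaussian M-values (bimodal baseline, i.e. clearly
  methylated or unmethylated probes) with the same effect structure,
  transformed to betas by the inverse logit2 and clipped strictly inside
  (0, 1).
* **Cis links**: a planted promoter probe (within 1500 bp of the
  strand-aware TSS: `+` strand start, `-` strand end) has its M-value
  coupled to the *realized* standardized expression of its gene within each
  dataset. The loading is chosen from the target Spearman correlation via
  the bivariate-normal relation $r = 2\sin(\pi\rho/6)$, which controls the
  attained correlation exactly regardless of the expression noise level.
  The default target is $\rho = -0.9$, the strong promoter
  anti-correlation regime the overlap stage is meant to detect.
* **Seeding**: a master seed spawns independent per-stage substreams, so
  adding a stage never perturbs earlier draws, and equal seeds reproduce
  matrices byte-identically.

What the generator does **not** emulate: batch and chip effects,
normalization artifacts (the upstream CQN/BMIQ/ComBat pipeline is out of
scope), linkage disequilibrium or co-methylation blocks, count-level
library-preparation biases, or trans effects. Passing tests therefore
demonstrate the statistical machinery under the assumed sampling structure,
not robustness to those real-data complications.

## Cis overlap and enrichment

Selected genes and probes are paired when on the same chromosome with
$|\text{probe} - \text{TSS}| < 1\,\text{Mb}$ (strictly less; coordinates
are 0-based half-open internally and written 1-based inclusive). For each
pair and dataset, Spearman correlation is computed across the samples
shared between the two modalities (matched by individual), pooling all
disease groups. P-values use exact rank-permutation enumeration for
$n \le 7$ and the t-approximation above that (enumerating $n!$ orderings
is infeasible past that point at pair-list scale; the screening sample
sizes of interest are $n \ge 15$ where the approximation is accurate).
Pairs with $|\rho| > 0.5$ and $p < 0.05$ are ranked by p per dataset, and
the intersection across datasets is reported. Correlation uses beta values
and log2 CPM; being rank-based, the choice of methylation scale (beta vs
M) does not affect $\rho$.

Gene-set enrichment ranks genes by a per-gene score (a p-value from either
a per-dataset analysis or the NPC global output), restricts each set to
the analyzed universe, drops sets smaller than 20 or larger than 200, and
applies a one-sided Wilcoxon rank-sum test of the set against its
complement, with BH q-values over sets. The test is invariant under any
strictly monotone transform of the scores.

## A worked run

```{r example, eval = FALSE}
st <- simulate_study(
  n_genes = 1000, n_probes = 500, n_cis_pairs = 10,
  expr_spec = expression_spec(n_de = 40, effect_size = 1),
  seed = 1
)
res <- npc_global(st$expression, st$design, B = 1000, seed = 1)
glance(res)
sel <- select_features(res, p_max = 0.001, q_max = 0.1)

pairs <- pair_within_distance(sel, rownames(st$methylation$CD4$values),
                              st$annotations)
corr <- correlate_pairs(pairs, st$expression, st$methylation, st$design)
rank_and_intersect(corr)
autoplot(res)
```

The configuration-driven runner `run_pipeline(pipeline_config(...), dir)`
chains the same stages, writes per-stage TSVs (each carrying a config-hash
comment), a JSON manifest and a log, and reproduces its outputs
byte-identically for a fixed configuration.

## Validation strategy and problem sizes

The test suite validates the pipeline on sizes chosen to make the
statistical checks sharp while staying comfortable on a laptop:

* exhaustive-permutation exactness on a 6-individual fully paired design
  (90 distinct label assignments) against a brute-force `lm()`-based
  enumeration written independently of the package machinery;
* type-I calibration and KS uniformity of global p-values on a global-null
  study of about 2000 genes at `B = 500`;
* the identity that two duplicated, fully paired datasets reduce NPC to
  the single-dataset partial test within permutation granularity;
* recovery of 150 shared DE genes among 5000 at log2 effect 1.0 over ten
  seeds, compared against each single-dataset analysis and against a
  paired-only reanalysis at matched thresholds;
* recovery of planted promoter pairs (target $\rho = -0.9$, 25 shared
  samples) across 200 seeds, with a no-link null control;
* elementary oracles: normal-equations OLS, full-vs-reduced F, contrast
  t, the double-loop BH definition, the Spearman rank formula, and
  hand-computed Liptak values.

## Known limitations

* The partial statistic is a homoscedastic OLS F; precision weights
  (voom-style) and within-individual duplicate correlation are not
  implemented.
* Exact permutation Spearman p-values are only enumerated up to $n = 7$.
* With `B` permutations the smallest attainable global p is $1/(B+1)$;
  selection thresholds below that are unattainable by construction.
* The generator's independence across features means feature-level
  dependence (co-expression, co-methylation) is not represented; BH
  behaviour under strong dependence is not exercised.
* Only complete matrices are supported; missing values must be handled
  upstream.
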