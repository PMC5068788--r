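---
title: "Constrained PLS discriminant analysis for confounded LC-MS studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained PLS discriminant analysis for confounded LC-MS studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocplsda)
```

## The problem

Small untargeted metabolomics cohorts — here the motivating case is
amniotic-fluid profiling with 10–13 subjects per clinical group and
1400–1800 LC-MS features per ionization mode — are vulnerable to
confounding: clinical covariates (maternal age, BMI, therapies, gestational
age at sampling, newborn sex) may differ between groups and drive apparent
metabolic separation. `ocplsda` implements a discriminant workflow whose
latent structure is constrained to be orthogonal to those covariates, so a
discriminating component cannot be a covariate effect in disguise, together
with the validation and marker-selection machinery such a claim requires.

## Model

Let $X$ be the pretreated $n \times p$ feature matrix, $Y$ the
column-centered $n \times 2$ class-indicator matrix, and $Z$ the
column-centered $n \times c$ matrix of encoded constraint covariates.
Components are extracted as in NIPALS PLS2, except that each weight vector
is projected onto the null space of $K_a = Z^\top E_a$ before use
($E_1 = X$, $F_1 = Y$):

$$w_a \propto \text{dominant left singular vector of } (I - K_a^{+}K_a)\,E_a^\top F_a, \qquad t_a = E_a w_a,$$

with the usual loadings $p_a = E_a^\top t_a / t_a^\top t_a$,
$c_a = F_a^\top t_a / t_a^\top t_a$ and deflation of both blocks.
Because $w_a \in \mathrm{null}(Z^\top E_a)$, the scores satisfy
$Z^\top t_a = 0$ *by construction*, and the package verifies
$\max_a |Z^\top t_a| \le 10^{-8}\,\lVert Z\rVert\,\lVert t_a\rVert$ for
every fit, including every cross-validation and Monte-Carlo refit
(violations are carried outward as `max_constraint_violation`). With $Z$
empty the algorithm reduces exactly to PLS2-DA; the test suite checks this
equivalence against a brute-force eigendecomposition oracle.

Two design points were genuinely open:

* **Where to constrain.** We project in weight space
  ($w \in \mathrm{null}(Z^\top E)$) rather than pre-projecting the samples
  of $X$. This keeps scores as linear combinations of the actual training
  data and makes the orthogonality property explicit and testable; the
  invariant $Z^\top T = 0$ is the acceptance surface either way.
* **Deflation.** Both $X$ and $F$ are deflated per component (standard
  PLS2). The single-feature and full-rank limits then coincide with ordinary
  least squares, which the tests exploit as closed-form oracles.

Coefficients are $B = W(P^\top W)^{-1}C^\top$ and predictions for pretreated
new samples are $\hat Y = X_{new}B$ plus the training response means; the
class call is the argmax of the two response columns.

### Post-transformation

To report a fitted $A$-component model as "$A_{pred} + A_{orth}$", the
component basis is rotated by $G$, the full orthonormal left singular basis
of $T^\top Y$. The first $A_{pred} = \mathrm{rank}(T^\top Y)$ rotated
components carry all the response correlation (for a two-class centered $Y$,
$A_{pred} = 1$); the trailing rotated scores are *exactly* uncorrelated with
$Y$. The rotation leaves $\hat Y$, $B$ and the reconstruction $T P^\top$
unchanged to $10^{-10}$, which the suite asserts. One necessary trade-off:
after rotation the score columns are no longer mutually orthogonal (an
orthonormal rotation cannot preserve the diagonality of $T^\top T$ when the
score variances differ), and the rotated Y-loadings $CG$ have numerically
small rather than identically zero trailing columns. Exact zero loadings and
exact score–response orthogonality cannot both hold; we chose the latter,
which is the substantive OPLS-style claim.

Weight-vector signs are fixed so each vector's largest-magnitude element is
positive, making reports reproducible across platforms.

## Pretreatment

Default: natural-log transform, mean centering, Pareto scaling (divisor
$\sqrt{s_j}$ for feature standard deviation $s_j$) — the field-standard
recipe for electrospray peak intensities, fully configurable via
`pretreat_spec()`. Zero-variance features get divisor 1 and a warning.
Pretreatment statistics are *always* fitted on training samples only and
applied unchanged to held-out samples; the suite checks that spiking a
held-out outlier cannot move training statistics. Binary covariates are
encoded 0/1 and centered; "previous miscarriages" is treated as a count;
constant covariates are dropped with a warning.

## Validation

**Cross-validation** is "full": within each class-stratified fold the
pretreatment, the constraint centering and the model are refit from scratch
on the training part, and $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ accumulates
held-out squared error, with TSS referenced to the *training-fold* response
means (consistent with the no-leakage reading; the difference from a global
reference is tiny). Fold counts 6, 7 and 8 are evaluated by default. An
independent explicit-loop implementation reproduces the engine to
$10^{-10}$ in the tests.

**Permutation test.** Class labels are permuted uniformly with $X$ and $Z$
fixed; the full cross-validated $Q^2$ (7 folds by default) is recomputed per
permutation, and $p = (\#\{Q^2_{perm} \ge Q^2_{obs}\} + 1)/(n_{perm}+1)$,
so the smallest attainable p-value is $1/(n_{perm}+1)$. Two empirical
properties of the null are worth knowing. First, the null $Q^2$ distribution
at these sample sizes is broad: on pure-noise data ($n = 24$, $p = 200$, one
component, 7 folds) it has mean $\approx -0.10$ but roughly a third of its
mass above zero, with occasional values above $0.2$. A positive $Q^2$ alone
is therefore weak evidence; the permutation p-value is the calibrated
statement, and the suite verifies its uniformity under the null. Second,
$Q^2 \le R^2$ is a reliable empirical regularity for unconstrained fits
(where the full fit can overfit at will) but is **not** guaranteed for
constrained fits: when constraints suppress overfitting, cross-validated
prediction can marginally beat the training fit. The suite asserts
$Q^2 \le R^2$ for unconstrained fits only.

**ROC.** The AUC uses the exact midrank Mann-Whitney identity (ties count
one half) — the tests require bit-exact agreement with pair counting — and
the 95% CI uses DeLong's method (via pROC), truncated to $[0,1]$ and
collapsed to the point AUC in degenerate cases. The reported operating point
is the score cutoff closest to the top-left corner of the ROC plot
(minimizing $(1-Se)^2 + (1-Sp)^2$), with ties broken toward higher
sensitivity. Cross-validated ROC uses the held-out predicted case-response
column.

**Screens.** `confounding_screen()` fits PCA (with per-PC class t-tests) and
a PLS-DA with the metadata as the X-block; "no confounding" is declared when
the metadata PLS-DA 7-fold $Q^2 \le 0$. `external_factor_check()` reports
the point-biserial correlation (and t-test p-value) between the first
predictive score and an external binary factor such as the presence of
chorioamnionitis.

## Monte-Carlo stability selection

Each of `n_subsets` (default 200) subsets includes every sample
independently with probability 0.70 — the literal reading of Monte-Carlo
sampling "with prior probability 0.70"; a fixed-fraction variant is
available behind `fixed_fraction = TRUE`. Draws leaving fewer than three
samples in either class are redrawn, a guard that keeps subset fits sane. Per subset the whole pipeline is refit at the same component
count, the excluded samples are predicted and scored by ROC, and the 50
features with the largest $|b_j|$ for the case-response column are selected.
Selection frequencies divide by the number of *successfully fitted* models;
the final panel applies the strict rule "selected in **more than** 90% of
models", so a feature at exactly the threshold is excluded (the suite pins
the 180/200 boundary).

Two behaviors of this procedure deserve emphasis, both measured with the
package's own generator:

* **Recall rises steeply with effect size.** With 20 planted markers among
  500 features at $n = 24$, the strict panel recovers only ~20–50% of
  markers at a standardized shift of 1.5, ~50–80% at 2.0, and essentially
  all markers by 3.0. The rule is built for precision (false panels were
  $\le 5$, usually 0, in all experiments), not sensitivity.
* **The panel is not a dataset-wise null filter.** Subsets drawn at
  inclusion 0.70 share ~70% of their samples, so per-subset rankings are
  strongly correlated within a dataset: a noise feature that happens to look
  strong in the full dataset tends to stay in the top 50 across most
  subsets. On pure-noise data, panels of 2–6 features occur in roughly half
  of datasets. Stability selection controls *selection stability within a
  dataset*; dataset-level error control comes from the permutation test.
* **Constraint count trades against subset size.** Constraining ~17-sample
  subsets on nine covariates leaves roughly seven usable score dimensions
  and visibly destabilizes the rankings (markers plateau near 85%
  frequency); with three covariates the same markers reach 93–100%. In
  small studies, constrain on the covariates of genuine concern rather than
  everything recorded.

`recovery_experiment()` packages the key demonstration: with a covariate
that both drives features and correlates with class (association 0.6),
confounder-driven features are selected by unconstrained PLS-DA at mean
frequencies near 1.0 and suppressed below 0.05 by the constrained model — a
drop of ~0.9, far beyond the 0.2 the workflow requires.

## Univariate complement and annotation

`univariate_scan()` applies a Welch t-test per feature (the safer default
for heteroscedastic intensities; the pooled-variance Student test is a
flag), Benjamini-Hochberg q-values with the significance flag at $q < 0.20$,
and per-feature ROC with DeLong CIs. Tests run on the log scale for
consistency with the multivariate block.

Annotation is deliberately minimal mass arithmetic: $[M+H]^+$ adds and
$[M-H]^-$ subtracts one proton (1.007276 Da; the electron mass is
neglected, well under 1 ppm at these masses), the signed error is
$10^6(\text{obs}-\text{theo})/\text{theo}$, and matching accepts candidates
within a default 10 ppm. Monoisotopic masses are computed from C/H/N/O/P/S
formulas with IUPAC atomic masses. The bundled table carries the putative
amniotic-fluid metabolites; entries known only at the metabolite-class level
("amino acid chain", "sulphated steroid", "dicarboxylic unsaturated fatty
acid", "hydropyridine") have no formula and are excluded from mass matching
and round-trip tests, and the phosphatidylcholine entry is a synthetic
exemplar (an ether PC consistent with the observed m/z). Retention time is
carried through but never used for matching.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: two groups (default 12+12;
unbalanced via `c(13, 11)`), log-normal intensities (Gaussian on the log
scale with feature baselines $\mathcal{N}(7, 1.5)$ and residual SD 0.5,
exponentiated — the standard model for ESI peak areas), marker features
shifted by `marker_effect` residual SDs on the log scale, covariate-driven
features regressing on a standardized maternal-age covariate drawn with a
chosen correlation to class membership, and a metadata table mirroring the
study covariates (age, BMI, miscarriage count, four therapy flags,
gestational age 21–28 weeks, sex). No missing values by default; a
left-censoring switch exists but is off, since intensity missingness is a
separate modelling question. What the generator does *not* emulate — and
what passing tests therefore do not establish about real data — includes
correlated feature blocks (real adduct/isotope families move together),
retention-time drift, batch effects, heavy-tailed intensity noise, and
covariate effects on more than one latent direction.

## Numerical choices and problem sizes

Component extraction stops early (with a warning, returning fewer
components) when the residual covariance singular value falls below
$10^{-10}$ of the initial block scale, or when a score norm degenerates;
constraining directly on the class response annihilates all response
covariance and correctly yields a zero-component model. Constraint blocks
are checked for rank after centering (dependent columns are an error at fit
time; inside resampling loops degenerate columns are dropped silently, since
subsets can make a covariate constant). The component count is a user input;
the reference analyses use 3 components read as "1+2" after
post-transformation.

The simulation sizes used by the test suite — e.g. 200 null datasets of
$24 \times 200$ with 99 permutations for the calibration check, 100
Monte-Carlo subsets at $p = 500$ for recovery, 10 seeds for the
confounder-suppression comparison, and a 1369-feature study-like dataset in
`scripts/acceptance.R` — were chosen as the smallest sizes at which the
distributional claims above are stable across reruns. The acceptance script
uses a strong marker effect (2.5 SD) so that the strict >90% panel is
exercised with non-degenerate output; weaker effects legitimately produce
empty panels, as discussed above.

## Known limitations

Only two-class problems are supported (by design); there is no
hyperparameter search for the component count; bootstrap ROC intervals are
not implemented (DeLong only); annotation does no isotope-pattern or MS/MS
scoring and queries no online databases; and the generator's independence
assumptions above mean real-data performance claims still require real data.
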