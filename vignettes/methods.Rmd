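---
title: "Methods: principal component scores of glucose homeostasis from the OGTT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: principal component scores of glucose homeostasis from the OGTT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttpcs)
```

This vignette documents the model behind the package: how the principal
component scores (PCS) are constructed, which glucometabolic indices are
computed and under which conventions, how the synthetic cohort generator is
built and calibrated, and which numerical and statistical choices were made
where the underlying methodology leaves freedom. Default problem sizes used
throughout (cohort sizes, tree counts, imputation counts) are this package's
own choices, selected so every check runs in minutes on one CPU.

## 1. Data model

One observation is a *subject-visit*: a 2-hour, 75 g oral glucose tolerance
test (OGTT) with glucose (mg/dl), insulin (µU/ml) and C-peptide (ng/ml)
sampled at minutes 0, 30, 60, 90 and 120, plus age (years) and BMI (kg/m²).
Visits are labelled `V1` (early gestation), `V2` (24–28 weeks) and `V3`
(post partum). Other units are supported through `unit_policy()`; every
index converts its inputs once, centrally, to the units its formula is
defined in.

## 2. Score construction

The 17 features are the 15 timed measurements plus age and BMI
(`feature_columns()`). Before standardization each variable is transformed
toward symmetry:

* insulin and BMI: natural logarithm,
* C-peptide: square root,
* glucose and age: identity.

`build_feature_matrix()` applies the transforms and standardizes each column
(z-scores), either against the cohort itself ("self-standardized") or against
externally supplied means/SDs (`read_standardization()`). With a loading
matrix $V$ (17 × 3), scores are the projection $S = A V$ and the rescaled
scores are

$$\mathrm{PCS}_k = \frac{S_k + 100}{17},$$

so a subject at the standardization means scores exactly $100/17 \approx
5.882$ on every component.

`derive_loadings()` obtains $V$ as the top eigenvectors of the feature
correlation matrix (eigendecomposition of $A^\top A/(n-1)$). Eigenvectors
are sign-indeterminate, so the package fixes orientation **semantically**
rather than by the common "largest loading positive" rule:

* component 1: fasting-insulin loading negative (higher PCS1 = more insulin
  sensitive),
* component 2: 60-minute glucose loading positive (higher PCS2 = more
  post-load glycaemia),
* component 3: fasting-insulin loading positive (higher PCS3 = more fasting
  insulin resistance),
* any further component: largest-magnitude loading positive.

The semantic anchors were adopted after the magnitude rule proved unstable in
simulation: it oriented the third component *against* the fasting insulin
resistance axis it summarizes, flipping the sign of its association with the
disposition index. With the anchors, the expected correlation directions
(PCS1 with insulin sensitivity, PCS3 with fasting insulin resistance) hold by
construction.

Loadings and standardization tables round-trip through plain CSV
(`write_loadings()`, `read_loadings()`), with eigenvalues carried in a
comment line so externally supplied loading files without eigenvalues remain
valid.

## 3. Glucometabolic indices

`compute_panel()` evaluates, per subject-visit:

* **Fasting sensitivity**: HOMA-IR $= G_0[\mathrm{mmol/l}] \cdot I_0 / 22.5$;
  QUICKI $= 1/(\ln G_0 + \ln I_0)$ with natural logarithms (values around
  0.17, not the 0.3–0.4 of the decadic variant).
* **Dynamic sensitivity**: the Matsuda index
  $10000/\sqrt{G_0 I_0 \bar G \bar I}$ over all five samples; the 2-hour
  OGIS surrogate of glucose clearance (ml·min⁻¹·m⁻²), using the published
  constants for the 75 g/120 min variant; the Stumvoll demographic
  regressions (MCR, ISI) which take insulin in pmol/l and glucose in mmol/l.
* **Secretion**: insulinogenic ratios — early
  $(I_{30}-I_0)/(G_{30}-G_0)$, late and total as insulin/glucose AUC
  ratios; the Stumvoll first- and second-phase regressions; and the
  C-peptide-derived total insulin secretion (below). A flat 0–30 min
  glucose increment makes the early ratio undefined; it is returned as `NA`
  with an explicit flag, never silently dropped.
* **Disposition**: ISSI-2 $=$ Matsuda × total insulinogenic ratio, an exact
  identity the tests enforce to 1e-12.
* **Classification**: `classify_gdm_iadpsg()` applies the IADPSG thresholds
  (fasting ≥ 5.1, 1 h ≥ 10.0, 2 h ≥ 8.5 mmol/l, inclusive); a missing
  sample yields `"unknown"` unless another sample already crossed a
  threshold.

### C-peptide deconvolution

Insulin secretion rate (ISR) is reconstructed from peripheral C-peptide with
a two-compartment model under population kinetic constants for normal
adults: biexponential disposal with half-lives 4.95 and 33 minutes (fast
fraction 0.76) and a central distribution volume affine in body surface
area, $V_d = 1.92\,\mathrm{BSA} + 0.64$ litres. The half-lives are converted
to the rate constants $k_{01}, k_{12}, k_{21}$; the peripheral pool is
integrated on a 0.25-minute grid with exact exponential steps; time
derivatives of the central concentration use piecewise-linear slopes. At a
constant concentration the implementation reduces exactly to the steady
state $\mathrm{ISR} = k_{01} V_d C$, which is the main unit test oracle.
Total insulin secretion (TIS) is the trapezoid integral of ISR over 0–120
min, reported per m² BSA by default.

Beta-cell glucose sensitivity and rate sensitivity are *regression
surrogates* (slope of ISR on concurrent glucose; early incremental ISR per
early rate of glucose change), not fits of a full dose–response model, and
are labelled as such.

## 4. Synthetic cohort generator

Real OGTT cohorts of this kind are confidential, so the package ships a
generator whose marginals are calibrated to a published-style pregnancy
study sample (67 women, attrition to 57 at `V2` and 23 at `V3`, a small GDM
minority of about 9%). The generator exists to make the pipeline testable;
it is not a physiological simulator.

Each subject carries three lognormal latent traits:

| latent | meaning | default SD (log) |
|---|---|---|
| `si` | peripheral insulin sensitivity | 0.45 |
| `beta` | beta-cell secretory function | 0.45 |
| `hf` | fasting/hepatic insulin-resistance axis | 0.50 |

$\log si$ and $\log \beta$ are bivariate normal with correlation −0.3
(compensation: poorly sensitive subjects tend to secrete more); `hf` is
independent. The product $si \cdot \beta$ (the disposition) drives the
glucose excursion.

Per visit, curves are built around target mean curves that carry the
population pregnancy effects (higher glycaemia at `V2`, higher fasting
glucose post partum):

* glucose: $g_0 \cdot e^{-0.12 d + 0.08\log hf + \varepsilon}$ plus the
  target excursion scaled by $e^{-0.7 d + \varepsilon}$, where
  $d = \log si + \log\beta$; every lognormal factor is analytically
  mean-centred so population means match the targets up to Monte Carlo
  error;
* insulin: $\exp(\text{target log-insulin} + 0.6\log\beta - 0.4\log si +
  1.1 w_t \log hf + 1.5 \log(g/\bar g) + \varepsilon)$, where the weights
  $w = (1, 0.15, 0.05, 0.05, 0.05)$ confine the fasting axis mostly to the
  basal sample;
* C-peptide: the secretion signal smoothed with an exponential kernel of
  time constant 60 min (its slower peripheral kinetics), scaled to the
  target curve.

Noise has subject-level ("trait") and occasion-level components: 75% of the
excursion-amplitude noise variance and 60% of the basal-glucose noise
variance are stable within subject. Without this split, independent
per-visit noise inflated both the fasting-glucose SD and the fraction of
subjects crossing a diagnostic threshold at *either* prepartum visit; with
it, the realized GDM fraction settles near the ~9% design target.

The third latent (`hf`) was added after an earlier two-latent design left
the third principal component as uninterpretable noise (its eigenvalue sat
at ~1, the level of a standardized singleton). A dedicated fasting axis
gives component 3 a physiological identity and realistic fasting-insulin
dispersion.

GDM labels are **not** drawn directly: they emerge from applying the IADPSG
thresholds to the generated prepartum curves, so the realized fraction
(attached as an attribute) is an emergent property. Parity, family history
(with one missing value per ~67 subjects) and GDM history are generated
with realistic frequencies; a history of GDM is only possible in multiparous
women and is enriched at low disposition.

`inject_missingness()` blanks a fixed number of *post-load* measurement
cells completely at random — fasting samples and covariates are never
blanked, which keeps every conditional imputation model well-posed.

All randomness flows from a single integer seed; generation restores the
caller's random stream afterwards.

## 5. Imputation

`impute_chained()` is a self-contained implementation of multivariate
imputation by chained equations: each incomplete measurement column is
regressed on all other measurements plus age and log-BMI *on the transformed
scales* (log insulin, square-root C-peptide), missing entries are replaced
by draws from the conditional normal predictive distribution (or by
predictive-mean-matched donors), sweeps are iterated (default 5), and the
procedure is repeated for `m = 50` completed data sets whose average fills
each cell. Observed cells are never altered — the tests check this bitwise.

## 6. Analysis stage

* Welch's unequal-variance t-test with Satterthwaite degrees of freedom,
  computable from raw samples or from printed group summaries (both routes
  agree to 1e-12).
* Pearson chi-squared **without** continuity correction, because the
  reference contingency p-values are only reproduced uncorrected, and
  Fisher's exact test — the multiparous GDM-history comparison is only
  reproduced by the exact test, a documented method/value mismatch in the
  source tables.
* Univariable logistic regression for GDM with profile-likelihood 95%
  intervals; odds ratios are reported per 0.01 score units. Quasi-complete
  separation is detected and flagged rather than crashing.
* Random-forest permutation importance (unscaled mean accuracy decrease)
  with CART forests; only the importance *ranking* is treated as
  meaningful, since absolute importances depend on algorithm and data. The
  default is 10⁴ trees; desk-scale checks use 2000.
* ISSI-2 regressed on PCS1–3 by OLS (raw response by default, log
  optional, since the appropriate response scale is not fixed by the
  methodology).
* Visit effects per score via a random-intercept linear mixed model, REML
  estimates with a maximum-likelihood likelihood-ratio test for the global
  visit effect.

`run_pipeline()` chains simulate/load → impute → indices → feature matrix →
loadings → scores → analysis, writes every stage artifact (CSV/JSON) and a
log with seeds and row counts, and is checksum-reproducible under a fixed
seed.

## 7. Worked example

```{r example}
co <- generate_cohort(generator_config(n_subjects = 200, seed = 7))
A  <- build_feature_matrix(co)
L  <- derive_loadings(A)
sc <- project_scores(A, L)
round(sum(L$eigenvalues[1:3]) / 17, 3)           # top-3 variance fraction
pan <- compute_index_panels(co)
cor(sc$PCS[, 1], pan$matsuda, method = "spearman")
```

## 8. Limitations

* The generator matches marginal means/SDs and qualitative contrasts; it
  does not emulate within-subject correlation beyond what the latent traits
  and trait-like noise imply, nor ethnicity, fetal outcomes, or treatment.
* Glucose sensitivity/rate sensitivity are regression surrogates of
  model-based beta-cell parameters.
* The C-peptide kinetic constants are population values for normal adults;
  no individual kinetic adjustment beyond BSA is attempted.
* Loading matrices derived from synthetic cohorts are *not* the original
  study eigenvectors; externally supplied loadings are treated as opaque
  inputs (score orthogonality is then not guaranteed and is reported as
  not applicable).
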