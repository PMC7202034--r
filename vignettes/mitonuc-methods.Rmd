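---
title: "mitonuc: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitonuc: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators emulate, the numerical conventions, and where we made judgment
calls.

## 1. Closed-flow respirometry

A sample is a sealed 10 mL syringe of flies incubated 60–80 minutes; the
analyzer reports fractional O2 and CO2 concentrations of the excurrent
stream at mass flow rate `FRe` (mL/min, STP). Volumetric rates are

$$\dot{V}_{O_2} = FR_e\,\frac{(F_iO_2 - F'_eO_2) - F'_iO_2\,(F'_eCO_2 - F_iCO_2)}{1 - F'_iO_2},
\qquad
\dot{V}_{CO_2} = FR_e\,\frac{(F'_eCO_2 - F_iCO_2) + F_iCO_2\,(F_iO_2 - F'_eO_2)}{1 + F_iCO_2}.$$

Assumptions: incurrent air is scrubbed of CO2 and water vapor, so
`FiO2 = F'iO2 = 0.2094` and `FiCO2 = 0`, under which the formulas collapse
to the familiar simplified forms (`VCO2 = FRe * F'eCO2`). The respiratory
quotient RQ = VCO2/VO2 is defined only for VO2 > 0. We do not model
instrument lag or drift correction of raw traces, nor water-vapor dilution
beyond the water-vapor-free assumption — the package starts from integrated
fractional concentrations.

Total O2 consumed over an incubation can come either from pre-integrated
concentrations (primary path: `VO2 * incubation_min`) or from a simple
closed-chamber inversion with configurable chamber volume (default 10 mL,
the syringe size; the injected bolus is 5 mL). The instrument's
peak-integration constant is not published, so the closed-chamber model is
one defensible reading, used by the simulator, and both paths share the
printed equations.

Rates are adjusted per fly (post-assay head count — flies die or escape)
and per hour, then **normalized within block** to the first acquisition of
the reference cell (default strain OreR, genotype w1118, standard
treatment; per-strain resolution is available for wildtype-only designs).
"First" is the smallest acquisition index. We read "standard units" as a
ratio to the reference, not a z-score: an intercept sum of squares near 170
with ~260 observations of mean ≈ 1 (published omnibus table) is consistent
only with the ratio reading. Normalization makes the reference exactly 1,
preserves within-block ordering, cancels any multiplicative block factor
(instrument sensitivity, that day's cohort), and leaves RQ invariant.

## 2. The statistics layer

**Influence filtering.** The full factorial OLS model (K = 3 explanatory
variables) is fit and observations with Cook's distance above
`2 * 4/(N - K - 1)` are flagged and removed, with the report retaining
every distance. Note a genuinely Gaussian dataset of n = 200 typically has
~2–3 points above this doubled cutoff — the rule is a pragmatic trimming
device, not an outlier *test* — which is why our "clean fixture loses
nothing" tests use bounded noise, where zero removals hold by construction.

**Gated two-group tests.** Normality is assessed on pooled group-centered
residuals (the model's requirement, not the raw pooled data — raw pooling
would conflate a mean shift with non-normality); homoscedasticity by the
Brown–Forsythe (median-centered) Levene variant, the common default of the
implementation the analysis tradition uses. Routing: both gates pass
(Shapiro p > 0.05, Levene p > 0.1) → classical OLS/ANOVA F; normal but
heteroscedastic → HC4; "profoundly non-normal" → Wilcoxon. We
operationalize "profoundly" as Shapiro p ≤ 0.05 since no second threshold
is published. For two groups the OLS F and t are the same test; we fit the
OLS form with an F/t duality check in the suite. The Wilcoxon is
two-sided, exact for tie-free samples of ≤ 20 per group, otherwise the
normal approximation with continuity correction (mid-ranks for ties).

**HC4.** The sandwich covariance uses per-observation weights
$e_i^2/(1-h_i)^{\delta_i}$ with $\delta_i = \min(4, N h_i / p)$, which
discounts high-leverage residuals more aggressively than HC0–HC3 —
appropriate for small in-vivo datasets with occasional leverage. Inference
is a two-sided t with N − p df. Under equal leverage and equal-magnitude
residuals it reduces to a scalar multiple of the classical covariance; its
type-I error under a heteroscedastic null is verified at α = 0.05 within
[0.035, 0.065] over 2,000 replicates.

**Multiplicity.** Holm's step-down: sort ascending, multiply the i-th
smallest by (m − i + 1), enforce the running maximum, cap at 1. Families
are declared, not inferred — the published comparison table only
reproduces under its visible blocks (one family of 16 strain-level
contrasts, five per-strain triplets, one family of 12 species-pooled
contrasts), and the package defaults mirror that structure while remaining
config-driven.

**Effect sizes.** Hedges' g uses the pooled SD and J = 1 − 3/(4(n_a+n_b) − 9);
magnitude labels at |g| < 0.2 / 0.5 / 0.8. For the Type-III table (sum-to-zero
contrasts; marginal SS by removing each term's columns from the full
model), with T the total SS over **all** rows — intercept and residuals
included — and MSe the residual mean square:

- η² = SS/T and ω² = (SS − df·MSe)/(T + MSe). Including the intercept in T
  is unusual but is the only convention that reproduces the published
  columns (0.60305/174.674 = 0.00345); we document it prominently rather
  than silently normalize differently.
- partial η² = SS/(SS + SS_res); Cohen's f = sqrt(pη²/(1 − pη²)).
- partial ω² = (SS − df·MSe)/(SS + (N − df)·MSe) with **N = sum(df) + 1**
  (= 261 for the published table). A natural alternative, N = residual df +
  parameter count = 260, does not reproduce the published numbers; the
  +1 convention comes from the effect-size package lineage the analysis
  used, and we follow the numbers.
- power is the noncentral-F tail beyond the α = 0.05 critical value with
  λ = f²·(df_term + df_resid + 1). This is the classic `pwr` convention;
  λ = f²·N does not match the published power column (0.0803 vs the
  printed 0.07948 for the genotype row), λ = f²·254 does to ~5 decimals.

## 3. KA/KS

Coding sequences are threaded through the protein alignment (gap → `---`,
exact translation required; terminal stops trimmed; sequences with
internal stops or frame problems are dropped with a warning). For a pair,
only codon columns ungapped and unambiguous in both rows are compared.

Each codon position is classed by its synonymous single-nucleotide
neighbors under the standard genetic code: 3 of 3 synonymous → fourfold,
at least one → twofold (threefold sites such as Ile-3 are conventionally
twofold), none → nondegenerate. Changes to stop codons never count as
synonymous. The classes derive from the code itself, not from the
illustrative amino-acid list sometimes quoted (which omits fourfold boxes
like Ser/Thr/Arg-4).

Counting: site tallies L0/L2/L4 are averaged over the two sequences
(possibly fractional); each differing position contributes half a
transition/transversion count at each sequence's own class; multi-hit
codons are decomposed position-wise with no pathway enumeration — this
matches the site-class bookkeeping of the combining formulas, and pathway
weighting is out of scope. Per class, Kimura-two-parameter components are

$$A_i = \tfrac12\ln\frac{1}{1-2P_i-Q_i} - \tfrac14\ln\frac{1}{1-2Q_i},
\qquad B_i = \tfrac12\ln\frac{1}{1-2Q_i},$$

combined as KA = A0 + (L0·B0 + L2·B2)/(L0 + L2) and
KS = (L2·A2 + L4·A4)/(L2 + L4) + B4 — transitions at twofold sites are
mostly synonymous (hence weighted into KS), transversions there mostly are
not. The published source prints only the combining formulas; reading
A_i/B_i as per-class K2P components is the central interpretive decision
of this module. A non-positive log argument marks the class saturated and
the affected KA or KS is coerced to 9.999999 and flagged. KA/KS is
reported missing when KS = 0 or either side is saturated; species means
exclude such pairs by default (the divisor shrinks accordingly).

Empty classes (L_i = 0) get zero weight rather than an error. The exact
published variant's treatment of Arg/Leu first positions cannot be pinned
down from the text; accuracy is therefore established by simulation
recovery (ω = 0.1 recovered in [0.07, 0.14]; neutral median in
[0.8, 1.25]) rather than by external ortholog-set numbers, which would
require genome-database downloads.

## 4. Trees

Neighbor joining (via ape's implementation behind a validating wrapper) is
exact on additive metrics — the suite checks random additive trees up to
n = 8 by path-length and topology. Negative branch lengths, which NJ can
produce on near-star metrics, are clamped to zero and flagged. Bootstrap
support resamples alignment columns with replacement; each replicate's
seed derives from the master seed by index, so support does not depend on
taxon input order. The analysis default is 1000 replicates; tests scale
down to 20–100 and say so. Maximum-likelihood branch-length
re-optimization is deliberately out of scope: the package reports the NJ
point estimate.

## 5. Synthetic data: what a green test establishes

`simulate_respirometry` draws, per block, a multiplicative instrument
scale (lognormal, sdlog 0.08) and a cohort fly-size factor; per sample, a
fly count (25–30), incubation (60–80 min), lognormal biological noise
(sdlog 0.12, a realistic respirometry CV), mass, and — at rate 0.015,
about the published 4/264 — a 5–10× high-leverage outlier. Gas fractions
are obtained by inverting the closed-chamber VO2 model, so processing the
table recovers the generated per-fly rates exactly; the first sample of
every block is the reference cell. The raw whole-sample rate and mass
share the fly count and the size factor, producing the raw mass–rate
correlation (target 0.57, solved analytically from the variance
components); per-fly and block-reference normalization removes both shared
pieces, and the suite asserts this qualitatively (raw R > 0.3, normalized
|R| < 0.2) rather than at any exact published value. The generator does
*not* emulate instrument traces, temperature drift, activity, or
between-strain variance heterogeneity — so green tests certify the
estimators and plumbing, not instrument physics.

`simulate_codon_pair` evolves a random sense-codon root by κ-biased
single-nucleotide proposals: stop-creating proposals are rejected,
synonymous ones always fix, nonsynonymous ones fix with probability ω.
The proposal budget is derived analytically from the requested synonymous
divergence through the root's synonymous-proposal probability — not tuned
to any recovery test. Defaults (300 codons, κ = 2, ω = 0.1, KS ≈ 0.3)
emulate the strong-purifying regime of a conserved metabolic regulator.
Realized synonymous/nonsynonymous event counts are returned as ground
truth. This is a selection *filter*, not a full codon model: no site-rate
variation, no codon-frequency bias.

## 6. Numerical conventions and degenerate inputs

- All stochastic functions take explicit seeds; identical seeds give
  byte-identical outputs (the pipeline stamps every run with a config hash
  and seed).
- Fractions outside [0, 1], non-positive flow, or excurrent O2 above
  incurrent beyond a 1e-6 tolerance are rejected at construction.
- Zero flies is an explicit "all flies lost" error — flagged, never
  silently dropped. Missing or non-positive block references error with
  the block named.
- Constant two-group data, singular designs, empty Holm families, empty
  codon overlaps and empty species averages are all named errors.
- Ties in the reference predicate resolve by acquisition index; ties in
  Wilcoxon by mid-ranks; Holm ties are order-stable.
- Pipeline exit codes: 0 success, 2 validation failure, 3 stage failure;
  failed stages quarantine a partial log.

## 7. Known limitations

- The respirometry path trusts pre-integrated fractional concentrations;
  it cannot detect integration or lag artifacts upstream.
- The Type-III effect-size conventions (intercept-inclusive totals,
  N = sum(df)+1, λ = f²(u+v+1)) reproduce the published-table lineage; a
  fresh analysis might defensibly choose otherwise, and the functions
  accept explicit `N` where applicable.
- KA/KS uses class-averaged site counts without pathway weighting; for
  deeply diverged pairs this underweights multi-hit codons, and saturation
  coercion (9.999999) makes such pairs unusable for averaging (they are
  excluded by default).
- Bootstrap support is bipartition frequency on the NJ point estimate; it
  is not a posterior probability and inherits NJ's distance-model
  assumptions (K2P by default).
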