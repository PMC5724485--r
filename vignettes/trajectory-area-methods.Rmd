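---
title: "Methods: joint occasion regressions, standardised trajectories and the area between curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint occasion regressions, standardised trajectories and the area between curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajarea)
```

## The model

`trajarea` analyses a two-arm randomised trial with repeated assessments at
occasions $t_1 < t_2 < \dots < t_K$ (months of age), where the instrument
measuring a given developmental domain may change between occasions. For
each post-baseline occasion $k$ the model is a linear regression of the
(possibly transformed) outcome on treatment assignment and prespecified
covariates — the relevant baseline measure value, centre, age at that
assessment, maternal ethnicity and maternal education:

$$y_{ik} = x_{ik}^\top \gamma_k + \beta_k\,\mathrm{treat}_i + \varepsilon_{ik},
\qquad (\varepsilon_{i1},\dots,\varepsilon_{iK}) \sim N(0, \Sigma).$$

The equations form a seemingly-unrelated-regressions system: each has its
own outcome scale, predictors and error variance, but the errors are
correlated across occasions within a participant through the unstructured
$K \times K$ covariance $\Sigma$. Joint estimation borrows strength across
occasions and is what makes the combined summary below more precise than
any single-occasion contrast.

**Missing outcomes.** The system is estimated by full-information maximum
likelihood: participant $i$ with observed outcome subset $O_i$ contributes
$\log N(y_{i,O_i};\, \mu_{i,O_i},\, \Sigma_{O_i O_i})$. Under
missing-at-random dropout this uses every participant, including those with
incomplete records. Covariates are required to be complete; participants
missing a covariate or the baseline measure are dropped with a logged
warning (the estimator's missing-data guarantee concerns outcome records —
the motivating trial adjusted for covariates but had them essentially
complete).

**Algorithm.** The likelihood is maximised by an ECM scheme rather than by
quasi-Newton search over a Cholesky-parameterised $\Sigma$: the E-step
imputes each participant's missing outcome components by their conditional
normal mean (accumulating the conditional covariance), and the CM-steps
update all coefficients jointly by generalised least squares and $\Sigma$
in closed form. Both routes maximise the same criterion; ECM was chosen
because each iteration is cheap and closed-form, it keeps $\Sigma$ positive
definite without reparameterisation, and the observed-data log-likelihood
is provably non-decreasing along the path — one of the package's tested
invariants, and important when the bootstrap refits the model tens of
thousands of times. Starting values are equation-wise OLS on observed rows
and the residual moment matrix. Convergence is declared at relative
log-likelihood change below `tol = 1e-8` (cap 500 iterations); a stalled
fit returns `converged = FALSE` with diagnostics rather than raising. With
complete data and identical regressors the fixed point is exactly
equation-wise OLS, which the tests assert to 1e-8. The core is compiled
(RcppArmadillo), grouping participants by missingness pattern.

**Coefficient covariance and a small-sample choice.** For the mean
parameters of a normal model the expected information is block-orthogonal
to the covariance parameters, so
$\mathrm{Cov}(\hat\beta) = \left(\sum_i X_{i,O_i}^\top \Sigma_{O_iO_i}^{-1}
X_{i,O_i}\right)^{-1}$ evaluated at the MLE. The ML estimate of $\Sigma$
divides residual cross-products by $n$, not by a residual degree of
freedom; at trial scale ($n = 54$, seven parameters per equation) the
resulting Wald test would be anti-conservative by a predictable amount
(expected size $\approx 0.067$ at nominal 0.05). The package therefore
scales the coefficient covariance by $n/(n-\bar p)$, $\bar p$ the mean
number of parameters per equation — the same convention classical SUR
software uses for its residual covariance. This was decided on analytic
grounds before the calibration experiment was run; the measured size under
the null generator is 0.056. `df_correct = FALSE` restores the raw ML
covariance.

## Standardisation across changing instruments

Because the instrument changes with age, occasion coefficients are mapped
to Cohen's $d$: $d_k = \beta_k / s_{w,k}$, with $s_{w,k}$ the pooled
within-group SD of the *observed* (transformed) outcome at occasion $k$.
Pooling is by degrees of freedom over the two arm cells, and additionally
over the levels of an optional SD stratum — used at the last follow-up,
where the structured assessment's developmental module shifts the score
scale enough that within-module SDs are the appropriate yardstick.
Right-skewed symptom totals at follow-up are analysed as $\log(1+y)$ so the
same standardised-effect estimator applies across the instrument switch.

$\mathrm{SE}(d_k) = \mathrm{SE}(\beta_k)/s_{w,k}$: the SDs are treated as
known constants at this stage, mirroring the linear-combination Wald
construction; the sampling variability of $s_{w,k}$ is picked up by the
participant bootstrap instead. The baseline occasion is anchored at
$d = 0$ with zero variance — randomisation implies a zero expected
difference there — which also settles that the area below starts at the
first assessment, not at the first post-baseline one. Negative $d$ on a
severity scale means benefit; printed reports show $|ES|$ with a direction
label.

## The area between curves

With the control curve held at zero, the anchored trajectory
$(t_k, d_k)_{k=0}^K$ is integrated by the trapezium rule:

$$A = \sum_{k} \tfrac{t_{k+1}-t_k}{2}(d_k + d_{k+1}) = w^\top d,
\qquad \mathrm{Var}(A) = w^\top \mathrm{Cov}(\hat d)\, w,$$

with end weights $(t_2-t_1)/2$, $(t_K-t_{K-1})/2$ and interior weights
$(t_{k+1}-t_{k-1})/2$; the weights sum to the span. $z = A/\sqrt{\mathrm{Var}(A)}$
gives a two-sided normal p. The headline scalar is $A$ divided by the span
— a time-weighted mean Cohen's $d$, the only dimensionally consistent
reading of reporting an "area" result on the effect-size scale; for a
constant trajectory it returns that constant exactly.

Confidence intervals: percentile bootstrap, resampling participants with
replacement *within arm* (unstratified resampling at $n \approx 27$ per arm
can produce nearly empty arms), refitting the entire pipeline per
replicate. Percentile (not BCa) intervals are the default, endpoints taken
as order statistics (type-1 quantiles) of the converged replicates;
replicates that resample themselves into a degenerate design — e.g. a
covariate rendered constant — are dropped and counted, with an error if
more than 20% fail (overridable). `B = 1000` by default.

## The synthetic trial world

No participant-level data accompany the motivating trial, so the generator
*is* the test bed, and its defaults are a stated world, not tuning knobs:

- **Arms and occasions**: 28 intervention / 26 control, assessed at 9, 15,
  27, 39 months, ages jittered uniformly by ±1.5 months around nominal.
- **Series structure**: each developmental domain is one latent
  standard-normal trait across its occasions (exchangeable correlation 0.4
  by default), mapped monotonically onto the instrument scale of each
  occasion. Because domains switch instruments mid-series, the two
  instruments of one domain share the latent trait — which is precisely
  what gives the SUR equations their cross-equation correlation.
- **Instrument maps**: symptom totals are exponentiated normals rounded to
  integers (matching the right-skewed, count-like published cells — e.g.
  control follow-up mean 6.32, SD 6.79); age-normed scores are rounded
  normals; interaction ratings are clipped to [1, 7] at one decimal;
  event-coded proportions use a logistic map with delta-method slope,
  three decimals. Control-arm means/SDs are calibrated to the published
  per-cell summary table; the intervention arm is shifted on the *latent*
  scale by the configured standardised effect curve. For the identity
  (normal) family the latent effect is exactly the standardised effect on
  the analysed scale — the parameter-recovery tests use such a series; for
  nonlinear maps the realised standardised effect differs somewhat from
  the latent one, which is why recovery is not asserted there.
- **Default effect curves** follow the published trajectory shapes:
  symptoms (0, −0.3, −0.5, −0.3); a strong early caregiver effect decaying
  by follow-up (0, 0.8, 0.4, 0.1, 0); a steady child dyadic effect
  (≈0.35); early language dips that resolve; null-ish adaptive effects.
- **Missingness**: visit-level Bernoulli per arm × occasion (defaults
  matched to the published per-cell Ns, peaking at 18% for the
  intervention arm's 27-month visit), i.e. missing at random given arm and
  occasion — the FIML assumption. An outcome-dependent mechanism is
  deliberately absent. Baseline visits are never fully missing.
- **Categorical outcome**: per-arm trinomial with the published
  proportions (control 16/8/2, intervention 16/7/4).

What a green test does *not* establish: robustness to outcome-dependent
(MNAR) dropout, item-level missingness within a visit, rater drift or
coding error in the video-based measures, or model misspecification beyond
the mild non-normality the instrument maps introduce. The generator's
independence across domains (latent traits of different series are
uncorrelated) is also a simplification; it affects nothing within a single
analysis block.

## Categorical analyses and reliability

- **Freeman–Halton exact test** (2×K): full enumeration of tables with the
  observed margins; p is the total probability of tables with
  hypergeometric-product probability ≤ observed, with an absolute tie
  tolerance of 1e-12; a guard rejects totals above 500 (no Monte-Carlo
  fallback, by scope). Verified against an independent 2×2 hypergeometric
  sum and against the published 2×3 p = .846.
- **Proportional odds**: cumulative-logit likelihood maximised by
  Newton–Raphson (analytic gradient, observed information by central
  differences of the gradient, step-halving). The trial parameterisation
  codes the indicator 1 = no-intervention arm with severity-increasing
  cumulative logits, the coding consistent with the published OR = 0.83
  direction; the covariate can simply be flipped for the inverse. Complete
  separation is detected and reported.
- **ICCs**: one-way random single measures ICC(1,1) $= (MS_B - MS_W)/(MS_B
  + (k-1) MS_W)$, and two-way random absolute-agreement single measures
  ICC(A,1), both from explicit ANOVA mean squares. Zero between-subject
  variance gives a defined non-positive value; fully constant ratings are
  an error (undefined coefficient).

## Numerical choices, degenerate inputs

- EM tolerance 1e-8 (relative), cap 500; bootstrap refits warm-start from
  the full-data solution.
- Singular designs are rejected up front with the offending columns named;
  all-missing equations and zero within-group SDs are errors naming the
  occasion; non-positive-definite generator correlation matrices are
  rejected naming the series.
- Wide-format CSV I/O round-trips exactly (missing = empty cell), with
  schema validation that collects and reports all violations at once.
- Reports and JSON artifacts contain no timestamps, so a rerun with the
  same seed is byte-identical.

## Known limitations

- Wald inference treats the within-group SDs as fixed; the bootstrap is
  the primary interval.
- No sandwich/robust standard errors, no random-effects growth curves, no
  weighting for informative dropout (all out of scope).
- The ordinal model's published-software coding convention was not stated
  in the source; the chosen direction is documented above and exposed.
- Multiple domain blocks are reported without multiplicity adjustment,
  matching the prespecified-outcome framing; a Bonferroni toggle exists in
  the pipeline configuration, off by default.
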