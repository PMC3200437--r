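---
title: "Comparing model evidence approximations for GLMs and DCMs"
author: "dcmEvidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing model evidence approximations for GLMs and DCMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmEvidence)
```

## The problem

When several candidate models of the same brain-connectivity data are on
the table — say a "full" network in which an experimental manipulation
modulates two connections, and a "nested" one in which it modulates only
one — the Bayesian answer is to compare their model evidences
$p(y \mid m)$. The evidence integrates the likelihood over the prior, so it
automatically trades data fit against model flexibility. It is, however,
intractable for nonlinear models, and in practice one of three
approximations is used:

* the **Laplace free energy** $F_L$, produced as a by-product of
  variational Laplace (VL) model inversion,
* **AIC** $= \mathrm{Accuracy} - p$, and
* **BIC** $= \mathrm{Accuracy} - \tfrac{p}{2}\log N$,

where $p$ counts free parameters, $N$ data points, and the accuracy is the
log likelihood evaluated at the posterior means. This package implements
all three (plus the small-sample corrected AICc), the models they are
applied to — analytic Bayesian GLMs and bilinear dynamic causal models
(DCMs) for fMRI — and the Monte Carlo sweeps that measure each criterion's
sensitivity and specificity for full-versus-nested comparison as functions
of the signal-to-noise ratio and of $N$.

## Free energy: accuracy minus complexity

For the observation model $y = g(\theta) + e$ with Gaussian noise
$C_y$, Gaussian prior $N(\mu_\theta, C_\theta)$ and Gaussian (approximate)
posterior $N(m_\theta, S_\theta)$, the Laplace free energy is

$$F_L = \underbrace{-\tfrac12 e_y^T C_y^{-1} e_y - \tfrac12 \log |C_y|
  - \tfrac{N}{2}\log 2\pi}_{\text{Accuracy}}
  - \underbrace{\left[\tfrac12 e_\theta^T C_\theta^{-1} e_\theta
  + \tfrac12 \log \tfrac{|C_\theta|}{|S_\theta|}\right]}_{\text{Complexity}}$$

with residual $e_y = y - g(m_\theta)$ and prior departure
$e_\theta = m_\theta - \mu_\theta$. When noise hyperparameters are
estimated rather than known, an analogous complexity term for
$\lambda$ is added. The log-determinant ratio is the Occam factor: a
posterior that contracts a lot relative to the prior, or departs far from
the prior mean, costs evidence. Unlike AIC/BIC, this penalty is *per
parameter and prior-referenced* — a parameter estimated at three prior
standard deviations is expensive for $F_L$ but free for AIC/BIC. That
asymmetry is the substantive point of the whole comparison.

`evidenceAccuracy()`, `evidenceComplexity()` and `laplaceFreeEnergy()`
expose these terms directly; `laplaceFreeEnergy()` also decomposes the
accuracy over regions (exact when noise is block-independent across
regions) and the complexity over parameter sets (approximate, because it
ignores cross-set posterior correlation; the exact total is always
reported alongside, and serialised records flag the per-set numbers as
approximate).

For a GLM with known noise, $F_L$ computed from the analytic posterior is
*exactly* the log marginal likelihood
$\log N(y;\, X\mu_\theta,\, X C_\theta X^T + C_y)$. The package exploits
this as its primary internal oracle: `glmLogEvidence()` is an independent
closed form against which `laplaceFreeEnergy()` (and the whole VL path on
linear problems) is tested to $10^{-6}$.

## The DCM generative model

Neuronal dynamics are bilinear,
$\dot z = (A + \sum_j u_j B^j) z + C u$, observed through an extended
Balloon model per region (vasodilatory signal, inflow, Grubb-exponent
venous volume, deoxyhemoglobin) and a nonlinear BOLD signal equation with
revised coefficients built from the resting oxygen extraction $E_0$ and
the intra/extravascular ratio $\varepsilon$
($k_1 = 4.3\,\vartheta_0 E_0 T_E$, $k_2 = \varepsilon r_0 E_0 T_E$,
$k_3 = 1 - \varepsilon$, with $\vartheta_0 = 40.3$, $r_0 = 25$,
$T_E = 40$ ms, $V_0 = 4\%$).

Priors (all Gaussian, `dcmPriorBelief()`):

| parameter                | prior                    | rationale |
|--------------------------|--------------------------|-----------|
| self-connections $A_{ii}$ | $N(-1, 0.177^2)$ Hz     | implies decay half-lives with mean ≈ 720 ms, ~90% in 500–1000 ms |
| cross-connections $A_{ik}$ | $N(1/64, 0.5^2)$ Hz    | weakly positive, encourages stable dynamics |
| modulatory $B$, input $C$ | $N(0, 2^2)$ Hz          | shrinkage priors |
| hemodynamic latents       | $N(0, 1/256)$           | $\kappa$, $\tau$, $\varepsilon$ as scaled exponentials $0.64 e^{\eta}$, $2 e^{\eta}$, $1 e^{\eta}$; $\gamma = 0.32$, $\alpha = 0.32$, $E_0 = 0.4$ fixed |
| noise log-precisions $\lambda_i$ | $N(0, 1)$ per region | mean prior precision $e^{1/2} \approx 1.7$ |

The hemodynamic equations and their prior variances are not printed in the
source study (they live in an appendix we do not have), so the package
implements the standard DCM-for-fMRI extended Balloon model with
DCM8-era default means and small latent variances, isolated behind
`balloonBold()` so an alternative observation model can be swapped in.

Worth knowing about the priors as printed: with $\sigma_{cross} = 0.5$ on
a fully connected three-region network, about 3% of prior draws of $A$
have a positive real eigenvalue. Such draws diverge (the integrator raises
an instability error) and the data generator resamples them, reporting the
resample count. Separately, sustained strongly negative neuronal drive
pushes inflow towards zero, where the Balloon model is genuinely singular;
these draws also error and resample. Neither is a numerical artifact —
refining the step size does not rescue them.

### The speech network

`buildSpeechModels()` returns the two three-region models compared
throughout: regions P (posterior temporal), F (inferior frontal) and
A (anterior temporal), fully intrinsically connected; an auditory spike
train $u_{aud}$ drives P; an intelligibility indicator $u_{int}$ modulates
P→F in both models and additionally P→A ($b_{AP}$) in the full model only.
The two models therefore differ in exactly one free parameter — a
deliberately hard comparison.

The real paradigm's event timing is not published, so `makeSpeechInputs()`
builds a stand-in: 1-second auditory events every 8 s, alternating
intelligibility. Likewise the held-constant non-modulatory parameter
values of the original fits are unpublished; `speechFixedParams()` uses
self-connections −1 Hz, cross connections 0.3 Hz, driving input 0.3 Hz and
prior-mean hemodynamics, all overridable and recorded with every
generated data set.

## Variational Laplace

`vlFit()` maximises $F_L$ under the factorised posterior
$q(\theta)q(\lambda)$:

* Gauss–Newton parameter updates with Levenberg–Marquardt damping,
  posterior covariance $S_\theta = (J^T C_y^{-1} J + C_\theta^{-1})^{-1}$
  from a central-finite-difference Jacobian (relative step
  $\max(|\theta_i|, 1) \times 10^{-4}$);
* damped Newton updates for the noise log-precisions, with
  $C_y^{-1} = \sum_i e^{\lambda_i} Q_i$ and $Q_i$ identity blocks per
  region in the fMRI case;
* every candidate step is evaluated on the *actual* free energy and
  rejected (with increased damping) if it would decrease it, so the
  accepted trajectory is non-decreasing by construction;
* convergence when the improvement stays below `tol` (default $10^{-2}$)
  for two consecutive iterations, up to `maxIter` (default 128); all of
  this is exposed through `vlOptions()`. The update-scheme details
  (damping schedule, iteration caps) are engineering choices — the
  contract is only that $F_L$ is locally maximised, which the linear-model
  oracle pins down exactly.
* parameters with zero prior variance are held at their prior mean,
  excluded from the update and from the AIC/BIC parameter count $p$
  (fixed-at-zero parameters are not estimated; this matches the
  12-versus-9 regressor and $b_{AP}$ counting). Hyperparameters are not
  counted in $p$.

The $\lambda$ update maximises $F_L$ itself rather than the
expected-residual variant; the resulting bias in $\exp(m_\lambda)$ is of
order (free parameters)/(data points) and is verified to be within 10% of
the generating precision at $N = 488$ scans per region.

## Synthetic data and calibration

`makeGlmDesign()` emulates a four-condition event-related design, each
condition convolved with a canonical double-gamma HRF (peak 6 s,
undershoot 16 s, ratio 1/6) plus its temporal and dispersion derivatives —
3 basis functions per condition, 12 columns, 351 scans at TR = 2 s by
default; the nested design drops the first condition's three columns.
Event schedules are pseudo-random with mean inter-trial interval 8 s,
seeded. The true basis set and paradigm timing of the source data are not
published; these are documented stand-ins.

SNR is defined as $\langle\sigma_y\rangle / \sigma_e$: the mean temporal
SD of the noiseless signal over the noise SD. For GLMs
$\langle\sigma_y\rangle$ is averaged over 1000 seeded prior draws of the
coefficients (`glmPriorSignals()`, prior SD $\sigma_p = 6.05$ when
emulating the study setting); for DCMs it is averaged over the three
predicted region time series. `generateGlmDataset()` and
`generateDcmDataset()` then add i.i.d. Gaussian noise at the calibrated
SD. Modulatory DCM parameters are drawn from their prior and made
positive by absolute value, so modulation is always facilitating; all
draws are bit-reproducible from their seeds.

What the generator does *not* emulate: scanner drift, temporal
autocorrelation (data are assumed pre-whitened), motion artifacts, or
between-subject variability. Passing tests therefore show that the
criteria behave as described for well-specified i.i.d.-noise simulations,
not that they are robust to those real-data complications.

## The sweeps

`glmSnrSweep()` and `glmNSweep()` run the analytic GLM comparison over an
SNR grid (or 20 sample sizes between 32 and 512 at SNR 0.5), aggregating
oriented log Bayes factors (true model versus the alternative) by the
mean over replications; `dcmSnrSweep()` does the DCM analogue with VL
fits, aggregated by the median because DCM replications are heavier
tailed, excluding (and counting) non-converged fits. Replication seeds
are derived from the master seed by a counter scheme, so any single grid
point is reproducible in isolation. `decomposeComparison()` then
attributes a free-energy difference to per-region accuracy and
per-parameter-set complexity.

The study-scale settings are 1000 replications per GLM grid point and 50
per DCM grid point at 488 scans. The shipped tests run the same pipelines
at desk scale — e.g. 10 DCM replications at 128 scans, the scale at which
a full sweep point completes in minutes on one core — which is enough to
reproduce the qualitative pattern: at very low SNR the free energy's mean
log Bayes factor is within Monte Carlo error of zero while BIC (strongly)
and AIC (less so) favour the nested model; on full-generated DCM data the
free energy detects the extra modulation, helped by a complexity term that
notices when the nested model buys back accuracy with an a-priori unlikely
intrinsic connection (typically inflated several-fold) that the
fixed-penalty criteria cannot see. How far AIC/BIC's accuracy advantage
falls short of that complexity penalty depends on the stand-in paradigm
and fixed parameters (the empirical ones are unpublished): with the
defaults here, draws whose P→A modulation is large but whose P→F
modulation is small leave region-A structure the nested model cannot
mimic, so AIC and BIC medians are not reliably negative at desk scale.

## Numerical choices

* Log-determinants and quadratic forms always go through Cholesky
  factors; determinants are never exponentiated and covariances never
  explicitly inverted on the data scale.
* All logarithms are natural; "log Bayes factor 3" corresponds to a Bayes
  factor of $e^3 \approx 20$ and posterior probability just above 0.95.
* Posterior model probabilities are computed as the logistic of the log
  Bayes factor, so enormous evidence differences cannot overflow.
* Neurodynamic and hemodynamic integration uses fixed-step RK4 at
  $dt = TR/16$, with hemodynamic states in log space
  ($\ln f, \ln v, \ln q$) for positivity; agreement with an adaptive
  reference integrator is tested to a relative $L_2$ error of $10^{-3}$.
* AICc errors (rather than silently extrapolating) for $N \le p + 1$,
  where its correction changes sign.
* Degenerate inputs: singular covariances raise definiteness errors;
  all-constant signals make SNR calibration error; region/parameter maps
  must partition their index ranges exactly.

## Limitations

* $F_L$ here is the Laplace form; it is not guaranteed to lower-bound the
  log evidence for nonlinear models.
* The per-set complexity decomposition ignores cross-set correlation and
  is reported as approximate.
* Only deterministic, single-state, bilinear DCMs with i.i.d. per-region
  noise are covered; empirical-Bayes estimation of prior variances is out
  of scope.
* The source study's empirical data sets are not redistributable; their
  scalar summaries ($\sigma_p = 6.05$, $\hat\sigma_e = 0.73$, empirical
  SNRs 1.3 and 0.2) enter only as documented constants of the synthetic
  setup, and no claim of empirical reproduction is made.

## A worked example

```{r example, eval = FALSE}
ms <- buildSpeechModels(nScans = 128)
ds <- generateDcmDataset(ms$full, snr = 2, seed = 101)
ff <- dcmFit(ms$full, ds$y, ds$inputs)
fn <- dcmFit(ms$nested, ds$y, ds$inputs)
bayesFactor(freeEnergy(ff), freeEnergy(fn))
decomposeComparison(ff, fn)
```

On this draw (true $b_{AP} \approx 1.1$) the nested fit inflates the F→A
intrinsic connection about threefold relative to the full fit, the
accuracy advantage of the full model is realised in region A, and the
dominant term in $\Delta F_L$ is complexity, not accuracy — the
mechanism by which the free energy out-selects the fixed-penalty
criteria. The same quantities are computed, at the same scale, by the
test suite.
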