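# dcmEvidence

Bayesian model comparison for neuroimaging time-series models: how well do
the **Laplace free energy (F_L)**, **AIC** and **BIC** approximate the log
model evidence, and which of them can actually tell a full network model
from a nested one?

The package is aimed at methods researchers in brain connectivity /
dynamic causal modelling (DCM) who want a tested, self-contained
simulation bench. It implements:

* the Laplace free energy with its accuracy/complexity decomposition

  F_L = [ -½ e_yᵀC_y⁻¹e_y - ½ log|C_y| - (N/2) log 2π ]
        - [ ½ e_θᵀC_θ⁻¹e_θ + ½ log(|C_θ|/|S_θ|) ]  (- hyper analogue),

  plus AIC = Accuracy - p, BIC = Accuracy - (p/2) log N, AICc, Bayes
  factors and posterior model probabilities (`laplaceFreeEnergy()`,
  `aic()`, `bic()`, `aicc()`, `bayesFactor()`);
* analytic Bayesian GLMs — conjugate posterior, closed-form log evidence
  (which equals F_L exactly for known noise, and serves as the oracle in
  the tests), criterion scoring (`glmPosterior()`, `glmLogEvidence()`,
  `glmCriteria()`);
* a bilinear DCM generator for fMRI: shrinkage priors over intrinsic /
  modulatory / input connections, extended Balloon hemodynamics with the
  nonlinear BOLD signal equation (compiled RK4 integrator), and the
  three-region intelligible-speech full/nested model pair
  (`samplePrior()`, `dcmPredict()`, `buildSpeechModels()`);
* a variational Laplace fitter for y = g(θ) + e with precision-basis
  noise, Gauss–Newton/Levenberg–Marquardt steps that never decrease the
  free energy (`vlFit()`, `dcmFit()`);
* seeded synthetic-data generators and SNR calibration
  (`makeGlmDesign()`, `calibrateSnr()`, `generateGlmDataset()`,
  `generateDcmDataset()`);
* the study pipelines: SNR and sample-size sweeps of oriented log Bayes
  factors for both model classes, and the per-region / per-parameter-set
  diagnosis of a comparison (`glmSnrSweep()`, `glmNSweep()`,
  `dcmSnrSweep()`, `decomposeComparison()`).

A thin CLI over the generators and sweeps ships in
`inst/scripts/evidence-bench.R`.

## Worked example

A full-versus-nested GLM comparison at SNR 0.5 on the emulated
four-condition event-related design (351 scans, 12 regressors, prior SD
6.05):

```r
library(dcmEvidence)
X <- makeGlmDesign(seed = 1)                        # 351 x 12
snr <- calibrateSnr(glmPriorSignals(X, 6.05, 1000, seed = 1), targetSnr = 0.5)
ds <- generateGlmDataset(X, 6.05, snr, seed = 2)    # drawn from the full model
full   <- glmCriteria(glmSpec(X,          6.05, snr@noiseSd), ds$y)$criteria
nested <- glmCriteria(glmSpec(X[, -(1:3)], 6.05, snr@noiseSd), ds$y)$criteria
full
#> CriterionSet (p = 12, N = 351)
#>   F_L = -1422.3510  AIC = -1416.6652  BIC = -1439.8299  AICc = -1417.1267
nested
#> CriterionSet (p = 9, N = 351)
#>   F_L = -1433.0279  AIC = -1430.3409  BIC = -1447.7145  AICc = -1430.6049
bayesFactor(freeEnergy(full), freeEnergy(nested))
#> logBF 10.68, posterior probability ~1
```

The free energy favours the (true) full model by a log Bayes factor of
about 10.7 — decisive, since log Bayes factors above 3 (Bayes factor
e³ ≈ 20, posterior probability > 0.95) are conventionally treated as
clear evidence. At much lower SNR the mean F_L log Bayes factor goes to
zero while AIC/BIC acquire a bias towards the nested model — run
`glmSnrSweep(0.0025, reps = 1000, trueModel = "full", seed = 1)` to see
it, and `dcmSnrSweep()` for the DCM analogue.

The prior over self-connections implies a decay half-life distribution
that calibrates the neuronal timescale:

```r
st <- halflifePriorStats(1e6, seed = 1)
#> mean half-life 717.3 ms, fraction in [500, 1000] ms 0.944
```

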