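# sohga

Automated model selection for population pharmacokinetics with a
single-objective hybrid genetic algorithm.

Population PK model building means deciding, jointly: which covariates
enter the model, on which structural parameters, through which functional
form, and with which inter-individual-variability (IIV) and residual-error
structures.  The conventional stepwise procedure makes those decisions one
at a time and can miss interacting combinations.  This package is a
self-contained toolkit for searching that decision space:

* **A nonlinear mixed-effects estimator** (`fit_model()`): closed-form
  one/two-compartment models, FO and FOCE-I (first-order conditional with
  interaction) approximations of the marginal likelihood, empirical Bayes
  estimates, and a finite-difference covariance step with standard
  errors, the estimation correlation matrix and its condition number.
* **A binary-genome hybrid GA** (`run_sohga()`): every model decision is
  a fixed-width bit field; candidates are scored by

  `fitness = OBV + 10·(#covariate + #IIV + #residual parameters)
             + 400·[minimization or covariance failed]
             + 300·[max |correlation| > 0.95]
             (+ 300·[condition number > 1000], optional)`

  with fitness-scaled roulette selection (weights in [0.2, 4]), 0.7
  crossover events per parent pair, 0.01 mutations per bit, four
  protected niches (Hamming ≤ 4), elitism, and a one-bit downhill local
  search every five generations.
* **Automated stepwise covariate modeling** (`run_scm()`): forward
  inclusion / backward elimination on likelihood-ratio thresholds
  (3.84, 6.63, 7.88 at p = 0.05, 0.01, 0.005 with 1 df).
* **A simulation-study generator** (`simulate_covariates()`,
  `simulate_pk_dataset()`): 200 subjects with realistically correlated
  covariates (BMI, sex, age, creatinine, height → weight → BSA → CRCL,
  plus four decoys) and concentrations from a known one-compartment model
  (CL 0.763 L/h, V 1.94 L, 20% IIV, combined error), with effect sizes
  calibrated so each true covariate moves the objective by 10–100 points.
* **Comparison metrics** (`aic()`, `bic()`, `mpe()`, `rmse()`,
  `cohen_kappa()`, `compare_models()`).

NONMEM-style rectangular CSV datasets (`ID, TIME, AMT, EVID, DV,
covariates`) are read and written by `read_pkdata()` / `write_pkdata()`.
A thin command-line front end lives at `inst/scripts/pksohga`
(subcommands `simulate`, `fit`, `scm`, `sohga`).

## Worked example

```r
library(sohga)

# simulate the 200-subject study
covs <- simulate_covariates(seed = 11)
ds   <- simulate_pk_dataset(covs, seed = 12)
ds
#> <pk_dataset> 200 subjects, 200 doses, 1600 non-missing observations
#> covariates: BMI, SEX, AGE, CR, HT, WT, BSA, CRCL, CV1, CV2, CV3, CV4

# fit the generating model
fit <- fit_model(true_model_spec(covs), ds)
fit
#> <pkfit> onecpt_iv|CL~BMI.exp+CL~CRCL.exp+V~BSA.exp+V~SEX.exp_d|iiv:CL,V|combined
#> OBV: 911.626  converged: TRUE  covariance: TRUE
#>          CL           V  CL~BMI.exp CL~CRCL.exp   V~BSA.exp V~SEX.exp_d
#>   0.7541000   1.8120000   0.3674000   0.1674000   0.4771000  -0.1374000
#>    omega.CL     omega.V  sigma.prop   sigma.add
#>   0.1860000   0.1862000   0.0106400   0.0005972
```

The typical values recover the truth (CL 0.763 L/h, V 1.94 L) within
their standard errors, the effect coefficients sit near the generating
(0.35, 0.17, 0.45, -0.22), and the estimated IIV (18.6% on both
parameters) is close to the generating 20%.
A covariate search over all 24 (parameter × covariate) pairs:

```r
base <- base_model_spec(covs)
cand <- simulated_candidate_effects(covs)

scm <- run_scm(base, ds, cand, p_in = 0.05, p_out = 0.01)
scm$selected   # includes CL~BMI.exp, CL~CRCL.exp, V~SEX.exp_d

space <- covariate_search_space(base, cand)
run <- run_sohga(space, ds,
                 ga_config(pop_size = 30, generations = 10, seed = 101))
run$best$spec  # the best-fitness candidate model
```

Both engines recover the BMI and creatinine-clearance effects on
clearance and the sex effect on volume; the body-surface-area effect on
volume is systematically replaced by proxies (height/weight), as expected
from the covariate correlation structure.

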