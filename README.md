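# kinresponse

Perturbation–response analysis of random kinetic metabolic models.

Metabolism is homeostatic but not rigid: after a sudden displacement of
metabolite concentrations, some metabolic states relax back monotonically
while others transiently *amplify* the displacement before returning.
`kinresponse` is for systems biologists and modelers who want to ask, in a
fully controlled setting, **which structural features of a reaction network
produce that amplification**. It generates thermodynamically consistent
random kinetic models — a minimal mass-action model with a 3-form cofactor
pool (an ATP/ADP/AMP analogue) coupled to a tunable fraction *f* of
reactions, a catalytic variant without cofactors, and the random catalytic
reaction network (RCRN) toy cell — integrates their stiff relaxation
dynamics from randomized perturbations, and quantifies responsiveness.

The central statistic is the **response coefficient**

```
chi = max_t || ln x(t) - ln x_st ||  /  || ln x(0) - ln x_st ||
```

(Euclidean norm; the max includes t = 0, so chi >= 1 — chi = 1 is monotone
relaxation, chi >> 1 is transient amplification). Perturbations are
multiplicative, `r_n ~ U(0.6, 1.4)` at the default 40 % strength, and
preserve every conserved pool exactly. On top of this sit:

* **clamping analysis** (`clampScan`) — freeze one metabolite at its
  steady-state value and report the signed relative change
  `rho± = ±(<chi_clamped> - <chi_ori>)/<chi_ori>` with paired perturbation
  draws; destabilizing clamps are flagged;
* **network expansion** (`expandAndMeasure`) — add random (optionally
  cofactor-coupled) reactions with parameters bootstrapped from the base
  model and measure the change in mean chi, screening every extension for a
  unique attractor;
* **density/coupling sweeps** (`runSweep`) — ensembles over the reaction
  count R and coupling fraction f with tidy CSV + JSON-manifest output;
* **supporting machinery** — exact integer conserved-moiety analysis,
  multistability screening, analytic Jacobians with stability
  certification, enzymatic rate-law templates, elementary reaction
  decomposition, a closed-form estimate of metabolite fluctuation strength
  under gamma-distributed enzyme noise, and lossless JSON / GraphML
  serialization.

The stiff mass-action core (RHS, Jacobian, stopping criteria) is compiled C
driven through `deSolve`, so ensemble experiments with tens of thousands of
trajectories run in minutes on one CPU.

## Worked example

```r
library(kinresponse)

m   <- generateMinimalModel(nSpecies = 16, nReactions = 23, f = 0.75,
                            beta = 10, seed = 42)
ss  <- findAttractor(m)
ss
#> SteadyState: residual 6.51e-08 | max Re(eig) -0.006582 | 1 conserved pool(s)

ens <- responseDistribution(m, ss, nIni = 32, seed = 7)
ens
#> ResponseEnsemble: 32 trajectories, 0 failed; mean chi = 1.1861
range(chis(ens))
#> [1] 1.00000 1.94367
```

The attractor is certified stable (all non-pool eigenvalues have negative
real part) and the 32 perturbation trials span monotone relaxations
(chi = 1) up to a trajectory whose log-space excursion nearly doubles its
initial displacement (chi = 1.94); the ensemble mean 1.19 is this network's
responsiveness score. Which species' dynamics carry it?

```r
head(clampScan(m, ss, nIni = 16, seed = 7), 5)
#>   species meanChiClamped        rho  sign destabilized failed
#> 1     C14       1.230639 0.10121244  plus        FALSE  FALSE
#> 2     A**       1.043225 0.06649130 minus        FALSE  FALSE
#> 3      A*       1.068149 0.04418818 minus        FALSE  FALSE
#> 4     C12       1.078661 0.03478166 minus        FALSE  FALSE
#> 5      C7       1.098780 0.01677899 minus        FALSE  FALSE
```

Freezing the cofactor forms A\*\* and A\* *reduces* the mean response
(`rho-` of 6.6 % and 4.4 %): the carrier pool's own dynamics are a driver
of responsiveness in this network, in line with the role of the adenylate
pool in real metabolic models. And the fluctuation estimate behind the 40 %
perturbation default:

```r
cvEstimate(6.82)
#> [1] 0.6200944
```

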