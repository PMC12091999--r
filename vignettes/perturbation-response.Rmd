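---
title: "Perturbation-response analysis of random kinetic metabolic models"
author: "kinresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-response analysis of random kinetic metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinresponse)
```

## The scientific question

Cellular metabolism is homeostatic, yet far from rigid: after a sudden
displacement of metabolite concentrations (division noise, enzyme-expression
noise, an environmental shift), some metabolic states relax back quietly
while others transiently *amplify* the displacement before returning.
`kinresponse` provides a self-contained laboratory for studying which
structural features of a metabolic network produce that amplification.  Two
candidate determinants are built into the generators:

* **cofactor coupling** — a small pool of interconverting carrier forms
  (A\*\*, A\*, A; an ATP/ADP/AMP analogue) attached to a fraction $f$ of the
  reactions, conserving its total concentration; and
* **backbone sparsity** — the number of reactions $R$ connecting the $N$
  metabolites, with $R = N-1$ the sparsest (a chain) and larger $R$
  progressively denser.

## The response coefficient

For a model with stable steady state $x^{\mathrm{st}}$, a trajectory started
from a perturbed state $x(0)$ is scored by

$$
\chi \;=\; \frac{\max_t \lVert \ln x(t) - \ln x^{\mathrm{st}} \rVert}
               {\lVert \ln x(0) - \ln x^{\mathrm{st}} \rVert},
$$

the peak Euclidean log-space distance from the attractor relative to the
initial distance.  Because $t = 0$ is included in the maximization,
$\chi \ge 1$ always; $\chi = 1$ means the distance decays monotonically,
$\chi \gg 1$ means the perturbation is transiently amplified.  Natural
logarithms are used throughout.

Perturbations are multiplicative and conserved-quantity-preserving: each
concentration is scaled by an independent factor $r_n \sim U(1-s,\,1+s)$
with default strength $s = 0.4$ (factors in $[0.6, 1.4]$), after which each
conserved pool is restored exactly to its steady-state total.  The 40 %
default is deliberately below the ~62 % ceiling suggested by the
gamma-noise estimate below.

## The minimal cofactor model

The generator builds mass-action models

$$
\frac{dx_n}{dt} = \sum_{r=1}^{R} S_{nr} J_r(x) + D_n (X_n - x_n),
\qquad
J_r = v_r\Bigl(k_r^+ \prod_{n \in \mathrm{Sub}(r)} x_n
            - k_r^- \prod_{n \in \mathrm{Prd}(r)} x_n\Bigr),
$$

with state vector stacking the $N$ backbone chemicals first and the three
cofactor forms last.  Construction, in order:

1. **Backbone** (`buildBackbone`): a linear chain $C_1 = C_2 = \cdots = C_N$
   ($N-1$ uni-uni reactions) plus $R-(N-1)$ extra uni-uni reactions drawn
   uniformly without replacement from the species pairs not yet connected.
   Exchange with the environment is enabled for $\max(2,\,\mathrm{Round}(0.05N))$
   species — always both chain endpoints, so the network has no dead ends —
   with the nutrient endpoint at external concentration 100 and all other
   exchanged species at 1.  `Round()` is half-away-from-zero everywhere a
   count is derived from a fraction, so ties are deterministic.
2. **Cofactor coupling** (`coupleCofactors`): exactly $\mathrm{Round}(fR)$
   reactions are coupled to an interconversion of two distinct, randomly
   chosen cofactor forms, with random direction (the "from" form is a
   substrate of the forward direction).  Cofactors never appear as backbone
   reactants, are never exchanged, and are not themselves catalytic.
3. **Thermodynamics** (`assignThermodynamics`): standard chemical potentials
   $\mu_n \sim U(0,1)$ for the backbone, fixed at $1.0/0.5/0.0$ for
   A\*\*/A\*/A; irreversibilities
   $k_r^{\pm} = \min\{1, \exp(\mp\beta\,\Delta\mu_r)\}$ with
   $\Delta\mu_r = \sum_{\mathrm{Prd}} \mu - \sum_{\mathrm{Sub}} \mu$, so that
   $k^+/k^- = e^{-\beta\Delta\mu_r}$ exactly (detailed balance) and closed
   variants relax to the Boltzmann equilibrium $x_n \propto e^{-\beta\mu_n}$
   with all fluxes individually zero.
4. **Rates** (`assignRates`): $v_r = 10^{u}$, $u \sim U(-3.66,\,7.13)$ — the
   empirical decade-spread of kinetic constants in genome-scale *E. coli*
   kinetic modeling.

A coupled reaction can accumulate $|\Delta\mu| \le 1$ from the backbone pair
plus $\le 1$ from the cofactor pair, so $\sup|\Delta\mu| = 2$ and the
default $\beta = 10$ caps the suppression at $e^{-20}$.  The **catalytic
variant** (`buildCatalyticVariant`) replaces cofactor coupling by an
enzyme-like catalyst species, $C_n + C_l \rightleftharpoons C_m + C_l$
(autocatalysis permitted): same number of quadratic terms as $f = 1$, but
the catalyst cancels from both the stoichiometry and $\Delta\mu$, so
$\sup|\Delta\mu| = 1$ and $\beta = 20$ matches the cofactor model's maximal
$\beta\,\Delta\mu$.  The cofactor totals are set to one; at model build the
three forms start at equal thirds (this only seeds the integration — the
attractor is computed downstream).

## The RCRN baseline

The random catalytic reaction network (`buildRcrn`) is the classic toy cell
in which every metabolite is also a catalyst:

$$
\frac{dx_i}{dt} = \sum_{j,k} x_k\,(v_{ijk} x_j - v_{jik} x_i)
  + D_i\, x_{T(i)}\, x_i^{\mathrm{ext}} - \mu x_i,
\qquad \mu = \sum_i D_i\, x_{T(i)}\, x_i^{\mathrm{ext}} .
$$

Only the first metabolite is a nutrient ($D_1 = 1$, external concentration
1) and the last is its transporter.  Because growth dilutes at the total
uptake rate, $d(\sum_i x_i)/dt = \mu(1 - \sum_i x_i)$: the total
concentration relaxes to 1 and nothing is conserved.

**A caution about the rate pool.**  The generator's default rate pool is the
minimal model's $10^{U(-3.66, 7.13)}$.  With an 11-decade spread, each
species' kinetics is dominated by one or two edges, so the *effective*
network of a nominally dense RCRN is sparse — and sparsity is exactly what
generates responsiveness.  Empirically, such instances are *not* a
weak-response baseline (mean $\chi \approx 1.3$–2 at $N = 64$–128, with
frequent stiffness failures).  The weak-baseline character of dense random
networks — $\chi$ piled up at 1, below a sparse cofactor ensemble — emerges
as soon as the edge weights are comparable; the test suite demonstrates it
with a 4-decade pool ($10^{U(-2,2)}$) passed explicitly.  When using the
RCRN as a dense null model, choose the rate pool accordingly.

## Dynamics machinery and numerical choices

* **Integration**: `lsoda`/`lsodar` (stiff, adaptive) with the analytic
  mass-action Jacobian, implemented in C for throughput; an R reference
  implementation of the right-hand side is cross-checked against the
  compiled one in the tests.  Output is taken on a log-spaced grid of 512
  points from $10^{-9}$ to the horizon (the fastest bimolecular reactions
  have timescales near $10^{-9}$; the grid's resolution of the $\chi$ peak
  is validated against a $10^5$-point brute-force oracle on a non-normal
  linear fixture).
* **Steady states** (`findAttractor`): integrate with an in-solver stopping
  criterion $\max_n |dx_n/dt| < \varepsilon_{\mathrm{abs}} +
  \varepsilon_{\mathrm{rel}} \max_r |J_r|$
  ($\varepsilon_{\mathrm{rel}} = 10^{-9}$), up to a hard cap of $10^{10}$
  time units, then polish by damped Newton with the conserved-pool totals
  held fixed; certify stability from the Jacobian spectrum after removing
  one zero mode per conserved pool.  Because `eigen()` resolves eigenvalues
  only to about $10^{-15}$ of the spectral radius (which reaches $10^8$
  here), real parts below $10^{-9}$ of the radius are treated as marginal
  rather than unstable.
* **Response trajectories**: integration stops early once the log-distance
  falls below $10^{-3}$ of its initial value or the state is numerically
  steady; $\chi$ is the maximum over the integrated window (including
  $t = 0$), so trajectories that have not returned by the cap still carry a
  well-defined fixed-horizon $\chi$.  Only hard solver failures are
  excluded (and counted) — mirroring the protocol's exclusion of
  computational failures only.
* **Conserved pools** (`conservedPools`): an exact integer basis of the left
  null space of the stoichiometry restricted to species without exchange
  (and not clamped), by fraction-free integer elimination.  The cofactor
  total $(1,1,1)$ is always recovered when cofactors are present.  Sparse
  backbones — chains especially — generically carry a *second*, mixed-sign
  moiety spanning backbone and cofactor species.
* **Pool-preserving perturbation**: disjoint pool supports are restored by a
  uniform per-pool rescale.  Overlapping supports (the chain moiety case)
  use the multiplicative projection $x \odot \exp(P^\top\lambda)$, solved by
  damped Newton on the strictly convex dual; by Birch's theorem the positive
  solution exists and is unique, so positivity is never traded against the
  constraints.  (An additive projection is *not* a safe alternative: with
  concentrations spanning many decades it must be damped so strongly that
  perturbations collapse into the linear regime.)
* **Multistability** (`screenMultistability`): endpoints from log-uniform
  initial states in $(10^{-3}, 10^3)^N$ (pool totals fixed to the reference
  values, since the attractor of a model with pools depends on them) are
  clustered with a max-log-distance tolerance of $10^{-4}$.

## Clamping and expansion

`clampSpecies` freezes one coordinate at its steady-state value (zero
derivative, fluxes still read the frozen value); `clampScan` re-certifies
stability under clamping (destabilized species are flagged and carry no
statistic, the "cross" of the original analysis) and otherwise reruns the
response ensemble with the *identical* perturbation draws as the unclamped
model, reporting

$$
\rho^+_x = \frac{\langle\chi_x\rangle - \langle\chi_{\mathrm{ori}}\rangle}
               {\langle\chi_{\mathrm{ori}}\rangle}
\quad\text{or}\quad
\rho^-_x = \frac{\langle\chi_{\mathrm{ori}}\rangle - \langle\chi_x\rangle}
               {\langle\chi_{\mathrm{ori}}\rangle},
$$

exactly one per species (a tie is reported as "plus" with $\rho = 0$).  The
paired-seed design removes most Monte-Carlo variance from the difference.

`addRandomReactions`/`expandAndMeasure` implement network expansion: uni-uni
reactions between random non-cofactor species, upgraded with probability $p$
(the base model's coupled fraction) to cofactor-coupled bi-bi reactions;
rate constants are bootstrap-resampled from the base model's per-scheme
empirical pools and irreversibilities follow from the base potentials, so
expansions stay thermodynamically consistent.  Species are never added —
only density increases.  Extensions are screened for a unique attractor
before the response protocol runs; multistable and failing extensions are
rejected and counted.  For plug-in models with enzymatic kinetics the three
closed-form rate-law templates (`reversibleMM`, `orderedBiBi`,
`factorizedBiBi`) and the elementary reaction decomposition
(`erdDecompose`, binding/conversion/release steps with a conserved enzyme
moiety) are provided; the Michaelis–Menten-type closed form is recovered
from the decomposed system's quasi-steady state in the tests.  A
growth-rate acceptance hook for expansion is available but disabled by
default (generated models carry no growth dilution).

## Fluctuation-strength estimate

For the motif $\varnothing \xrightarrow{vp} X \xrightarrow{uqx} \varnothing$
with enzyme concentrations $p, q$ independently gamma$(a, b)$ distributed
(the stationary law of bursty transcription/translation), the
quasi-steady-state concentration is $x = vp/(uq)$ and

$$
\langle x\rangle = \frac{v}{u}\frac{a}{a-1},\qquad
\langle x^2\rangle = \frac{v^2}{u^2}\frac{a(a+1)}{(a-1)(a-2)},\qquad
\mathrm{CV} = \sqrt{\frac{2a-1}{a(a-2)}} ,
$$

independent of the scale $b$.  At the proteomics-calibrated shape
$a = 6.82$ the CV is $\approx 62\,\%$; since the irreversible-reaction
assumptions bias this upward, the package's default perturbation strength is
the smaller 40 %.  The link is configuration, not computation.  A
Monte-Carlo oracle (`mcQssNoise`) checks the closed forms to within
statistical error.

## Study conditions and what the tests show

The shipped experiments run at desk scale, chosen once: $N = 16$ backbone
species, grid cells with 128 networks × 32 trajectories (the headline
protocol uses 512 × 128 at $N = 64$); expansion and variant comparisons use
64 paired networks.  At these sizes the package's test suite reproduces,
qualitatively: mean $\chi$ non-increasing in $R$ and non-decreasing in $f$;
the catalytic variant below the $f = 1$ cofactor model (so the cofactor
effect is not mere nonlinearity); expansion by random reactions not
increasing mean $\chi$; and cofactor clamping lowering mean $\chi$.

What passing these tests does **not** show: the generators emulate random
mass-action networks with idealized thermodynamics — no enzyme saturation,
no regulation, no growth dilution (outside the RCRN), no real metabolic
annotation.  Conclusions about real central-carbon metabolism rest on the
original kinetic models, not on these synthetic ensembles; the package's
claim is only that cofactor coupling and backbone sparsity are *sufficient*
to produce strong responses in minimal settings.

## A worked example

```{r example, eval = FALSE}
m  <- generateMinimalModel(nSpecies = 16, nReactions = 23, f = 0.75,
                           beta = 10, seed = 42)
ss <- findAttractor(m)
ens <- responseDistribution(m, ss, nIni = 32, seed = 7)
meanChi(ens)
hist(chis(ens), breaks = 20, main = "P(chi)", xlab = "chi")

## which species' dynamics carry the responsiveness?
clampScan(m, ss, nIni = 32, seed = 7)

## density/coupling sweep (tidy one-row-per-network output)
sw <- runSweep(data.frame(R = c(15, 23, 31), f = 0.75),
               nSpecies = 16, nNetworks = 64, nIni = 32, seed = 1)
aggregate(meanChi ~ R, sw, mean, na.rm = TRUE)
```

## Known limitations

* Exchange intensities are binary ($D_n \in \{0, 1\}$), as in the model
  definition; weaker couplings are represented by rescaling reaction rates.
* Ultra-slow modes (effective rates down to $v_r e^{-\beta\Delta\mu} \sim
  10^{-13}$) cannot be integrated to completion; the residual stopping
  criterion plus Newton polishing handles steady states, and the
  fixed-horizon $\chi$ semantics handles response trajectories.
* Mixed-sign conserved moieties are balanced to cancellation precision
  (about $10^{-12}$ relative), not exactly — the limit of double precision.
* SBML export is not provided; models serialize losslessly to JSON and the
  reaction graph exports to GraphML.
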