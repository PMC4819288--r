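---
title: "Individualized whole-brain network modelling of stroke: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized whole-brain network modelling of stroke: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`virtualstroke` simulates region-averaged BOLD signals from an individual
structural connectome and estimates, per subject, two global parameters
(global coupling $c$, conduction velocity $v$) and three local coupling
gains ($K_{11}$, $K_{12}$, $K_{21}$), the quantities that act as
dynamics-level markers of the post-stroke brain.

## Network evolution equation

Each of the $N$ parcellation regions carries a Stefanescu–Jirsa 3D (SJ3D)
neural mass, a mode-level reduction of a population of Hindmarsh–Rose
bursting neurons.  Region $i$'s excitatory mean field
$x_i(t) = \sum_q w_q \xi_{iq}(t)$ evolves under its local dynamics plus
linearly superposed, delayed input from every connected region:

$$\dot X_i = f\!\left(X_i(t)\right) + c \sum_j w_{ij}\, x_j(t - \Delta_{ij})
  \, e_{\xi} + \eta(t),$$

where $w_{ij}$ are the connection weights, $\Delta_{ij} = L_{ij} / v$
converts tract length (mm) and conduction velocity (m/s) into a delay in
ms, the afferent input enters only the excitatory membrane equations
($e_\xi$), and $\eta$ is additive white noise.

## The SJ3D local model

Per mode $q$ (three modes by default) the six state families are the
excitatory membrane potential $\xi$, fast recovery $\eta$ and slow
adaptation $\tau$, and their inhibitory counterparts $\alpha, \beta,
\gamma$:

$$\begin{aligned}
\dot\xi_q   &= \eta_q - a\xi_q^3 + b\xi_q^2 - \tau_q
  + K_{11}(\bar x - \xi_q) - K_{21}(\bar\alpha - \xi_q) + IE_q + A_i \\
\dot\eta_q  &= c - d\xi_q^2 - \eta_q \\
\dot\tau_q  &= rs(\xi_q - x_0) - r\tau_q \\
\dot\alpha_q &= \beta_q - a\alpha_q^3 + b_{\mathrm{inh}}\alpha_q^2 - \gamma_q
  + K_{12}(\bar x - \alpha_q) + II_q \\
\dot\beta_q  &= c - d_{\mathrm{inh}}\alpha_q^2 - \beta_q \\
\dot\gamma_q &= rs(\alpha_q - x_0) - r\gamma_q
\end{aligned}$$

with $\bar x = \sum_k w_k \xi_k$ and $\bar\alpha = \sum_k w_k \alpha_k$
the quadrature-weighted mean fields.  Defaults: $a=1$, $b=3$, $c=1$,
$d=5$, $r=0.006$, $s=4$, $x_0=-1.6$, $\mu=2.2$, $\sigma=0.3$.  The pair
of constants (4, 5) listed for the inhibitory populations is interpreted
as the inhibitory membrane-equation analogues of $b$ and $d$
($b_{\mathrm{inh}}=4$, $d_{\mathrm{inh}}=5$); the state variables
$\beta,\gamma$ are distinct objects that merely reuse the letters.

**Mode reduction.** The distribution of input currents across the
population is $N(\mu, \sigma^2)$; `derive_modes()` discretizes it with an
$M$-point Gauss–Hermite rule, $I_q = \mu + \sqrt{2}\sigma t_q$, and the
normalized quadrature weights $w_q$ both weight the mean field and define
the mode-mixing matrices of the $K$ couplings (every membrane equation
sees the weight-averaged field of the source subpopulation).  The exact
mixing matrices of the original reduction are not printed in the source
material; the quadrature-consistent choice here is isolated in the
`mode_set` object so an alternative can be swapped in without touching the
integrator.  With $\sigma = 0$ the modes coincide; the weights are then
set uniform, a documented special case that is dynamically equivalent.

## Numerical integration

The network SDE is integrated with the stochastic Heun scheme (additive
noise): one Gaussian increment $E = \sigma_\eta \sqrt{dt}\, Z$ per state
per step is shared by predictor and corrector.  Deterministically the
scheme is second order (verified against $\dot x = -x$); with pure noise
the increment variance is exactly $\sigma_\eta^2\, dt$.  Conventions that
matter:

* **Step size.** The native step is 0.0122 ms.  Tests and desk-scale
  experiments use a coarsened 0.1 ms step; this is purely a runtime
  scaling.
* **Noise placement.** "SD 1 white noise added to each node" does not
  specify equations.  At the native step, noise on all six families is
  stable and is the default.  At the coarsened step the slow adaptation
  variables (damping rate $r = 0.006$/ms, stationary SD
  $\approx \sqrt{1/2r} \approx 9$) eject the state past the cubic
  stability boundary, so every coarse-step run uses the exposed
  membrane-only mask (noise entering through the membrane potentials,
  i.e. input-current fluctuations).  This was established from the
  stability analysis, not tuned to any result.
* **Delays.** $\Delta_{ij}$ in integration steps is
  `round(L/v/dt)` with a minimum of 1 step on every existing edge; the
  "zero-delay" mode is the same one-step lag, which makes the
  $v \to \infty$ limit and the dedicated flag coincide exactly.
* **Coupling-side weight scaling.** Raw streamline capacities span orders
  of magnitude ($\sim e^{10}$); feeding them into $c\sum w x$ diverges
  instantly.  Whether the source pipeline used raw, log or normalized
  weights is not stated, so the transform is configuration
  (`weight_transform`), defaulting to division by the largest weight.
  The $c \cdot w$ scaling invariance is tested under the `"raw"`
  transform, where it is non-trivial.
* **Determinism.** Initial conditions (uniform box around the membrane
  rest point) come from R's RNG; the integrator's noise comes from a
  self-contained mt19937-64 + ziggurat sampler in C++.  Both derive from
  the configuration seed, so trajectories are bitwise reproducible.
  Incoming edges are summed in a value-ordered sequence so region
  relabelling permutes trajectories exactly.

## Hemodynamics

BOLD is the causal convolution of the recorded mean field with a gamma
kernel (shape 6, scale 1 s, support 25 s, unit sum — the canonical
single-gamma response peaking at 5 s; only "gamma kernel" is specified
upstream, so the parameters are configuration).  The convolved signal is
sampled at $t = k \cdot TR$ (TR = 2 s); the mean field is block-averaged
at a 1 ms recording stride beforehand, which acts as the anti-alias
stage.  The first kernel-length of output is flagged as hemodynamic
transient and excluded from all fit metrics.

# Parameter estimation

Estimation is sequential, as in the protocol this package reproduces:

1. **Exploration** (`explore_global`): short stochastic simulations on a
   (coupling, velocity) grid, each cell with a counter-derived seed;
   the map records global variance (mean over regions of the temporal
   variance of the mean field, computed on the neural signal before any
   BOLD derivation).  Exploration runs are 30 s by default — variance
   estimates stabilize much earlier than spectra.
2. **Range selection** (`select_range`): high-variance cells are those at
   or above the 0.75 map quantile (quantile thresholds make the selection
   invariant to monotone rescaling); "bifurcation" boundaries are grid
   jumps exceeding 5 times the median absolute discrete derivative (or
   half the largest jump when the map is mostly flat).  The selection is
   the largest contiguous high-variance box; ties break toward lower
   coupling.
3. **Fitting** (`fit_parameters`): per candidate, simulate, derive BOLD,
   and score three metrics against the target — absolute difference of
   mean amplitudes, absolute difference of spectral peak frequencies, and
   the correlation between the candidate's FC matrix and the reference FC
   ("phase").  The metrics live on incommensurate scales and no weights
   are specified upstream, so they are combined by rank aggregation; the
   minimal combined rank wins, ties toward lower coupling.  All
   candidates share one noise seed (common random numbers), which makes
   the procedure deterministic, reduces comparison variance, and makes
   the self-fit case exact.  Local gains are swept one-dimensionally
   (K12, then K21, then K11) after the global stage, holding current
   bests — a joint 10³ local grid would be out of scale for n-of-one
   clinical fitting.

# The synthetic world

No imaging data ships with the package; `synthetic_data` generates every
input at stated, fixed conditions:

* **Connectomes** (`generate_connectome`): 96 regions on two mirrored
  hemispheric shells (radius 70 mm ± 10%, the medial fifth of each
  hemisphere pulled inward as "subcortical"), edge probability
  $\propto e^{-d/60\,\mathrm{mm}}$ scaled to density 0.35, tract length =
  Euclidean distance × 1.2 (fixed tortuosity).  The printed control
  cohort summary (mean 10.16 ± 1.03, range 8.75–12.07 on the log-weight
  scale) is interpreted as the *across-subject* distribution of
  per-connectome mean summaries: a width-3.32 interval cannot support a
  within-connectome SD of 1.03 (the uniform bound is 0.96), whereas 11
  subject means of SD 1.03 have an expected range of almost exactly the
  printed one.  Each connectome draws its subject-level mean from a
  truncated normal over the printed range whose parent mean is solved so
  the truncated mean equals 10.16; edge log-weights scatter around it
  with SD 1.0 (within-connectome spread is not a calibration target; the
  near-zero printed skewness motivates the symmetric choice).
* **Virtual lesions** (`apply_virtual_lesion`): an MCA-like contiguous
  block of 10 left-hemisphere regions (most lateral region plus nearest
  neighbours, spanning cortical and subcortical labels); all incident
  edges scaled by $1-s$.  The default severity $s = 0.867$ is the unique
  value for which the expected incident-edge fraction (0.1985 for 10 of
  96 regions) shifts the mean summary from the control 10.16 to the
  stroke cohort's 9.76: $0.1985 \ln(1-s) = -0.40$.  The mean summary
  decreases monotonically in $s$ up to, but not including, the complete
  lesion: at $s = 1$ the incident edges vanish from the nonzero-edge
  summary entirely and the summary rebounds — an inherent property of
  nonzero-edge statistics, noted rather than hidden.
* **Ground-truth BOLD** (`generate_ground_truth_bold`) provides fitting
  targets at known parameters for recovery experiments.
* **Clinical tables** (`generate_clinical_table`): parameters uniform
  within the stroke cohort's fitted ranges; Fugl–Meyer (post and
  maintenance) decreases with $K_{12}$ at −20 points per unit gain and
  the maintenance WMFT increases with coupling at +24 points per unit —
  both correspond to correlations of $|r| \approx 0.6$ at the default
  noise (5 Fugl–Meyer points, 0.4 WMFT points), the moderate effect-size
  regime of the reported significant regressions.  Demographics and
  lesion characteristics are drawn from plausible ranges and carry no
  planted effect.

What a green test does **not** establish: the generator has no
subject-level geometry variation beyond the seed, no hemispheric weight
asymmetry, no spatial autocorrelation of weights beyond the distance
kernel, and its BOLD comes from the same forward model used in fitting —
recovery results therefore measure internal consistency of the pipeline,
not robustness to model misspecification.

# Known limitations

* **Velocity identifiability.** In a frozen 12-node recovery world
  (150 mm shells, membrane noise 0.3, truth at coupling 0.5 / velocity
  10 m/s / $K_{21}$ 0.5 on a 5×5(×5) grid, 60 s of transient-free BOLD),
  ten seeded repetitions recover coupling within one grid step 9/10 times
  and $K_{21}$ 10/10, but velocity only 6/10.  Conduction delays (ms)
  act far below the BOLD timescale; their only robust BOLD signature here
  is amplitude suppression at very slow velocities, and the spectral-peak
  and FC metrics on 30-sample series are noise-dominated, so rank
  aggregation can override the informative amplitude metric.  The joint
  recovery criterion is asserted as stated in the acceptance suite and is
  expected to fail on the velocity component; this mirrors the marginal
  velocity contrast in the empirical cohort the pipeline models.
* **Statistical design.** Which covariates entered the original
  regressions jointly is not recoverable; `regress_outcomes` takes an
  explicit formula and defaults to the reported orientation (model
  parameters as dependent variables), with the predictive orientation
  available by swapping the formula.
* The control-cohort global-coupling row of the source summary table
  (range 0.044–0.047, mean 0.053) is internally inconsistent; no value
  from it is treated as ground truth anywhere.
* Config serialization is JSON only; trajectory containers are
  plain-text + JSON header rather than a binary format.

# Reproducibility

A single base seed expands into per-stage, per-subject and per-grid-cell
seeds via `derive_seed(seed, counter)` (a fixed affine map modulo
$2^{31}-1$).  Identical configuration and seed give byte-identical
trajectories, maps, fit tables and cohort reports.
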