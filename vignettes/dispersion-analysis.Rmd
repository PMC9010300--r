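---
title: "Quantifying micro-to-millisecond conformational exchange from CPMG relaxation dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micro-to-millisecond conformational exchange from CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgdisp)
library(dplyr)
```

## The physical problem

Many proteins interconvert between a dominant ("ground") conformation and
weakly populated ("excited") conformers on the microsecond-to-millisecond
timescale.  The excited states are invisible in ordinary spectra, but the
exchange broadens the observable resonances: the effective transverse
relaxation rate $R_{2,\mathrm{eff}}$ of a nucleus depends on how often a
train of refocusing pulses interrupts the dephasing caused by jumping
between environments.  In a Carr-Purcell-Meiboom-Gill (CPMG) experiment the
pulse rate $\nu_\mathrm{CPMG}$ is varied and the resulting *dispersion
curve* $R_{2,\mathrm{eff}}(\nu_\mathrm{CPMG})$ is fit to a two-state
exchange model, yielding the exchange rate $k_\mathrm{ex} = k_{AB} +
k_{BA}$, the excited-state population $p_B$, and per-nucleus chemical-shift
differences $\Delta\omega$ between the states.  Methyl-TROSY versions of
the experiment extend this to large systems such as the 42-kDa actin
monomer, with isoleucine delta-1 methyls as probes; comparing the
reconstructed excited-state chemical shifts between ligand states (ATP- vs
ADP-bound) then discriminates among 2-, 3- and 4-state conformational
equilibria.

This vignette documents the models, the estimation procedure, the synthetic
data generator, and the numerical and design choices behind the package.

## Forward models

All forward models treat two-state exchange $A \rightleftharpoons B$ with
$k_{AB} = p_B\,k_\mathrm{ex}$, $k_{BA} = (1 - p_B)\,k_\mathrm{ex}$ and equal
intrinsic relaxation of the two states (a single exchange-free rate $R_2^0$
per curve; the data give no handle to separate ground- and excited-state
intrinsic rates at $p_B \ll 1$).

The constant-time CPMG element of duration $T_\mathrm{relax}$ contains $N$
180-degree refocusing pulses, with the convention $\nu_\mathrm{CPMG} = N /
T_\mathrm{relax}$; requested frequencies are snapped to the nearest integer
$N$ and a warning is raised if the relative snap error exceeds 2%.

**Single quantum (SQ).**  The transverse magnetisation 2-vector evolves
under $L = K + i\,\mathrm{diag}(0, \Delta\omega)$ between pulses, and each
180-degree pulse conjugates the coherence.  The package propagates the
exact echo-pair operator $A\bar A\bar A A$ (with $A = e^{L\delta}$,
$\delta = T_\mathrm{relax}/2N$) through its spectral decomposition —
closed-form $2\times 2$ exponentials, eigenvalue powers — so the result is
exact for any finite $N$, including the amplitude ("end") effects that the
classical Carver-Richards dominant-eigenvalue expression neglects.  The
textbook Carver-Richards form is provided separately
(`carver_richards_r2eff()`) as a reference; we found it deviates from the
exact propagator by several s$^{-1}$ at $p_B \approx 0.2$ in slow exchange,
which is why the exact spectral solution is the fitting workhorse.  In fast
exchange both reduce to the Luz-Meiboom law, which the test suite asserts
to better than 1%.

**Multiple quantum (MQ).**  The methyl $^1$H/$^{13}$C MQ coherence passes
alternately through double-quantum (frequency $\Delta\omega_H +
\Delta\omega_C$) and zero-quantum ($\Delta\omega_H - \Delta\omega_C$)
evolution as the $^{13}$C refocusing train interchanges the two; the
ground-state component is detected.  One echo pair is propagated by
$A B B A$ with $A, B$ the DQ and ZQ interval exponentials.  Two properties
pin this model down: at $\Delta\omega_H = 0$ it reduces *exactly* to the SQ
propagator, and it is sensitive to the *relative sign* of $\Delta\omega_H$
and $\Delta\omega_C$ — we note (and assert in tests) that any model that
prepares and detects DQ and ZQ symmetrically is provably blind to that
relative sign, so the alternating single-channel structure is essential.
MQ pulse counts are even by construction, which caps the 80-1000 Hz grid at
960 Hz for $T_\mathrm{relax} = 25$ ms.

Every closed-form curve is verified against `bloch_mcconnell_r2eff()`, an
independently coded brute-force propagator that steps pulse by pulse
through the train with generic matrix exponentials; the two routes agree to
numerical precision over a seeded grid spanning $k_\mathrm{ex} \in [100,
3000]$ s$^{-1}$, $p_B \in [0.005, 0.2]$, $|\Delta\omega_C| \le 3$ ppm,
$|\Delta\omega_H| \le 0.3$ ppm at both fields.

Unit conversions use a single constant, `GAMMA_C_OVER_H = 0.251450` (the
$^{13}$C/$^1$H frequency ratio), applied only inside the propagators;
fitted $\Delta\omega$ are stored in ppm (signed as excited minus ground) so
they are field-independent.

## Fitting

`fit_single_residue()` minimises $\sum \left((R_{2,\mathrm{eff}}^\mathrm{obs}
- R_{2,\mathrm{eff}}^\mathrm{calc})/\sigma\right)^2$ over all curves of one
residue simultaneously.  Because $R_2^0$ enters the model additively, the
per-curve intrinsic rates are profiled out in closed form (variable
projection), leaving four nonlinear parameters.  The objective is
multimodal, so the optimiser (Levenberg-Marquardt, `minpack.lm`) restarts
from a $6 \times 5$ grid of $k_\mathrm{ex} \in \{100, 250, 500, 1000, 2000,
3000\}$ s$^{-1}$ $\times$ $p_B \in \{0.005, 0.01, 0.05, 0.1, 0.2\}$,
refines each node and keeps the best; the opposite relative sign of
$\Delta\omega_H$ is tried from the best node.  Bounds: $k_\mathrm{ex} \in
(10, 10^4)$ s$^{-1}$, $p_B \in (10^{-4}, 0.5)$ (the upper bound breaks the
$p_B \leftrightarrow 1 - p_B$ labelling symmetry), $\Delta\omega_C \in [0,
6]$ ppm (magnitude; SQ data are sign-blind and MQ fixes only the relative
sign, carried by $\Delta\omega_H \in [-1, 1]$ ppm), $R_2^0 \in (0, 200)$
s$^{-1}$.  Flat profiles (amplitude below twice the median noise) are
flagged unidentifiable rather than reported with spurious precision.

`fit_global()` shares $(k_\mathrm{ex}, p_B)$ across residues, keeps
per-residue $\Delta\omega$ (in ppm, shared across fields) and per-curve
$R_2^0$ (per residue, coherence type and field).  It starts from the
consensus (median) of the individual fits plus three coarse
$(k_\mathrm{ex}, p_B)$ nodes — with per-residue fits already in hand, a
full grid at the global stage buys nothing and costs a lot.  Discordant
residues are pruned iteratively: after each global fit, each residue's
share of the global chi-square (`chi2_group`, over the same points and
sigmas as its individual fit) is compared with its individual `chi2_indiv`,
and all residues with ratio $> 2$ (strict) are removed together before
refitting, for at most 10 iterations; ties at exactly 2 are retained, and a
`prune_worst_only` mode removes one residue at a time.  Convergence uses
relative tolerances of $10^{-10}$ in the Levenberg-Marquardt steps.

Parameter uncertainties are one-sigma values from the covariance matrix
(inverse curvature at the optimum, with the per-curve $R_2^0$ columns
included analytically); the matrix is rescaled to unit diagonal before
(pseudo-)inversion because the parameters span seven orders of magnitude in
units, and directions with vanishing curvature are reported as infinite
errors.  `estimate_errors(fit, bootstrap = n)` cross-checks the covariance
errors by parametric bootstrap, and a Monte-Carlo calibration test asserts
the covariance errors match the empirical scatter of repeated fits within a
factor of two.

Per-point sigmas come from replicated $\nu_\mathrm{CPMG}$ measurements:
the intensity noise of each dataset (experiment $\times$ field) is the
pooled standard deviation over all replicate groups ($n-1$ denominators),
floored by the nominal spectral noise when supplied, and propagated as
$\sigma_{R_2} = \sigma_I / (T_\mathrm{relax}\, I)$.

Residues enter the global analysis when their dispersion amplitude
$\Delta R_2$ — $R_{2,\mathrm{eff}}$ at the slowest minus the fastest
pulsing rate, endpoint replicates averaged — exceeds 2 s$^{-1}$ in any
experiment (`classify_dynamic_residues()`).

## Shift analysis and state-model discrimination

The combined chemical-shift perturbation between two ligand states is
$\Delta = \sqrt{(\delta^{1}\mathrm{H})^2 + (0.25\,\delta^{13}\mathrm{C})^2}$
ppm; `flag_perturbed()` supports both the mean-over-residues threshold
(default) and a fixed 0.04 ppm cutoff.

Dispersion fitting yields only $|\Delta\omega_C|$; the sign comes from
comparing exchange-shifted peak positions between HSQC- and HMQC-type
spectra (or between two fields).  Predicted positions use the imaginary
part of the slowest-decaying eigenvalue of the free-precession evolution
matrix of each coherence (the HMQC $^{13}$C-dimension position is the
DQ/ZQ half-difference), not a full lineshape simulation — standard and
adequate at $p_B \ll 1$, and testable against the propagator.  The SQ-MQ
position difference is second order in $\Delta\omega_H$, so it is resolvable
only for residues with appreciable $^1$H shift differences;
`determine_sign()` returns "undetermined" (NA) whenever the predicted
separation is below the supplied position uncertainty, and undetermined
residues propagate both reconstruction candidates flagged `ambiguous`.
Excited-state shifts are $\delta^* = \delta_\mathrm{ground} +
\mathrm{sign}\cdot|\Delta\omega|$ per nucleus, with the fitted
$\Delta\omega_H$ following the sign of $\Delta\omega_C$ (the MQ model is
invariant under a joint flip), and uncertainties combined in quadrature.

`compare_state_models()` formalises the scatter-plot comparison of the four
shift tables (ATP, ADP grounds; ATP*, ADP* excited).  A two-state
equilibrium requires ATP* to coincide with ADP; a three-state equilibrium
requires ATP* to coincide with ADP*; if neither holds the minimal model has
four states.  Residues whose ground-state shifts already differ between the
nucleotides ("boxed") are excluded, since nucleotide chemistry alone can
explain their differences.  The visual judgement is made computable with
two knobs, both exposed: a residue is off-diagonal when its $^{13}$C
difference exceeds $z = 3$ pooled sigmas, and a pair of states is
discordant when at least `min_off = 2` residues are off-diagonal (one
outlier never decides a global verdict).  $^{13}$C shifts drive the
verdict, matching how the comparisons are usually drawn; $^1$H columns ride
along in the tables as secondary evidence.

## The synthetic-data generator

`simulate_dispersion()` emulates the study design so the whole pipeline is
testable without any download.  The built-in scenarios use the reported
global parameters as ground truth:

| scenario | $k_\mathrm{ex}$ (s$^{-1}$) | $p_B$ | dispersive residues | experiments |
|---|---|---|---|---|
| ATP   | 510  | 0.83% | 9 (I64...I327) | MQ + $^1$H SQ, 600 & 800 MHz |
| ADP   | 1194 | 10%   | 6 (I34...I317) | MQ + $^1$H SQ, 600 & 800 MHz |
| K118N | 450  | 1.6%  | 9 (as ATP)     | MQ + $^{13}$C SQ, 600 & 800 MHz |

MQ grids are 80-880 Hz (600 MHz) and 80-960 Hz (800 MHz) at
$T_\mathrm{relax} = 25$ ms (even pulse counts); $^1$H SQ grids run
66.7-1000 Hz at 30 ms (ATP) or 80-1000 Hz at 25 ms (ADP).  Per-residue
truths are drawn per seed: $|\Delta\omega_C| \sim U(0.5, 2.5)$ ppm with
random signs for dispersive residues (zero otherwise), $|\Delta\omega_H|
\sim U(0, 0.05)$ ppm for the ATP-like scenarios (their $^1$H SQ dispersions
stay below ~1 s$^{-1}$) and $U(0.02, 0.08)$ ppm for ADP, where the $^1$H
contribution is substantial (2-5 s$^{-1}$) without overwhelming the
profiles; intrinsic rates $R_2^0 \sim U(8, 25)$ s$^{-1}$ per curve.
Gaussian noise is added at the intensity level (default 0.5% of the
reference intensity, giving $\sigma_{R_2} \approx 0.2$-$0.4$ s$^{-1}$,
the order of magnitude of typical error bars), the reference point included;
600 MHz datasets carry two replicated frequencies and 800 MHz three, and
the data then pass through the same intensity-to-rate reduction as real
measurements.  24 resolved residues are generated; the three overlapped
isoleucines are omitted by default since overlap handling is out of scope.

What the generator does *not* emulate: spectral artifacts (off-resonance
effects, pulse miscalibration), peak overlap, baseline and phasing errors,
temperature instability, or deviations from two-state kinetics.  Passing
recovery tests therefore demonstrates the correctness and calibration of
the estimation machinery under the stated noise model, not robustness to
every pathology of real spectra.

`simulate_shift_tables()` instantiates the 2-/3-/4-state hypotheses with a
configurable conformational separation scale (offset magnitudes are drawn
in $[0.5, 1.5]\times$ scale so the scale is meaningful), including boxed
residues to exercise the exclusion logic, and `simulate_sign_inputs()`
produces SQ/MQ peak positions from the eigenvalue oracle plus position
noise.

## Recovery performance and problem sizes

The acceptance-style tests run the full pipeline on ten seeds per scenario
(24 residues, four experiments, ~1300 points each; a few seconds per seed
with the spectral engine) and require the median recovered parameters to
fall inside the reported one-sigma bands: $510 \pm 80$ s$^{-1}$ /
$0.83 \pm 0.09$% (ATP), $1194 \pm 154$ s$^{-1}$ / $10 \pm 2.4$% (ADP),
$450 \pm 55$ s$^{-1}$ / $1.6 \pm 0.2$% (K118N); correctly specified fits
give reduced $\chi^2$ in $[0.7, 1.3]$, and the seed-paired ADP/ATP
population ratio recovers the ~12-fold difference within 25%.
`scripts/acceptance.R` recomputes the fold-change from scratch.

## Known limitations

Two-state exchange only (no three-site forward models); no temperature
series; covariance (plus optional bootstrap) errors rather than Bayesian
posteriors; errors may be underestimated if the true process has more than
two states.  The MQ propagator assumes even pulse counts and perfect,
infinitely short pulses.  Sign determination degrades gracefully to
"undetermined" when $\Delta\omega_H$ is small, which is common for
methyls.  Whether individual fits use the analytical or numerical model is
moot here because the two agree to numerical precision; the brute-force
propagator is retained purely as an independent check.

## A worked pipeline

```{r pipeline, eval = FALSE}
d <- simulate_dispersion(scenario_spec("ATP"), seed = 1)
dyn <- classify_dynamic_residues(d, threshold = 2)
fit <- d |> filter(residue %in% dyn$residue) |> fit_global()
glance(fit)
autoplot(fit)

signs <- tibble(residue = fit$residues$residue, sign_c = 1)
ground <- tibble(residue = fit$residues$residue,
                 delta_h_ppm = 0.7, delta_c_ppm = 12, sigma_h = 0.002, sigma_c = 0.01)
excited <- reconstruct_excited_shifts(ground, fit, signs)
```
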