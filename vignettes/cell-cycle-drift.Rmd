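---
title: "Heritable cell-cycle timing, FUCCI dynamics and epigenetic drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritable cell-cycle timing, FUCCI dynamics and epigenetic drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdrift)
```

`ccdrift` models proliferating mammalian cell populations in which the
*timing* of the cell cycle is heritable: progeny cells inherit a fraction
of their parent's phase durations, siblings share correlated noise, and
those family correlations reshape the long-run composition of the
population. The package provides the simulator (phase durations, FUCCI
reporter proteins, full pedigrees), the estimators that recover the model
from observed pedigrees and fluorescence trajectories, and a
Wright–Fisher-style analysis that quantifies the resulting lineage
dominance — "epigenetic drift" — through an effective population size.

This vignette explains the models, their assumptions, the tunable
parameters (with units and defaults), the numerical choices and the design
decisions where the design was genuinely open.

## 1. Bifurcating autoregression of phase durations

Cell-cycle time is split into two aggregated phases, G1 and S/G2/M, which
are modelled *independently* (their empirical cross-correlation is low).
For a parent with phase duration $T$, the two progeny durations follow

$$T^i \;=\; m \;+\; \theta\,(T - m)\;+\;W^i, \qquad i = 1,2,$$

where $\theta \in [0,1)$ is the inherited fraction, $m$ (hours) is a
location constant, and $(W^1, W^2)$ is an *exchangeable bivariate
lognormal* noise pair: the componentwise exponential of a bivariate normal
with common mean $\mu$, common variance $\sigma^2$ and correlation $\rho$.
The lognormal choice respects the non-negativity and positive skewness of
measured phase durations. On the natural scale the noise pair has
correlation $(e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)$.

At equilibrium (which the chain reaches from any starting value because
$|\theta| < 1$),

$$\mathrm{E}(T) = m + \frac{e^{\mu+\sigma^2/2}}{1-\theta}, \qquad
\mathrm{Var}(T) = \frac{e^{2\mu}e^{\sigma^2}(e^{\sigma^2}-1)}{1-\theta^2},$$

$$\rho_{\text{sib}} = \theta^2 + (1-\theta^2)\,
\frac{e^{\rho\sigma^2}-1}{e^{\sigma^2}-1},
\qquad \rho_{\text{parent}} = \theta, \qquad
\rho_{\text{cousin}} = \rho_{\text{sib}}\,\theta^2 .$$

The cousin relation deserves a note: each cousin regresses on its own
parent with slope $\theta$ and the two parents are themselves a sibling
pair, so the factor is $\theta^2$ (not $\theta$). Simulated pedigrees
confirm this (`stationary_moments()` and the property tests).

Draws that would produce a non-positive duration (possible when
$\theta(T-m)$ is very negative) are redrawn, up to 100 attempts per
division; for all parameter ranges used here the event is vanishingly
rare, so the autoregressive form is preserved without truncation bias.

### Estimation by the method of moments

Given sample moments of a pedigree — mean, variance, the sibling
correlation on *symmetrized* pairs (each unordered pair contributes both
orders; the natural convention for exchangeable pairs) and the
parent–progeny correlation — the parameters are recovered by exact
inversion at an assumed noise correlation $\rho$:

1. $\hat\theta = \hat\rho_{\text{parent}}$.
2. $\hat A = (\hat\rho_{\text{sib}} - \hat\theta^2)/(1-\hat\theta^2)$,
   which must lie in $(0,1)$; $\hat\rho_{\text{sib}} < \hat\theta^2$ means
   the model cannot explain the data and is reported as an error.
3. $\sigma^2$ solves the transcendental equation $x^{\rho}-1 = \hat A(x-1)$
   with $x = e^{\sigma^2} > 1$. A root exists iff $\rho > \hat A$; it is
   found by bracketed bisection (bracket grown geometrically, cap
   $10^{12}$, residual tolerance $10^{-12}$). The root tends to 1 as
   $\rho \downarrow \hat A$ (vanishing noise variance) and diverges as
   $\rho \to 1$; past the bracket cap the solver reports non-convergence
   rather than a spurious root.
4. $\hat\mu$ and $\hat m$ follow by inverting the variance and mean
   relations.

Because the inversion is exact, `estimate_params()` composed with
`stationary_moments()` is the identity on feasible parameter sets (tested
at $10^{-9}$).

$\rho$ itself is not identified by these moments. `profile_rho()` scans a
grid of candidate values, simulates a large equilibrium sample at each
fully-determined parameter set, and picks the candidate minimizing the
Kolmogorov–Smirnov distance to the observed durations. The KS criterion is
this package's choice; nothing in the moment structure dictates it.

Near the feasibility boundary the estimator is intrinsically fragile: as
$\sigma^2 \to 0$, $A \to \rho$, so for small noise variances the sample
$\hat A$ sits within a sampling error of $\rho$ and the solve can fail for
a sizeable share of datasets. This is a property of the method, not of the
implementation; estimator validation is therefore run at moderate
$\sigma^2$, and infeasible draws are reported, not retried.

Pedigrees observed through a fixed time window (like 72 h films)
under-represent slow-cycling parents, which attenuates the estimated
correlations. `simulate_pedigree_generations()` produces depth-limited,
censoring-free pedigrees for estimator validation;
`simulate_population()` reproduces the windowed-observation situation.

### Default parameter sets

The empirical aggregates pin the marginal scale: total cycle time with
mean 20.4 h and CV 0.30 (15% serum), G1 taking roughly 45% of the cycle
and carrying most of the variability, and stronger inheritance of S/G2/M
than of G1. `default_phase_params()` encodes one concrete choice:

| phase | mean (h) | CV | $\theta$ | $\rho_{\text{sib}}$ | $\rho$ |
|-------|---------|------|-------|------|------|
| G1 | 9.2 | 0.52 | 0.25 | 0.50 | 0.55 |
| S/G2/M | 11.2 | 0.34 | 0.40 | 0.65 | 0.65 |

The noise correlations $\rho$ are chosen so that the implied log-scale
variances come out moderate ($\sigma^2 \approx 0.6$–0.7), giving
realistically skewed (not pathologically heavy-tailed) duration
distributions. These are the synthetic generator's ground truth — the
fitted values for any real dataset should come from the estimators.

## 2. FUCCI reporter dynamics

Within one cycle of length $T_C$ with G1/S transition at $T_{G1}$, the
Cdt1 and Geminin reporter amounts follow linear ODEs with phase-dependent
degradation:

$$\dot C = p_C - d_C\,C - a\,(t-T_{G1})^+\,C, \qquad
\dot G = p_G - d_G\,G - b\,(T_{G1}-t)^+\,G .$$

Production rates are constant within a cell; degradation has a constant
background plus a linear ramp that switches on after (Cdt1) or before
(Geminin) the G1/S transition — a deliberately coarse stand-in for the
APC/SCF-mediated proteolysis program. The constants are shared by all
cells: $d_C = 0.08$/h, $d_G = 0$ (exactly; the ramp alone drives G1 decay
of Geminin), $a = 0.088$/h², $b = 0.124$/h², and heuristic factors
$\vartheta_C = 6$, $\vartheta_G = 4$ linking peak levels to rates
($p_C = C_{G1}/T_{G1}\cdot\vartheta_C$, $p_G =
G_{end}/T_{SG2M}\cdot\vartheta_G$).

**Integration.** The ODEs are scalar and linear, so each fixed-step RK4
update is affine in the state; the whole trajectory is obtained from a
cumulative product/sum over the per-step affine coefficients — bit-identical
to the step-by-step loop but vectorized (internal step 0.01 h, output
every 0.25 h to match 15-min imaging). When cumulative decay is so strong
that the product scan would underflow (possible for extreme phase
durations), the integrator falls back to the plain recurrence. Tests
verify the G1 closed form to $10^{-8}$, an independent fine-step reference
integrator to $10^{-6}$, and 4th-order step-halving convergence.

**Per-cell fitting.** With degradation fixed, the solution is affine in
the production rate, so the least-squares rate given an observed
trajectory is a closed-form projection onto the unit-production particular
solution (clipped at zero). No iteration is needed — a simplification the
linearity makes exact.

**Unequal division.** At mitosis each protein amount is split by an
independent $\mathrm{Beta}(\alpha,\alpha)$ fraction with mean ½. The
primitive parameter is the coefficient of variation of the split,
$cv = 0.13$ by default, with $\alpha = (cv^{-2}-1)/2 \approx 29.09$. (The
same quantity is sometimes quoted rounded as 29.3; the package
exposes $cv$ and derives $\alpha$.) Mass conservation
at division is exact by construction. Split asymmetry does not feed back
on durations, and a regression test confirms duration statistics are
invariant to $cv$ over [0.05, 0.3].

**Production-rate regressions.** New-born cells draw
$p_C = a_{G1} + r_{1,G1}T_{G1} + r_{2,G1}C_0 + \varepsilon$ (and the
analogous $p_G$ on $T_{SG2M}, G_0$), with the $\varepsilon$ pair bivariate
normal *between siblings* ($\rho_{p_C} = 0.66$, $\rho_{p_G} = 0.54$),
reproducing strong sibling and weak parent–progeny correlation of protein
dynamics. Negative draws are clipped to zero and counted. Coefficients are
not universal constants; the defaults are the synthetic generator's ground
truth, chosen so that the birth-amount feedback loop (birth amount →
production rate → division amount → birth amount) has gain below one and
marker levels stay stationary along lineages. On data they are
re-estimated by ordinary least squares (`estimate_production_regression()`).

## 3. Endpoint detection on noisy trajectories

`annotate_trajectory()` recovers division times and G1/S transitions from
a tracked fluorescence trace:

1. **Noise estimate and smoothing.** Local quadratic regression (loess,
   direct fit). The window defaults to $40\,\hat\sigma_{\text{rel}}$ hours
   clamped to [1, 4] h, where $\hat\sigma_{\text{rel}}$ is the median
   relative residual of a first-pass fit — about 2 h at the default 5%
   noise. Tracks whose noise exceeds 50% or whose signals are flat are
   flagged (`high-noise`, `flat-signal`) and not processed.
2. **Differentiation.** Central differences on the uniform grid.
3. **Divisions.** Local minima of the Geminin derivative deeper than 6×
   its MAD (a spike-robust scale — division drops are an order of
   magnitude deeper than noise excursions), with a 5 h minimum separation;
   where two candidates collide the deeper wins.
4. **G1/S transitions.** The maximum of the smoothed Cdt1 signal between
   consecutive divisions. The Cdt1 channel is smoothed with a window of at
   least 2 h: its peak is a broad, low-frequency feature whose argmax
   jitters under noise, unlike the sharp division spike. Maxima within
   1 h of either division are failed as `peak at boundary` (both phases
   last hours; a maximum hugging a division indicates mistracking).

Complete, quality-passing cycles yield $T_{G1} = t_{G1S} - t_{\text{birth}}$
and $T_{SG2M} = t_{\text{div}} - t_{G1S}$.

**A known, physical bias.** Under the ramped degradation model the Cdt1
maximum does not occur at $T_{G1}$: the marker keeps rising until the ramp
overtakes production, roughly $(p_C/C - d_C)/a \approx$ 0.5–1.5 h later.
The argmax estimator of the transition therefore carries that lag even on
noiseless data. Division times are free of this effect (recovered within
one 0.25 h frame on noiseless synthetic films, away from film edges).
Correlation-based inheritance estimates are insensitive to the
constant part of the lag; its cell-to-cell variation plus peak-argmax
noise attenuate them mildly.

## 4. Population simulation

`simulate_population()` runs an event-driven, continuous-time simulation:
divisions are processed in chronological order (ties broken by cell
index), each division drawing progeny durations from the bifurcating
autoregression (or i.i.d. lognormal cycle times in the *uncorrelated*
variant), splitting proteins, and drawing production rates for the sibling
pair. A hard population cap stops the run with an explicit `truncated`
flag — never a silent truncation. Runs are deterministic given the seed.

For drift analyses only the division times and lineage labels matter, so
`simulate_census()` uses a generation-wave scheme — no global event
ordering is needed when the stop rule is the time horizon alone — and
handles populations of $10^5$–$10^6$ cells in seconds. Census counts use
the half-open convention (a cell is present on
$[t_{\text{birth}}, t_{\text{div}})$).

**Founders.** Unsynchronized founders receive an equilibrium cycle and an
age uniform on $[0, T_C)$; their first division occurs after the residual
time. The age law at $t=0$ is not dictated by the model; uniform age is
the package's choice and `synchronized = TRUE` provides the age-zero
control. (Sampling founders from a grown population instead would
length-bias their cycle times; the uniform-age law keeps the founder
cycle-time law equal to the equilibrium law.) Founder protein levels come
from a short warm-up run along single lineages.

**Homeostasis.** Because $\theta < 1$, the duration distribution forgets
the founder: lineage simulations started from 13.6 h and 61.3 h ancestors
converge to the same stationary law (tested by KS at the 5% level on
populations at 200 h), while the *population sizes* they leave behind
differ strongly — the mechanism behind lineage dominance.

## 5. Wright–Fisher analysis of epigenetic drift

Replicate simulations from $N$ founders yield per-ancestor descendant
fractions $Y_i^{(m)}$ at an analysis time (default 300 h; the fractions
stabilize after about 200 h). If the progeny-count vector behaved like
Wright–Fisher multinomial resampling with effective size $K$, then
$\mathrm{E}(Y_i) = 1/N$, $\mathrm{Var}(Y_i) = (N-1)N^{-2}K^{-1}$,
$\mathrm{Cov}(Y_i, Y_j) = -N^{-2}K^{-1}$, and the pairwise correlation is
$-1/(N-1)$ for every $K$.

`effective_size()` inverts the variance relation,
$\hat K = (N-1)/(N^2 \hat V)$, with $\hat V$ the across-replicate variance
of the fractions (per-ancestor centering, averaged over ancestors). It
also reports the pooled statistics $S_r^2$ (centered on $1/N$) and $S_c^2$
(centered on per-ancestor means). Because rows sum to one, the
exchangeable mean is exact and *both* statistics estimate
$\mathrm{Var}(Y_i) = (1-1/N)(KN)^{-1}$; covariance and correlation are
estimated directly from ancestor pairs.

The benchmark is the harmonic-mean law for populations of varying size:
$K = \{\Delta t^{-1}\int_0^{\Delta t} N(\tau)^{-1}d\tau\}^{-1}$, evaluated
by the trapezoid rule on the census grid, alongside the exponential-growth
closed form $N_0 N_T (N_T - N_0)^{-1}\ln(N_T/N_0)$; for unsynchronized
exponential growth the two agree closely. Family correlations *lower*
$\hat K$ below this law — drift is stronger than census dynamics alone
would suggest — while the uncorrelated variant sits near it.
`correlation_sweep()` maps $\hat K$ over parent–progeny and sibling
correlation targets, re-deriving the phase parameters at each grid point
with the marginal mean and variance held fixed (infeasible pairs, sibling
correlation below $\theta^2$, are marked, not raised).

`compare_to_binomial()` checks distributional adequacy: scaled fractions
against $\mathrm{Binom}(K, 1/N)$ draws. The reported CDFs pool all
ancestors; the Wilcoxon rank test deliberately uses one exchangeable
coordinate per replicate, because the $N$ coordinates of one replicate are
dependent (they sum to $K$) and pooling them inflates the test's type-I
error well beyond nominal. Even so the test runs a few points above
nominal, since the reference sample is drawn at the *estimated* size.

## 6. The synthetic-data generator

`generate_experiment()` emulates a FUCCI time-lapse experiment: founders
filmed for 72 h, one tracked position per founder followed through
divisions (as a tracking algorithm follows one cell position),
fluorescence sampled every 0.25 h, multiplicative lognormal measurement
noise (5% relative by default, with an optional additive floor), first and
last cycles typically incomplete. Sidecar ground truth (division times,
transitions, per-cycle durations, full parameter provenance and seed)
makes every pipeline stage testable offline.

What it does *not* emulate: segmentation/tracking errors and cell
swapping, photobleaching and focus drift, density-dependent effects,
death, and quiescence (G0). Passing tests on synthetic films therefore
demonstrate correctness of the estimators under the model's own
assumptions plus measurement noise — not robustness to every artifact of
real imaging.

## 7. Problem sizes and reproducibility

The test-suite experiments use sizes chosen to keep sampling error well
inside the asserted tolerances: equilibrium checks on ~8,000–10,000-cell
generation-limited pedigrees; recovery experiments with 12–20 replicate
pedigrees of ~2,000 cells; closed-loop film experiments with 120 tracks
(≈300 complete cycles) and 20 replicates; drift estimation with 300–400
replicate populations of ~10⁵ cells; multinomial calibration fixtures with
10⁴ replicates. All stochastic functions consume R's global RNG, so a
single `set.seed()` makes any experiment — and the acceptance script —
exactly reproducible.

## 8. Known limitations

- Phases are aggregated to G1 and S/G2/M; no finer phase structure.
- No cell death, quiescence or density dependence; populations only grow.
- The G1/S estimator inherits the Cdt1 peak lag described above; absolute
  G1 durations from trajectories are biased long by ~1 h under the default
  kinetics (division times are not).
- The noise correlation $\rho$ is identified only through a
  distribution-fit criterion; with small noise variances the whole
  moment system sits close to its feasibility boundary.
- Wright–Fisher adequacy is assessed marginally (variance and CDF); the
  full joint law of descendant counts need not be multinomial.
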