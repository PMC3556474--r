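---
title: "Maximum-entropy recovery of fluorescence lifetime distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy recovery of fluorescence lifetime distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdecay)
```

## The inverse problem

A time-correlated single photon counting (TCSPC) instrument histograms
photon arrival times into $M$ channels of width $w$ and records, in
channel $m$, a count $E_m$ whose mean is the convolution of the
instrument response function (IRF) $R(t)$ with the intensity decay law
of the sample.  For a heterogeneous sample the decay law is a
superposition of exponentials,
$$I(t) = \sum_{k=1}^{N} \alpha_k e^{-t/\tau_k},$$
with lifetimes $\tau_k$ placed on a grid equally spaced in $\log\tau$
and unknown nonnegative amplitudes $\alpha_k$.  On a uniform time axis
the model counts are the causal reconvolution sum
$$T_m = \sum_k C_{mk}\,\alpha_k, \qquad
  C_{mk} = \sum_{i \le m} R(t_i)\, e^{-(t_m - t_i)/\tau_k},$$
linear in $\alpha$.  The printed form of the reconvolution sum runs the
inner index over all channels, which would let future IRF samples
influence earlier times and diverge numerically; the causal truncation
$i \le m$ is the standard reading and is what the kernel implements.
Because the exponential factor depends only on the channel lag, every
kernel column obeys a first-order recursion and the full $M \times N$
matrix is built in $O(MN)$.

Recovering $\alpha(\tau)$ from $E$ is ill-posed: many amplitude
spectra fit the data within noise.  The maximum entropy method (MEM)
selects, among all spectra whose reduced chi-squared
$$\chi^2 = \frac{1}{M} \sum_m \frac{(E_m - T_m)^2}{\sigma_m^2}$$
is acceptable ($\chi^2 \sim 1$), the one maximizing the Skilling
entropy $S = \sum_k (\alpha_k - \alpha_k \log \alpha_k)$ — the least
committal distribution consistent with the data.  The divisor in
$\chi^2$ is $M$, not $M - N$: the statistic tests agreement, it does
not count parameters.

## The solver

The constrained problem is the stationarity of the Lagrangian
$\Lambda = -S + \lambda(\chi^2 - 1)$ in the augmented variable
$(\alpha_1,\dots,\alpha_N,\lambda)$:
$$F_i = \log\alpha_i + \lambda\,(\nabla\chi^2)_i = 0 \quad (i \le N),
\qquad F_{N+1} = \chi^2 - 1 = 0,$$
with the bordered Hessian
$H_{ij} = \delta_{ij}/\alpha_j + (2\lambda/M)\sum_m C_{mi}C_{mj}/\sigma_m^2$
for $i,j \le N$, the chi-squared gradient along the border and a
structural zero corner.  `mem_fit()` solves this system by nested
Newton iterations:

* **Inner problem.**  For fixed $\lambda$ the Lagrangian is strictly
  convex in $\alpha$ (entropy curvature $1/\alpha$ plus a
  positive-semidefinite data term).  Damped Newton steps are computed
  by LU factorization with partial pivoting (LAPACK `dgesv`), each
  step guarded by positivity handling and a golden-section
  backtracking line search on the merit $\tfrac12\|F\|^2$, with the
  full correction always tried first.  The data-term Gram matrix does
  not depend on $\alpha$ or $\lambda$ and is computed once per kernel.
* **Positivity.**  The entropy logarithm requires $\alpha_k > 0$.  A
  correction that would drive an amplitude nonpositive is first
  truncated componentwise to a fraction (default 0.99) of that
  amplitude's distance to zero, so one dying lifetime never throttles
  the whole step; if the truncated direction fails to decrease the
  merit, the exact Newton direction under a global fraction-of-step
  cap (`positivity_cap()`) is used instead, which is guaranteed to
  descend.  Amplitudes that reach the floor (`alpha_floor`, default
  $10^{-10}$ of the flat starting level) form an active set: they are
  removed from the Newton system and released as soon as their
  Lagrangian gradient turns negative.  Without the active set the
  admissible step collapses as $\lambda$ grows and the iteration
  stalls.
* **Outer problem.**  The reduced chi-squared of the inner solution is
  a continuous, decreasing function of $\lambda$, so the constraint is
  a scalar root-finding problem.  The multiplier update is the
  bordered-system Newton step evaluated at the inner solution,
  safeguarded by log-scale bisection once the root is bracketed and by
  geometric expansion while it is not.  The iteration starts from the
  flat spectrum whose model curve carries the same total intensity as
  the data, and from `lambda0` (default $10^6$); the converged
  solution does not depend on `lambda0`, which only moves the number
  of bracketing steps.

A single (N+1)-dimensional Newton iteration in which $\lambda$ rides
along inside the step — with no outer structure — was implemented and
tested first.  It reaches the same root on benign problems, but its
merit landscape contains a long flat valley of inner solutions: where
the iteration parks on that valley depends on the multiplier's
starting value, and traversing the valley toward the constraint costs
of the order of $10^5$ capped iterations.  The nested form keeps every
ingredient (bordered system, LU solves, positivity fraction,
golden-section backtracking) while making the multiplier's motion a
well-behaved scalar iteration.

### Where the iteration stops

Two facts shape the stopping rule.  First, at an exact root the
constraint row forces $\chi^2 = 1.000\ldots$; such roots are reached
to machine precision when they exist.  Second, a root need not exist:
the best chi-squared attainable by *any* nonnegative spectrum
fluctuates from one Poisson realization to the next (standard
deviation $\approx \sqrt{2/M} \approx 0.02$ at $M = 4096$), so for a
sizable fraction of realizations the floor lies above 1.  Driving
$\lambda$ upward against such a floor removes the entropy's influence
and fragments the spectrum into near-degenerate spikes without
improving the fit.

The solver therefore targets $\chi^2 = 1 + \texttt{chi2\_tol}/2$
(1.01 at the default band of $\pm 0.02$) rather than 1 exactly.  On
replicate benchmarks this choice recovers Gaussian band centers and
widths within their across-replicate scatter, while exact-root
targeting under-shoots band widths and destabilizes floor-limited
realizations.  When even the relaxed target is unattainable the
expansion stops at the attainable floor, the best visited solution is
returned (smallest distance to the target; the smaller multiplier —
the more regularized spectrum — wins near-ties), and the fit is
flagged unconverged if its chi-squared lies outside the band.

### Variances

Poisson counting statistics make each channel's variance equal to its
mean.  The simulator knows the mean exactly and attaches
$\sigma_m^2 = \max(\bar T_m, 1)$ to synthetic traces.  For measured
data, where only the realized count is available, `decay_trace()`
defaults to $\sigma_m^2 = \max(E_m, 1)$ — standard TCSPC practice.
The distinction matters: weighting by the noisy count correlates the
weights with the noise and biases $\chi^2$ upward by
$\mathrm{E}[(X-\mu)^2/\max(X,1)] > 1$ in low-count channels, enough
(2–6% at $10^4$ peak counts) to push the $\chi^2 = 1$ surface out of
reach and visibly broaden recovered spectra.  Zero-count channels are
floored at variance 1 to keep the statistic finite.

## The synthetic data generator

`simulate_decay()` emulates a TCSPC measurement: 4096 channels over
25 ns, a Gaussian IRF of 120 ps FWHM normalized to unit sum and
centered 500 ps into the record (the instrument's trigger delay; the
rising edge must be recorded, and the placement is configurable), a
ground-truth lifetime distribution, rescaling of the noiseless curve
to a target peak count, and an independent Poisson draw per channel
from a stated integer seed.  Replicate sets use consecutive seeds.
The caller's RNG state is saved and restored.

Ground-truth distributions are mixtures of discrete lines and Gaussian
bands.  A band is specified on the amplitude profile $\alpha(\tau)$ —
the same log-grid amplitude function in which recovered spectra are
plotted and profile-fitted — so band amplitudes are peak heights of
that profile, and a "10% secondary band" has one tenth the height of
the main one regardless of width.  Bands are realized on their own
fine linear grids of 2000 lifetimes spanning $\pm 5$ standard
deviations (carrying the $1/\tau$ Jacobian between the linear measure
and the amplitude-profile convention), deliberately distinct from any
log-spaced analysis grid, so that inversion tests never enjoy the
inverse crime of sharing a discretization with the generator.  What
the generator does *not* emulate: instrumental afterpulsing, pile-up,
dark counts, IRF drift or non-Gaussian IRF shapes.  Passing tests
therefore demonstrate correct inversion of ideal Poisson TCSPC data,
not robustness to instrumental artifacts.

## Spectrum summaries

A recovered spectrum is normalized to a unit-mass density in
$\log\tau$ (`normalize_spectrum()`), segmented into peaks as maximal
runs above a valley threshold (default $10^{-3}$ of the maximum —
low enough to keep MEM baseline ripple out of peaks, configurable
because overlapping bands may need a higher cut), and each peak is
summarized by amplitude-weighted moments: mean lifetime
$\langle\tau\rangle = \sum \alpha_k \tau_k \Delta_k / \sum \alpha_k
\Delta_k$, amplitude fraction, width $\Delta\tau$ (the
amplitude-weighted standard deviation of $\tau$ over the region) and
relative width $r = \Delta\tau / \langle\tau\rangle$.  Because the
weights live on a log-spaced grid, the moment width of a *broad*
Gaussian band carries an $O((\Delta\tau/c)^2)$ inflation from the
$1/\tau$ point-density tilt — exact for narrow peaks, roughly 10% at
$\Delta\tau/c = 0.3$ — which is why band parameters are estimated by
least-squares Gaussian profile fits (`fit_gaussian_profile()`,
Levenberg–Marquardt with bounds that keep centers on the grid and
widths between one grid spacing and the grid span), not by moments.
Profile fits are initialized from ranked local maxima of the curve,
with residual-based placement for shoulder components; replicate
studies (`mem_study()`) initialize at the simulated ground truth, the
usual protocol when benchmarking recovery against known truth.

## Numerical choices and defaults

| parameter | default | meaning |
|---|---|---|
| `chi2_tol` | 0.02 | chi-squared acceptance band half-width |
| `grad_tol` | $10^{-6}$ | RMS gradient declaring an inner solve converged |
| `max_iters` | 2000 | total Newton iterations across all multiplier values |
| `positivity_fraction` | 0.99 | fraction of the distance to zero allowed per step |
| `line_search_tol` | $10^{-3}$ | golden-section bracket width, relative to the capped step |
| `alpha_floor` | $10^{-10}$ | active-set floor, as a fraction of the flat start |
| `lambda0` | $10^6$ | starting multiplier (affects cost, not the solution) |

Degenerate inputs are rejected early: non-uniform time axes, IRFs
without weight, nonpositive variances, amplitudes outside the grid.
A singular Newton system is retried under escalating Levenberg-style
diagonal damping before the solver gives up.

## Reproduced accuracy studies and limitations

The test suite re-runs the package's accuracy studies end-to-end at
full scale: a three-exponential decay (100/1000/4000 ps, $10^4$ peak
counts) recovered on 400 lifetimes; mono-modal Gaussian bands of
widths 500/1000/1500 ps at 5000 ps and $5 \times 10^4$ peak counts
over 20 replicates each; a bimodal band with a 10% secondary; and
single-exponential sharpness across grids of 100–1000 lifetimes.
Three measured behaviors of the implementation are documented rather
than hidden.  First, at the $\chi^2 = 1.01$ stopping point the fitted
width of the narrowest band (10% relative width) reads about 5–7%
high; exact-root convergence removes the bias but is not robust across
noise realizations, as discussed above.  Second, the secondary band of
the 10% bimodal mixture, though resolved with the correct relative
amplitude, is smeared toward the main band by roughly 300 ps.  Third,
the relative width $r$ of a recovered single-exponential line at the
smooth stopping point is about 3% essentially independently of the
grid size; markedly sharper lines ($r < 1\%$) are obtained only when
the realization's attainable chi-squared floor lies above the target,
so the fit is data-limited and the width collapses to the grid
resolution — that regime shows the familiar decrease of $r$ with $N$
(about 2.4%, 1.6%, 0.7%, 0.7% for $N$ = 100, 200, 400, 1000), but
whether a given realization reaches it is a property of its noise
draw, not of the solver settings.  All other summaries land within
the across-replicate scatter of the corresponding study.

Beyond those, the main limitations are inherited from the model: no
IRF shift or scatter fitting, no baseline term, no error bars on the
recovered amplitudes (the posterior curvature is available in the
Hessian but not propagated), and no model selection for the number of
Gaussian components in profile fits.
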