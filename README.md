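# memdecay

Maximum-entropy recovery of fluorescence lifetime distributions from
time-resolved decay data.

Time-correlated single photon counting (TCSPC) records a fluorescence
decay as photon counts per time channel; the decay is the instrument
response function (IRF) convolved with the sample's intensity decay
law.  For heterogeneous samples — proteins with distributed
conformations, chromophores undergoing distance-dependent energy
transfer — the decay law is a continuous distribution of exponential
lifetimes rather than a few discrete components, and recovering that
distribution is a severely ill-posed inverse problem.  `memdecay`
implements the maximum entropy method (MEM) for this problem: among
all nonnegative amplitude spectra α(τ) on a log-spaced lifetime grid
whose reconvolved model fits the data at reduced chi-squared near one,

    chi^2 = (1/M) * sum_m (E_m - sum_k C_mk alpha_k)^2 / sigma_m^2  ~  1,

it returns the one maximizing the Skilling entropy

    S(alpha) = sum_k (alpha_k - alpha_k log alpha_k),

the least-committal spectrum consistent with the data.  The
constrained problem is solved through the stationarity system of the
Lagrangian Λ = −S + λ(χ²−1): damped Newton iterations with LU linear
solves, positivity capping of the corrections, and golden-section
backtracking for the amplitudes, with the multiplier λ driven by the
bordered Newton step on the χ² constraint.  The package also provides
the synthetic TCSPC generator (Gaussian IRF, multi-exponential or
Gaussian-mixture ground truths, per-channel Poisson noise) and the
spectrum summaries (peak segmentation, amplitude-weighted moments,
Gaussian profile fits, replicate studies) used to quantify recovery
accuracy.  Intended users: spectroscopists analysing TCSPC lifetime
data and developers benchmarking lifetime-inversion methods.

## Worked example

Simulate the classic three-exponential benchmark — 4096 channels over
25 ns, a 120 ps FWHM Gaussian IRF, lifetimes 100 / 1000 / 4000 ps with
equal amplitudes, 10^4 counts in the peak channel — and invert it on
400 lifetimes log-spaced between 20 ps and 10 ns:

```r
library(memdecay)

spec <- simulation_spec(
  distribution_spec(c(0.33, 0.33, 0.33), c(100, 1000, 4000)),
  total_span = 25000, M = 4096, fwhm = 120, peak_counts = 1e4,
  seed = 1)
sim <- simulate_decay(spec)

fit <- mem_fit(sim$trace, sim$irf, lifetime_grid(20, 1e4, 400))
summary(fit)
```

```
MEM fit: chi2 = 1.0098, lambda = 7.524e+05, 133 iterations (converged)
3 peak(s):
 k_start k_end   n mean_tau amp_fraction width rel_width
       1   163 163    101.5       0.3359  31.4   0.30950
     214   281  68   1001.7       0.3320 137.9   0.13770
     325   352  28   3993.0       0.3314 213.6   0.05348
```

The three recovered peaks sit at amplitude-weighted mean lifetimes of
about 101, 1002 and 3993 ps, each carrying one third of the amplitude:
the simulated parameters to within a few percent, from a single noisy
decay.  `plot(fit)` draws the normalized lifetime distribution;
`plot(fit, "decay")` and `plot(fit, "residuals")` show the
reconvolved fit and its weighted residuals.  `mem_study()` repeats
simulate-and-invert over replicate noise realizations and aggregates
peak or Gaussian-profile parameters with their standard deviations.

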