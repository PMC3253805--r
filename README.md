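# branchcycles

Do speciation events on a dated phylogeny recur with a characteristic
period? `branchcycles` treats the branching times of an ultrametric
chronogram as a point process on geological time and tests that process for
periodicity at user-chosen bands — in particular the ~400-kyr and ~100-kyr
Milankovitch eccentricity cycles, the classic "Court Jester" expectation
that abiotic climate forcing paces adaptive radiation. It is aimed at
molecular phylogeneticists and macroevolution researchers who have a dated
tree (or a table of node ages with credible intervals) and want a tested,
reproducible periodicity analysis rather than ad-hoc spreadsheet Fourier
runs.

The package ships the 25 well-supported dated branching events of the East
Mediterranean blind mole rats (Spalacidae) as a worked fixture
(`spalax_node_ages()`), together with a clade grouping
(`spalax_clade_groups()`).

## What it computes

Event ages a₁, …, a_N (Ma before present) are counted into half-open bins
of width Δ (default 0.1 My), giving a series x(t), t = 0, …, n−1, youngest
bin first. On the (default mean-detrended) series:

- **Partial autocorrelation** (`serial_pacf`): Durbin–Levinson recursion on
  the biased-denominator sample autocorrelation; each lag-k value φ_kk gets
  the large-sample standard error 1/√n, the statistic T = φ_kk·√n, and a
  one-sided normal p-value (`pacf_significance`).
- **Harmonic coefficients** (`fourier_coefficients`): a(f) = (2/n) Σ_t x(t)
  cos(2πft), b(f) = (2/n) Σ_t x(t) sin(2πft), f in cycles per bin.
- **Periodogram** (`periodogram`): a, b and intensity I(f) = (n/4)(a²+b²)
  on the Fourier grid f = k/n; Parseval's identity ties Σ(a²+b²)/2 to the
  sample variance.
- **Fisher's exact g-test** (`fisher_g_test`): g = max I / Σ I over the m
  ordinates, with the exact white-noise tail probability
  P = Σ_j (−1)^(j−1) C(m,j)(1−jg)^(m−1).
- **Bivariate amplitude comparison** (`compare_harmonics`): per-group
  amplitudes √(a²+b²) at a shared frequency, with a permutation p-value from
  shuffling event-to-group labels and re-binning.
- **Fossil calibration points** (`calibration_from_interval`): midpoint ±
  half-range of a fossil age interval, e.g. the 8.24–7.1 Ma Nannospalax
  interval → mean 7.67 Ma, sd 0.57 Ma.
- **A forced branching simulator** (`forcing_model`, `simulate_events`,
  `simulate_tree`): inhomogeneous Poisson events (Lewis–Shedler thinning)
  and pure-birth trees under λ(t) = λ₀·exp(Σᵢ Aᵢ cos(2πt/Pᵢ + φᵢ)), plus
  lognormal dating noise (`add_dating_noise`) — the ground-truth generator
  behind the type-I (`power_study`) and period-recovery
  (`period_recovery`) validations.

## Worked example

```r
library(branchcycles)
rep <- run_analysis(spalax_node_ages(), spalax_clade_groups())
print(rep)
print(calibration_from_interval(8.24, 7.1))
```

prints

```
Branching-event periodicity report (25 events, 0.1-My bins, detrend: mean)

Partial autocorrelation at the target periods:
  period 0.4 My (lag 4): pacf 0.359, t = 5.080, one-sided P = 1.884e-07
  period 0.1 My (lag 1): pacf 0.288, t = 4.073, one-sided P = 2.32e-05

Fisher's g-test: g = 0.1228 over m = 99 ordinates, P = 0.0002639
  peak at frequency 0.005 cycles/bin (period 20 My)

Per-group g-tests:
  I (5 events): g = 0.1071, P = 0.5201, peak period 0.3455 My
  III (4 events): g = 0.3594, P = 0.2539, peak period 0.38 My
  IV (3 events): g = 0.3666, P = 0.3247, peak period 0.9 My
  V (10 events): g = 0.1436, P = 0.6193, peak period 4.7 My
Calibration point: mean 7.67 Ma, sd 0.57 Ma (interval 8.24-7.1 Ma)
```

Reading this: the 25 events, binned at 0.1 My over the full 0–20 Ma span,
carry a positive partial autocorrelation at lag 4 — the 400-kyr band — that
is individually significant (t = 5.08 on the 200-bin series). The whole-tree
periodogram peak sits at the deepest frequency (period ≈ tree depth), which
simply reflects the clustering of most events towards the present; the
per-group g-tests at 3–10 events apiece illustrate how little power the
exact test has at these sample sizes (see the methods vignette). The
calibration line reproduces the fossil-interval arithmetic used to anchor
the Spalax/Nannospalax split. `write_report()` serializes the full report
(PACF table, periodogram, per-group results) as JSON; a command-line front
end with `extract`, `analyze`, `simulate`, `power` and `calibrate`
subcommands is installed at `inst/scripts/branchcycles.R`.

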