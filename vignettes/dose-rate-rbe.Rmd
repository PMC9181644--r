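---
title: "Modelling dose-rate-dependent cell survival and RBE from DSB repair kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dose-rate-dependent cell survival and RBE from DSB repair kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ionrbe` implements a mechanistic Monte Carlo model of cell killing by
ionizing radiation built on the clustering of DNA double-strand breaks
(DSB) in chromatin. The nucleus is a cylinder packed with cubic domains
of roughly 2 Mbp of DNA each — the "giant-loop" chromatin substructures.
A domain holding exactly one DSB carries an *isolated* damage (iDSB); a
domain holding two or more carries a *clustered* damage (cDSB), which is
far harder to repair correctly. Given the damage pattern at the end of
irradiation, the cell survives with probability

$$S = (1 - K_\mathrm{iDSB})^{N_\mathrm{iDSB}} \,
      (1 - K_\mathrm{cDSB})^{N_\mathrm{cDSB}},$$

where $N_\mathrm{iDSB}$ and $N_\mathrm{cDSB}$ count *domains* of each
class and the lethality parameters $K_\mathrm{iDSB}, K_\mathrm{cDSB}$
are per-damage probabilities of triggering the endpoint. Reinterpreting
the $K$'s as endpoint-trigger probabilities extends the same machinery
from clonogenic survival to in-vivo endpoints such as rat-spinal-cord
paresis; the endpoint probability of a delivery is then $P = 1 - S$ and
the TD50 is the total dose with $P = 0.5$.

Parameters (`endpoint_params()`), all dimensionless or in minutes:

* `k_idsb`, `k_cdsb` — per-damage lethality, in [0, 1];
* `t_half_idsb`, `t_half_cdsb` — repair half-lives of the two damage
  classes (`t_half_cdsb >= t_half_idsb`);
* `alpha_dsb` — DSB induction yield, 30 DSB per Gy per cell by default,
  constant over the clinical dose range.

Shipped presets: `DU145` (in-vitro survival,
$K_\mathrm{iDSB} = 5.9\times 10^{-3}$, $K_\mathrm{cDSB} = 0.17$,
$T_{1/2} = 4/100$ min) and the rat-spinal-cord paresis endpoint fitted
with (`RSC_repair`: $3.5\times 10^{-5}$, $9.8\times 10^{-3}$,
$11.4/129.6$ min) and without repair kinetics (`RSC_norepair`).

The nucleus (`nucleus_model()`) defaults to a cylinder of radius 5 µm
and height 10 µm holding ~3000 domains — a 6 Gbp diploid genome at
2 Mbp per giant loop. The cube edge follows from the volume; the
realised grid (square lattice of domain columns inside the
cross-section, times full layers along the axis, 3072 domains) is
reported in the object and used consistently by both engines. The
published analyses this package reconstructs do not restate the nucleus
geometry, so these are declared package defaults, not literature
values; every result object and output table echoes the value used.

## Photon (sparsely ionizing) engine

Sparsely ionizing radiation deposits dose homogeneously: the total DSB
count is Poisson with mean $\alpha_\mathrm{DSB} D$ and each DSB lands in
a uniformly chosen domain. The acute Monte Carlo engine
(`simulate_photon_acute()`) samples exactly that. Because uniform
allocation of a Poisson count makes the per-domain counts independent
Poisson variables with mean $\mu = \alpha_\mathrm{DSB} D / N$, the
expectation has a closed form,

$$E[S] = \left[e^{-\mu} + \mu e^{-\mu}(1 - K_\mathrm{iDSB})
        + (1 - e^{-\mu} - \mu e^{-\mu})(1 - K_\mathrm{cDSB})\right]^N,$$

implemented as `photon_survival_closed_form()` and used as the engine's
oracle and as the deterministic root target for acute iso-effect doses.

### Time-resolved delivery and repair kinetics

For a finite dose rate the delivery is split into $N_t = 100$ equal
time-steps; the partial dose $D/N_t$ is deposited at the *start* of each
sub-interval (making the acute limit exact as the interval length
vanishes) and repair advances in between. Each DSB draws an exponential
lifetime whose *median* equals the class half-life (rate
$\ln 2 / T_{1/2}$). The kinetic rules:

* a DSB landing in an empty domain is isolated and draws an i-type
  lifetime;
* any DSB added to a domain classified iDSB upgrades it to cDSB and the
  resident damage's lifetime is redrawn from the c-type distribution;
* at each step, damages whose lifetime has expired are repaired
  (removed); each removal fails with probability $K_\mathrm{iDSB}$ or
  $K_\mathrm{cDSB}$ according to the damage's classification *at
  removal time*, and any such misrepair inactivates the cell (survival
  0 for that iteration);
* when a cluster shrinks to a single DSB the domain reclassifies to
  iDSB for scoring and for subsequent misrepair draws, but the
  surviving damage keeps its c-type clock — the published description
  prescribes a redraw only on upgrade, so none is applied on
  declassification.

These two interpretation points (classification at removal rather than
at creation, and no lifetime redraw on declassification) are genuinely
open in the source description; both are isolated in `advance_state()`
and the engines, and the package's consistency property does not depend
on them: a lone DSB that is never joined contributes an expected factor
$(1 - K_\mathrm{iDSB})$ regardless of irradiation time, because the
repaired-then-misrepaired and still-present paths carry the same
factor. This is what makes survival independent of how long a window
one simulates, and it is tested across dose rates.

### Exact per-domain expectation

Uniform allocation also makes the *timed* photon model exactly
factorisable: domains evolve as independent, identically distributed
birth–death processes (Poisson arrivals per tranche, memoryless
exponential repair, domain-local misrepair), so

$$E[S] = f^N,$$

with $f$ the expected per-domain survival weight. The package
propagates $f$ through the 100 deposit/repair steps over the occupancy
states $\{0,\ 1_i,\ 1_c,\ n \ge 2\}$ (truncated at $n = 40$; the
per-tranche arrival mean is $\sim 10^{-4}$, so the truncation error is
far below double precision): deposits convolve with the Poisson arrival
distribution, repair applies binomial removal with the per-step survival
probabilities $e^{-\ln 2\, \Delta t / T_{1/2}}$ and misrepair weights
$(1-K)$ per removal. `photon_survival_timed_exact()` is deterministic,
costs microseconds, and agrees with the Monte Carlo engine within
Monte Carlo error on a dose × rate grid (tested at 4 standard errors).
It serves three roles: oracle for the timed MC engine, noise-free
iso-effect solver inside the RBE computations, and fast model core for
the lethality-parameter fit.

## Ion engine

Ion tracks deposit dose heterogeneously. The radial dose profile is the
Kiefer–Chatterjee amorphous-track parametrization: a constant-dose core
of radius $r_\mathrm{min} = 0.0116\,\beta$ µm and a $K_p/r^2$ penumbra
out to $r_\mathrm{max} = 0.062\,E^{1.7}$ µm ($E$ in MeV/u), with
$K_p = 1.25\times10^{-4}(z^*/\beta)^2$ Gy µm² and the Barkas effective
charge $z^* = z(1 - e^{-125\beta z^{-2/3}})$. The core dose is fixed by
energy conservation: the radial integral of the profile (times density)
must reproduce the LET, with 1 keV/µm³ = 0.1602 Gy in unit-density
water. This closure is the defining normalisation and is enforced to 1%
for raw, diffused and step profiles in the tests.

Radical diffusion convolves the profile with a 2-D Gaussian of standard
deviation $\sigma$ (default 0.004 µm — a radical diffusion length of a
few nanometres; the source publications do not state the value, so it
is a declared default, echoed in all outputs). The radially symmetric
convolution is evaluated through the modified-Bessel kernel
$I_0(r r'/\sigma^2)$ with exponent-shifted Bessel evaluation (the
combined exponent is $-\,(r - r')^2/2\sigma^2$), and the support is
extended past $r_\mathrm{max}$ only while the dose exceeds $10^{-6}$ of
the peak.

### Three-step parametrization and deposition

For deposition the profile is reduced to three concentric annuli of
constant dose whose levels are annulus-averaged doses, so each annulus
conserves its energy exactly. Tracks travel parallel to the cylinder
axis and each domain receives the step dose at the radial distance
between track axis and its column's centre line (midpoint rule).

The boundary placement is a design choice the source leaves open, and
it interacts strongly with the midpoint rule. Placing the inner
boundary at the (diffused) core radius — a few nanometres — conserves
energy but assigns the core annulus *average* (order $10^3$–$10^6$ Gy)
to an entire 0.64 µm domain whenever a track passes within nanometres
of its centre line: the per-event domain dose is then wrong by orders
of magnitude, whole domains saturate, and the low-LET ion limit breaks
(the model fell to RBE ≈ 0.67 where it should approach 1). The engines
therefore place the inner boundary at the *deposition footprint*
radius, `domain_side / sqrt(pi)` (the circle with the area of the
domain cross-section): a central traversal then receives exactly the
domain-area-averaged dose, the physically meaningful quantity at the
scale of the scoring grid, while the middle boundary stays at the
geometric mean and the outer at the profile support. Tracks narrower
than the footprint collapse onto a single step carrying the full track
energy. `three_step_profile(footprint = 0)` retains the plain
core-boundary construction.

The number of tracks through the sampling disk of radius
(nucleus radius + outer step radius) is Poisson with mean given by the
fluence–dose relation $D = 1.602\times10^{-9}\,\mathrm{LET}\,\Phi/\rho$
($\Phi$ in cm⁻²); positions are uniform. Per-domain DSB counts are
Poisson with mean $\alpha_\mathrm{DSB}\, d_\mathrm{eff} / N$, where
$d_\mathrm{eff}$ sums the *yield-weighted* step levels of the tracks
covering the domain (below). The timed ion engine deposits a fresh,
independent set of tracks for each of the $N_t$ tranches and advances
the same repair kinetics between tranches.

### Local-dose DSB-yield enhancement

At the very high local doses inside a track (≫ 100 Gy), single-strand
breaks are dense enough that opposite-strand SSB within a short stretch
of DNA combine into additional DSB. The pluggable yield model defaults
to this SSB-pairing form,

$$\eta(d) = 1 + \epsilon\,\frac{\alpha_\mathrm{SSB}}{2\alpha_\mathrm{DSB}}
  \left(1 - e^{-\alpha_\mathrm{SSB}\, d\, h / G}\right),$$

with $\alpha_\mathrm{SSB} = 1250$ SSB/(Gy·cell), window $h = 25$ bp and
genome $G = 6\times10^9$ bp. The conversion efficiency $\epsilon$
(default 0.15) is the fraction of within-window pairs that actually
form an extra DSB; it is calibrated so that the track-averaged yield
factor of a 1.1 MeV proton (25 keV/µm) is ≈ 1.2, the scale of measured
and track-structure-simulated DSB-induction RBE at that LET — counting
every pair ($\epsilon = 1$) would more than double the yield there,
which that literature excludes. The enhancement enters through
yield-weighted annulus levels — annulus averages of
$d\,\eta(d)$ over the *continuous* diffused profile — so the nanometre-
scale core contributes its high local dose to DSB production even
though deposition is footprint-averaged. An identity model
(`enhancement_identity()`) exists for all closed-form oracle work.

Proton presets pair the representative LET values 2, 8 and 25 keV/µm
with kinetic energies 28, 5.0 and 1.1 MeV interpolated from standard
stopping-power tables; user-supplied energy/LET pairs are taken at face
value.

## Dose–response, TD50 and the three RBE definitions

Fractions are simulated independently with equal doses and survivals
multiplied; given the misrepair bookkeeping this is equivalent to
complete inter-fraction damage resolution, so no inter-fraction
interval parameter exists. `solve_td50()` bisects the total dose to the
50% endpoint level; with the MC engine every evaluation reuses one seed
(common random numbers), making the bisected function deterministic and
letting most of the Monte Carlo error cancel in TD50 *ratios*. The
default bracket tolerance is 0.05 Gy (0.02 Gy in the package's own
analyses).

Three RBE definitions are provided, all as the photon iso-effect dose
over the ion dose at the ion's effect level:

* **fixed-reference** — photon reference at a fixed rate (2 Gy/min in
  the reconstructed analyses): rises with ion dose rate and saturates
  once the irradiation time is short against $T_{1/2,\mathrm{iDSB}}$;
* **dose-rate adapted** — photon reference at the ion's rate: falls
  with dose rate and saturates at the no-repair value;
* **no-repair** — both modalities acute.

`r_td50()` is the photon TD50 ratio between the 3.75 Gy/min reference
and a given rate at matched fractionation — the dose-rate correction
factor that multiplies the no-repair RBE in the spread-out-Bragg-peak
approximation `rbe_sobp_approx()`. The approximation is valid where the
dose-rate adapted RBE has already saturated (high dose rates); it fails
at low dose rates, and the package tests its internal consistency near
the 50% effect level at 10 Gy/s. `lq_decreasing_rbe()` implements the
linear-quadratic trend criterion: the acute-over-protracted RBE
decreases with dose iff
$\alpha_\infty/\alpha_{\dot\delta} > \beta_\infty/\beta_{\dot\delta}$.

Photon iso-effect doses inside the RBE functions default to the exact
per-domain engine (no photon-side noise); the ion side is always Monte
Carlo. Ion effect levels of exactly 0 or 1 cannot be matched by a
finite photon dose and raise an error rather than returning a value.

## Fitting lethality parameters

`fit_lethality()` estimates $(K_\mathrm{iDSB}, K_\mathrm{cDSB})$ by
least squares on TD50-vs-fraction-number data at the reference dose
rate, with half-lives held fixed — the classic formula/data interface
returning a classed fit with `print`, `summary`, `coef`, `predict`,
`residuals`, `simulate` and `plot` methods. Optimisation is
derivative-free (Nelder–Mead) on $\log_{10} K$ with box
$[10^{-8}, 1]$, started from a coarse log-grid scan; boundary-pinned
estimates and non-convergence are reported. With the exact engine the
objective is deterministic and noise-free data return the generating
parameters to well within 10%.

Identifiability is asymmetric by construction: with
$\alpha_\mathrm{DSB} = 30$ and ~3000 domains, the clustered channel
carries most of the effect at every clinically plausible fraction size
(the isolated channel reaches only ~17% of the log-effect even at 32
fractions), so $K_\mathrm{cDSB}$ is recovered tightly while
$K_\mathrm{iDSB}$ is noise-hungry: at 3% lognormal TD50 noise its
median relative error across replicates is ~40–50%. This limitation is
intrinsic to the data type, not the optimiser, and plausibly explains
why independently published fits of the isolated-DSB lethality for the
same endpoint differ by orders of magnitude.

## Synthetic data generator

`make_synthetic_td50()` stands in for measured photon tolerance-dose
series: it computes model TD50 values at the reference rate
(3.75 Gy/min) for a fraction schedule defaulting to
1, 2, 4, 8, 16, 32 — a geometric spread chosen to separate the fast and
slow damage channels as far as the data type allows — and perturbs them
with multiplicative lognormal noise (3% where noise is wanted).
Regeneration from the same parameters and seed is bit-identical. What
it does *not* emulate: litter/animal-level variability structure,
dose–response slope uncertainty around the 50% level, or any
correlation between fraction groups; passing recovery tests on these
tables therefore demonstrates estimator correctness under the model,
not robustness to real-data pathologies.

## Numerical choices and problem sizes

* Exact recursion: occupancy truncation $n_{\max} = 40$; Poisson
  arrival tail cut at $10^{-18}$.
* Radial integrals over profile evaluators use a dense trapezoid grid
  (linear near the axis, log-spaced beyond) rather than adaptive
  quadrature, which fails on annuli where the profile vanishes.
* Iso-effect bisection: common-random-number evaluations, default
  tolerance 0.05 Gy (TD50) / 0.02 Gy (RBE solves); brackets expand by
  doubling, with an error after 60 doublings.
* Monte Carlo sizes in the package's own analyses: 10⁴–2×10⁴ iterations
  for photon TD50 ratios (with common random numbers the ratio noise is
  ≈ 0.003), 1–3×10³ iterations for ion simulations at 6–24 Gy. These
  were chosen to keep each analysis in the minutes range on one core at
  the quoted precision; the engine defaults remain 10⁴.
* Seed discipline: all engines draw through R's RNG, so a single
  `set.seed()` (or the `seed` arguments) makes every result
  bit-reproducible.

## Known limitations

* No mixed-LET field transport: spread-out-Bragg-peak positions are
  handled through the $R_{TD50}$ approximation with dose-weighted LET
  and dose rate consumed as inputs.
* Mono-exponential repair per damage class; no saturable-enzyme or
  cell-cycle effects, no ultra-high-dose-rate (FLASH) sparing.
* The deposition footprint construction bounds, but does not remove,
  the midpoint-rule granularity of the three-step profile; its
  deposition error against the continuous profile is regression-tested
  at the few-percent level.
* The SSB-pairing yield model is a calibrated stand-in for the cited
  analytical enhancement formula, whose exact constants are not
  restated in the source; its one free scale is anchored to the
  DSB-induction literature as described above.
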