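---
title: "Methods: CSDA microdosimetry of 211At in thyroid follicle models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSDA microdosimetry of 211At in thyroid follicle models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follidose)
```

# The problem

Free astatine-211, an alpha emitter used in targeted alpha therapy,
accumulates in the thyroid much like iodine.  Because the alpha range in
tissue (roughly 48--70 um for the two 211At lines) is of the same order as a
thyroid follicle, the dose actually received by a follicle-cell nucleus
depends strongly on follicle size and on where the activity sits within the
follicle, and therefore differs between mouse, rat and human.  `follidose`
simulates this situation: it transports the 211At alpha particles through an
idealised spherical follicle and reports the microdosimetric quantities for
the follicle-cell nucleus, alongside the conventional MIRD organ-level dose
for comparison.

# Geometry

A follicle is modelled as a spherical colloid lumen (radius $a$) surrounded
by a single cell layer of thickness $t$.  Six spherical nuclei of diameter
$d$ sit on the $\pm x, \pm y, \pm z$ axes, centred mid-layer at
$|c| = a + t/2$.  Species presets (lumen diameter / $t$ / $d$): mouse
50/6/4 um, rat 70/8/6 um, human 150/10/8 um, with thyroid masses 3 mg,
30 mg and 19 g.  The multi-follicle variant wraps the follicle in one
neighbouring cell shell and one outer lumen shell (mouse 6/50, rat 8/70,
human 10/150 um) with no inter-follicular tissue.  Everything is
unit-density liquid water except, optionally, the lumen regions, which may
carry a stable-iodine mass fraction.  Beyond the outermost sphere the model
is vacuum; tracks are terminated there, which is harmless because every
source of interest lies inside and the alpha range is at most 70 um.

Source compartments: uniform in the lumen (A), on a concentric spherical
surface of radius $r$ inside the lumen (B; $r = 0$ is a point source),
uniform in the cell layer including the nuclei (C), uniform over the six
nuclei (D), and -- for the multi-follicle model -- uniform in the
surrounding lumen shell (E) or surrounding cell shell (F).  Positions are
drawn by exact inverse-CDF sampling of the radial coordinate (uniform in
volume) times an isotropic direction; no rejection step is needed, and the
sampling is exact.  For source D a nucleus is chosen uniformly; the six are
congruent, so per-nucleus and per-unit-volume sampling coincide.

# Transport model

Each history is one decay: an emission line is drawn from the two-line
211At spectrum (5.867 MeV at 42%, 7.450 MeV at 58%), a position from the
source compartment, a direction isotropically.  The particle then follows a
straight line in the continuous-slowing-down approximation (CSDA).  The
track is partitioned *exactly* at every region boundary (ray--sphere
intersections of the nested spheres), not by fixed-step marching, so there
are no step-size artifacts.  Within each segment the residual energy is
$E' = R^{-1}(R(E) - \ell)$ for the medium's range--energy relation; when
the residual drops below the 1 keV cut-off the particle is considered
stopped and the remaining energy is deposited at the end of the step.  The
energy imparted to a nucleus is the entry-minus-exit energy over the
track's chord through it.

The reference results for this problem were produced with a
condensed-history general-purpose code that includes energy straggling and
multiple scattering.  We deliberately do not replicate that: delta-ray
transport is unnecessary for spherical targets down to 1 um for alphas
below 10 MeV (the classical Kellerer--Chmelevsky argument), multiple
scattering of alphas is small over tens of micrometres, and straight CSDA
tracks make the transport exactly vectorisable and testable against
closed-form oracles.  An optional Gaussian (Bohr) straggling perturbation
of nucleus-chord deposits is available behind `straggling = TRUE`; it is
off by default, and the default defines all reference results in the
package.  One visible consequence of the missing straggling: the maximum
single-hit deposit is bounded by the energy whose residual range equals the
longest nucleus chord, so the extreme tail of $f(z_1)$ sits a few percent
below a straggled calculation, and the fraction of alphas fully stopped in
a lumen whose radius is close to the range (the rat model) comes out around
5.6% rather than the reported 7%.

# Stopping-power data

The only physical-data dependency is a pair of plain-text tables
(`inst/extdata/alpha_*_stopping.txt`): alpha mass stopping power in liquid
water and in elemental iodine on a 1 keV--10 MeV log grid.  The tables are
generated from a documented ICRU-49-style parametrisation -- proton Bethe
stopping ($I_{\mathrm{water}} = 75$ eV, $I_{\mathrm{iodine}} = 491$ eV)
evaluated at equal velocity, scaled by the Barkas effective-charge factor
for helium, with a power-law roll-off below the Bethe validity limit -- and
its two free constants are calibrated so the water table reproduces the
published CSDA anchors exactly: $R(5.867\ \mathrm{MeV}) = 48$ um and
$R(7.450\ \mathrm{MeV}) = 70$ um in unit-density water.  The resulting
curve peaks near 240 keV/um around 0.6 MeV and gives 216 keV/um at 1 MeV,
a physically reasonable Bragg curve.  At run time the table is
log-log-interpolated onto a 4000-point grid; the range is a cumulative
trapezoid of $dE/S$, and the energy--range maps are mutually inverse linear
interpolants on shared knots (round trip exact at the knots, tested to
1e-6 MeV).

Lumen iodine ("1%"/"2%") is interpreted as a *mass* fraction.  Mass
stopping powers combine by Bragg additivity,
$S_{\mathrm{mix}} = (1-w) S_{\mathrm{H_2O}} + w S_{\mathrm{I}}$, and the
density uses mass-fraction-weighted specific volumes,
$1/\rho = (1-w)/1.0 + w/4.94$.  The reference publication does not state
whether its concentrations were mass, volume or mole fractions, so the
iodine results are compared qualitatively (direction and magnitude of the
shifts) rather than pinned numerically.

# Estimators

With $N$ histories, $\varepsilon_{ik}$ the energy imparted by history $i$
to nucleus $k$, nucleus mass $m = \rho \pi d^3/6$ and mean chord
$\bar\ell = 2d/3$ (Cauchy):

* mean specific energy per decay
  $\langle z\rangle = \sum_{ik} z_{ik} / (6N)$ (all histories, averaged
  over the six nuclei, implemented as pooled sums);
* single-hit mean specific energy
  $\langle z_1\rangle = \sum z_{ik} / M$ over the $M$ pooled deposits with
  $z > 0$ (a "hit" is any positive deposit -- the 1 keV cut-off already
  bounds what can be missed);
* frequency-mean lineal energy
  $\langle y_F\rangle = \langle z_1\rangle\, m / \bar\ell$ (exact algebraic
  companion, asserted to 1e-12 on shared tallies);
* single-hit spectra $f(z_1)$ and $f(y)$: unit-area histograms over
  left-closed bins starting at 0, conventional widths 20 mGy and 5 keV/um;
* stopped-in-lumen fraction: histories whose residual energy reached zero
  before the first exit from the central lumen, split by emission line.

The identity $\langle z\rangle N = \langle z_1\rangle M$ holds exactly by
construction (with $M$ counted per nucleus, i.e. pooled/6).  For the
nuclei-uniform source the nuclei are simultaneously sources and targets and
the reference tables normalise per decay *in the source nucleus*; we follow
that convention (divisor 1 instead of 6), which makes
$\langle z\rangle = \langle z_1\rangle$ up to the rare cross-hit into a
neighbouring nucleus, as reported.

The relative error of $\langle z\rangle$ is the standard error of the mean
of the per-history nucleus-averaged $z$, divided by the mean (the standard
Monte Carlo relative-error convention); for $\langle z_1\rangle$ it is
computed over the pooled hits, ignoring the slight clustering of hits
within a history (a few per mille effect at the hit multiplicities that
occur here).

# Macrodosimetry

The MIRD mean dose is $\bar D = \tilde A \Delta \phi / m$ with
$\Delta = 6.8$ MeV per decay, $\phi = 1$ and the species thyroid mass; the
gland volume follows from the mass at unit density, 70% of it is follicles,
and the cumulated activity is spread uniformly over the lumen volume.  The
per-lumen decay count is then
$\tilde A\, V_{\mathrm{follicle}} / (0.70\, V_{\mathrm{thyroid}})$
(about 163.6 decays for a 1 Gy mouse gland), and the nucleus self-dose is
that count times the simulated lumen-source $\langle z\rangle$ -- about
0.33 Gy for the mouse, reproducing the reference comparison.  The
neighbour-follicle term is exposed as a documented convention (same lumen
decay density applied to the surrounding-lumen shell of the multi-follicle
model): the reference publication's neighbour bookkeeping is not derivable
from its stated assumptions (a uniform lumen decay density over that shell
gives a mouse neighbour term of roughly 1.6 Gy against the reported
0.51 Gy under every volume convention we tried), so neighbour doses are
reported under this package's convention and not asserted against the
reference numbers.

# Numerical and design choices

* **Tangent rays** (zero discriminant) count as misses; a zero-length
  chord deposits nothing either way.
* **Boundary ties**: energies are continuous across boundaries, so a chord
  endpoint landing exactly on a region boundary is handled by a zero-length
  partial step; the medium chosen for it is irrelevant.
* **RNG**: one seeded Mersenne-Twister stream with fixed chunking
  (`chunk_size`, default 250,000).  Runs are bit-reproducible for identical
  configurations; histories are *not* order-independent across different
  chunk sizes (a deliberate simplification over per-history substreams --
  R has no cheap counter-based generator, and reproducibility of a given
  configuration is what the tests require).
* **Degenerate inputs**: a nucleus larger than its cell layer, a surface
  source outside the lumen, surrounding sources on a model without
  surroundings, energies above the table grid and non-positive masses are
  all construction-time errors; a run with zero hits reports
  $\langle z_1\rangle$ and $\langle y_F\rangle$ as absent rather than 0.

# What the simulations do and do not establish

The package's green tests establish: the CSDA bookkeeping is exact against
independent fine-step integration and quadratic-formula ray oracles; the
estimators obey their algebraic identities exactly; sampling is uniform and
isotropic by statistical test; the stopped-in-lumen fraction matches the
closed-form containment probability; and the headline species results
(means, spectra maxima, lineal energies, the MIRD self term) reproduce the
reference MCNPX values within a +/-15% physics band plus 3 Monte Carlo
sigma at $10^6$ histories.  They do not establish agreement with straggled
transport in regimes dominated by range fluctuations (the rat
stopped-in-lumen fraction is the known case, 5.6% vs 7%), nor anything
about real thyroid tissue: follicles are not perfect spheres of one size,
inter-follicular tissue exists, and 211At biodistribution within a follicle
is only approximated by the idealised compartments A--F.

# Worked example

```{r example, eval = FALSE}
mod <- follicle_model(species = "human")
cfg <- simulation_config(mod, source_distribution("lumen_uniform"),
                         n_histories = 1e6, seed = 1)
run <- run_simulation(cfg)
run$summary
stopped_fraction(run)
fz <- build_spectrum(run, "z1")   # 20 mGy bins, unit area
```
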