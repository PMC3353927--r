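---
title: "An osmotic model of pollen-tube tip growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An osmotic model of pollen-tube tip growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmotip)
```

## The model

A pollen tube is treated as a cylinder of radius $r$ whose growth is
confined to the apex. Five coupled processes set the growth rate:

1. **Osmotic water entry.** Water crosses an apical permeable zone of
   length $L_{perm}$ (area $A_{mem} = 2\pi r L_{perm}$; the shank behind it
   is sealed by callose) at a rate set by the water-potential difference:
   $$\frac{dV}{dt} = P_{os} A_{mem} (\Delta\Pi - \Delta P),$$
   with $\Delta\Pi$ the osmotic and $\Delta P$ the turgor pressure
   difference across the membrane. Cylinder geometry converts volume to
   length: $dL/dt = (dV/dt)/\pi r^2$.

2. **Solute balance.** The internal osmotic pressure is van 't Hoff,
   $\Pi_i = RT\,m/V$; it rises with a solute accumulation rate $dm/dt$ and
   is diluted by water entry:
   $d\Pi_i/dt = (RT\,dm/dt - \Pi_i\,dV/dt)/V$.

3. **Viscous tip expansion.** Freshly exocytosed pectin forms a liquid
   film of thickness $L_{wall}$ over an apical disc of area $A_{tip}$.
   Turgor stretches it against a film tension $\gamma$
   (Young–Laplace): the area throughput is
   $$E = A_{tip}\,\frac{\max(0,\ \Delta P\,r/2 - \gamma)}{\eta\,L_{wall}},$$
   and the new area becomes shank surface, so $dL/dt = E/2\pi r$.

4. **Hardening.** Calcium cross-linking raises the film viscosity in
   proportion to the residence time of material in the film:
   $\eta = \eta_0 + \alpha\,A_{tip} L_{wall}/(dV_{wall}/dt)$. The
   hardening rate $\alpha$ is linear in external calcium and scales with
   $\sqrt{K_c D}$ (`hardening_law()`, `alpha_from_calcium()`).

5. **Wall-volume conservation.** Extrusion in, stretched film out:
   $dL_{wall}/dt = (dV_{wall}/dt - L_{wall} E)/A_{tip}$.

The **osmosensor** closes the loop: the cell senses the water-potential
difference $(\Delta\Pi - \Delta P)$ — the natural signal of a
semi-permeable pore — and sets the pectin extrusion rate,
$dV_{wall}/dt = K(\Delta\Pi - \Delta P)$, clamped at zero so deposition
only runs while water enters. At any steady state this coupling pins the
wall thickness at $L_{wall} = K r / (2 P_{os} A_{mem})$, independent of
the medium and of the hardening rate — which is why it is the only
coupling that stabilizes both turgor and thickness (see the screen below).

### Sensor output scales with the osmotic-zone area

We treat the sensors as molecules distributed over the permeable zone, so
the total output is $K \cdot (A_{mem}/A_{mem}^{ref}) \cdot
(\Delta\Pi-\Delta P)$. At the reference area this is exactly the intensive
law above. The distinction matters only when the zone itself changes size:
with a purely intensive sensor, a $\pm 1/3$ oscillation of $L_{perm}$
would force the steady wall thickness $K r/(2 P_{os} A_{mem}(t))$ to
oscillate by a third, whereas the area-scaled sensor keeps it constant
while pectin delivery doubles over a cycle in phase with growth — which is
the behaviour the driven-oscillation simulations require. We therefore
adopt the area-scaled form as a design choice.

## Turgor bookkeeping

Turgor is algebraic, not a state variable: the cytoplasm is treated as
incompressible, so the volume swallowed by elongation must equal the
osmotic influx, and at every instant
$$\Delta P = \Delta\Pi - \frac{r E / 2}{P_{os} A_{mem}}$$
(the rearranged influx law evaluated at the current smoothed expansion
throughput). The quasi-static balance solver (`solve_turgor()`, verified
against a bisection oracle) gives the same value whenever expansion is in
equilibrium with pressure, and in particular at every steady state — where
the discrepancy $\Delta\Pi - \Delta P$ equals $dV/dt / (P_{os} A_{mem})
\approx 0.43$ MPa at the calibrated operating point.

The expansion rate responds to pressure through short exponential
relaxations (half-times `ht_expansion` = dt/2 and `ht_turgor` = dt). This
one-step lag is not a numerical nuisance to be eliminated: it is what
gives the thin viscous film its instability. When the film softens (low
$\eta L_{wall}$), the pressure–expansion loop gain
$\approx (\Delta\Pi-\Delta P)/(\Delta P - 2\gamma/r)$ exceeds what the
smoothing can damp, the thickness oscillates at the iteration frequency
with growing amplitude, and the tip bursts — precisely how real thin films
fail, and the mechanism behind the bursting regimes below. Replacing the
lagged update by a fully implicit solve caps expansion at the water supply
and makes bursting impossible; we verified this and deliberately kept the
explicit scheme.

## Calibration of the standard parameter set

Geometry and permeability are measured quantities: $r = 8$ µm,
$r_{tip} = 2$ µm, $L_{perm} = 20$ µm, $P_{os} = 1.32\times10^{-3}$ cm/s
($9.36\times10^{-6}$ cm MPa$^{-1}$ s$^{-1}$), medium 0.3 Osm with 0.1 mM
calcium. The mechanical and supply constants are not directly measurable;
they are fixed once by requiring the steady state to reproduce the
observed operating point — growth $\approx 12$ µm/min, wall thickness
0.25 µm (TEM: 0.25 ± 0.07 µm), water-potential discrepancy 0.43 MPa with
turgor about half the osmotic gradient ($\Delta\Pi^* = 0.86$,
$\Delta P^* = 0.43$ MPa, consistent with osmotic pressures near 0.8 MPa
measured by incipient plasmolysis). Everything else follows algebraically
(see `tip_params()`): the conductance gives the influx, the influx the
area throughput, the throughput the extrusion rate (2.53 µm³/s), the
sensor gain $K = 2.53/0.43 \approx 5.9$ µm³ MPa$^{-1}$ s$^{-1}$, the
expansion law the operating viscosity (8.1 MPa s), and the solute balance
the supply rate ($2.62\times10^{-14}$ osmol/s).

Two constants required a choice rather than a derivation:

* $\eta_0 = 0.3$ MPa s — the viscosity of uncross-linked pectin sol, a
  small fraction (4%) of the operating viscosity, so that abolishing
  hardening leaves a film soft enough to spread catastrophically;
* $\gamma = 0.12$ MPa µm — a film tension small against the operating
  Young–Laplace tension (1.72 MPa µm), acting mainly as a floor that
  keeps the tension law stretching-only.

```{r params}
p <- tip_params()
p
```

## Time stepping and smoothing half-times

Integration is forward Euler at $dt = 0.4$ s, the scheme the model was
designed around; a halved step changes all steady-state summaries by well
under 1% (this is a test). Four half-times shape the fast dynamics; all
are configurable, and their defaults were fixed once against the
qualitative regime map of the perturbation batteries (which regimes grow
steadily, arrest, or burst), not against any quantitative target:

* `ht_expansion = dt/2`, `ht_turgor = dt`: damp the pressure–expansion
  loop at ordinary operating points while leaving soft-film configurations
  unstable (the bursting mechanism above).
* `ht_sensor = dt`: the response time of the signalling chain between
  sensor and exocytosis. It must be short: if deposition keeps running for
  several seconds after the driving force collapses (e.g. on a hypertonic
  step), the film inflates past the point from which growth can re-ignite
  and the cell freezes into arrest instead of re-equilibrating at a slower
  rate.
* `ht_param = dt/2`: external steps are effectively instantaneous
  (flow-chamber idealization). Hardening (calcium) steps are the
  exception: calcium equilibrates with the wall over seconds, so `alpha`
  steps ramp with a 10-s half-time by default. An instantaneous doubling
  of hardening would otherwise shut the sensor down faster than the
  mechanics can follow and spuriously burst the tip.

Initialization (`new_state()`) is a stationary 500-µm tube loaded with
solute at water equilibrium: $\Pi_i(0) = \Pi_o + \Delta\Pi^*$ and
$\Delta P = \Delta\Pi$, with the film at its calibrated thickness. Growth
develops within seconds as the algebraic turgor lets the film yield.

```{r baseline}
tc <- run(p, duration = 2000)
summary(tc)
```

## Perturbation scenarios

`scenario()` schedules step and sinusoidal perturbations on `C_o`,
`alpha`, `L_perm`, `dVwall_baseline` or `P_os_bar`; `preset_scenario()`
names the standard batteries (see `preset_names()`): the hardening battery
(calcium removal bursts the tip; 20× calcium arrests growth under a
thickened wall; halved hardening drops turgor abruptly and speeds growth
with unchanged thickness), the osmolarity battery (mild dilution speeds
growth at constant turgor and thickness; severe hypotonic shock bursts;
hypertonic medium slows growth, again at constant turgor and thickness),
the sinusoidal drives, and the whole-tube-permeability thought experiment.

```{r batteries}
for (nm in c("fig3_alpha_zero", "fig3_alpha_half", "fig5_hyper")) {
  tc <- run(p, nm, duration = 2500)
  cat(nm, "->", attr(tc, "outcome"), "\n")
}
```

### Driven oscillations

Externally driven sinusoids (the model has no endogenous pacemaker) probe
which variable could drive the observed ~1.2 min$^{-1}$ growth
oscillations. Driving pectin delivery or hardening makes turgor and/or
thickness oscillate — contrary to observation. Driving the osmotic-zone
length $L_{perm}$ by $\pm 1/3$ with the sensor active doubles the growth
rate over each cycle while turgor and thickness stay within a few percent;
without the sensor, both oscillate strongly and the wall eventually
escapes into runaway thickening — the unsensored film has only a finite
stability basin (its maximal outflow $A_{tip} T_{max}/\eta(L_{wall})$
falls below the fixed extrusion rate once $L_{wall}$ exceeds about twice
its operating value).

### Whole-tube permeability

If impermeabilization halts, membrane laid down after $t_0$ stays
permeable: $A_{mem} = 2\pi r (L_{perm} + L - L_0)$, with solute uptake
scaled per unit membrane area (transport scales with membrane), which pins
the operating pressures while growth scales with the permeable area. The
result is growth accelerating in proportion to length — incompatible with
the observed length-independence of growth rates, which is the argument
for a tip-confined osmotic zone of fixed size. These runs use $dt =
0.05$ s with the half-times held at their absolute values: the
pressure-feedback damping term scales as $1/A_{mem}$, so the 0.4-s step
becomes under-damped as the area grows; trajectories are analyzed over the
first ~250 s, after which the discrete relaxation oscillation re-emerges
even at the finer step.

## The sensor screen

`sensor_screen()` crosses the three sensable intensive variables
($\Delta\Pi-\Delta P$, $\Delta\Pi$, $\Delta P$) with the three settable
rates (wall extrusion, solute accumulation, hardening), auto-calibrating
each gain so all couplings share the same unperturbed operating point,
plus a no-sensor control. Each coupling is tested for whether it admits
steady growth at all, then perturbed (osmolarity ×1.5; hardening ×0.5,
the published halved-hardening manipulation; zone-length sinusoid ±50%)
and classified: a quantity "changes" when its maximum deviation from the
pre-perturbation mean exceeds 10% — the classification threshold is a
design choice, as no numeric criterion is published.

Only the water-potential → wall-extrusion coupling leaves both turgor and
thickness unchanged under the experimentally accessible perturbations.
Both turgor-input couplings on mechanics fail outright (burst or arrest
from the standard start). Two known limitations of the reproduction:

* the no-sensor cell under the ×1.5 osmolarity step runs into the
  thickening runaway (arrest), so its turgor is classified "changed"
  where the published table reports it unchanged;
* the three solute-rate couplings do admit steady growth here when
  started near the operating point (the solute balance pins $\Pi_i$ and
  the constant-extrusion wall branch is locally stable), though every
  ≥50% perturbation destroys them; the original report eliminated them as
  having no steady growth at all.

## Plasmolysis and the osmotic zone

A hypertonic step (0.3 → 0.8 Osm) pulls the cytoplasm off the apical
wall. Because detached wall no longer passes water (the unstirred layer
behind the retracting membrane), efflux is proportional to the remaining
permeable contact area, giving
$x(t) = l\,(1 - e^{-kt})$ with $k = 2 P_{os} \Delta\Pi / r$
(`retraction_forward()`, validated against a numerical integration of the
mass balance). The plateau $l$ measures the osmotic-zone length and the
rate constant the permeability; `fit_retraction()` recovers both by
Levenberg–Marquardt least squares, with the plateau flagged as weakly
identified when the curve is short compared with $1/k$.
`synth_retraction()` generates seeded noisy curves for calibration
studies; it emulates saturating retraction with additive Gaussian
measurement noise, but not tracking artefacts, tube-to-tube parameter
spread, or the slow residual shrinkage of the detached state — so
parameter-recovery results bound the statistical error of the fit, not
the biological variance of real curves.

```{r plasmolysis}
cv <- synth_retraction(P_os = 1.32e-3, l = 20, noise_sd = 0.5, seed = 1)
est <- fit_retraction(cv)
c(P_os_cm = est$P_os_cm, l = est$l)
```

## Degenerate inputs and numerical choices

* Zero extrusion ⇒ viscosity cap ($10^6 \eta_0$): a fully hardened film.
* $L_{wall} \le 0.2$ nm ⇒ burst: the state is frozen, the burst sample is
  recorded with zero pressure gradients, and nothing is recorded after.
* Negative $\Delta\Pi$ ⇒ plasmolytic efflux: expansion stops and volume
  is lost through the permeable zone.
* Tension clamp: $T = \max(0, \Delta P r/2 - \gamma)$; the film is only
  ever stretched.
* All runs are bit-reproducible given identical parameters, scenario and
  step (no hidden randomness in the integrator; only the plasmolysis
  noise generator consumes a seed).

## Problem sizes

The test-suite and worked examples use 1000–3000-s simulations at
$dt = 0.4$ s (2500–7500 steps, a second or two each), the sensor screen
runs 10 couplings × (1 unperturbed + 3 perturbed) trajectories, and
parameter-recovery studies use 50 seeded replicates of 31-point curves —
sizes chosen to characterize steady states and regime boundaries cleanly.

## Known limitations

The model is a well-mixed, isotropic description of the apical disc: it
does not predict tip shape, wall anisotropy, or spatial calcium and
methyl-esterification profiles (the hardening law keeps only the
$C_{Ca}\sqrt{K_c D}$ proportionality; any thickness-dependence of the
hardening rate is an extension point). Oscillations are externally driven
only — the model deliberately contains no pacemaker. Bursting times
depend on the discrete scheme (the instability is seeded at the iteration
frequency), so only the occurrence and ordering of bursts is meaningful,
not their precise timing. The screen limitations are listed above.
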