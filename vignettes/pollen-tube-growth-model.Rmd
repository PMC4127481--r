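---
title: "An integrative model of oscillatory pollen tube growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative model of oscillatory pollen tube growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Pollen tubes elongate by tip growth and, in culture, their growth rate
oscillates with a period of tens of seconds. Two classic views of what
paces growth — cell wall mechanics versus turgor-driven hydrodynamics —
make different predictions about how the oscillation should respond to the
osmolarity of the medium and to wall stiffness. `pollentube` implements a
model that couples the two views through ion dynamics, so that neither the
wall nor the water flow can be changed without the other adjusting.

Three layers are integrated, all referring to the growing tip region of a
cylindrical cell of outer radius $r$:

**Hydrodynamics.** Water enters across a fixed osmotic-zone membrane area
$A_{osm}$ at the tip:
$$\frac{dv}{dt} = L_p A_{osm}\,\big[(\pi_i - \pi_o) - P\big],$$
with $L_p$ the hydraulic conductivity, $\pi_i, \pi_o$ the cellular and
media osmotic pressures ($\pi = RT \sum c$, reflection coefficient 1) and
$P$ the turgor. Because $A_{osm}$ is an (experimentally supported) fixed
area rather than scaling with the cell, growth is linear rather than
exponential; the package contains a property test showing that making
$A_{osm} \propto v$ restores exponential growth.

**Wall mechanics.** The wall yields plastically only in the extensible tip
volume $v_{ext}$ and only above a critical turgor $P_c$ (Lockhart), plus an
elastic term with volumetric modulus $\varepsilon$:
$$\frac{dv}{dt}\Big|_{wall} = v_{ext}\,\phi\,\max(P - P_c, 0)
  + \frac{v}{\varepsilon}\frac{dP}{dt},
  \qquad \phi = 1/\eta .$$
The extensibility $\phi$ is the inverse of a wall viscosity $\eta$ that is
softened by calcium-dependent vesicle secretion $R_s = k_2 [Ca^{2+}]_i$
(with $k_2 = k_{2a}/r^2$) and matures back toward an equilibrium value:
$d\eta/dt = -\eta R_s / h + k_1(\eta_{eq} - \eta)$. Wall thickness $h$
thins with elongation and thickens with secretion. Because the water volume
and the wall-chamber volume of the cell are one and the same, turgor is not
a free parameter: it evolves as
$\,dP/dt = \varepsilon\,(\text{relative water rate} - \text{relative
plastic wall rate})$, which the test suite verifies as an exact identity
along every trajectory.

**Ion dynamics.** Four cytosolic ion concentrations
($Ca^{2+}, H^+, K^+, Cl^-$) obey flux balances
$$\frac{d[X]_i}{dt} = -\frac{OV \sum I_X}{z_X F}
  - k_X([X]_i - [X]_s) - \frac{1}{v}\frac{dv}{dt}[X]_i + \text{buffering},$$
where $OV = 2/r$ is the transporter surface-to-volume ratio, the $I_X$ are
membrane current densities, the relaxation terms exchange material with the
shank reservoir at set-points $[X]_s$, and growth dilutes everything. The
transporters are: an inward- and an outward-rectifying K⁺ channel, a
voltage-gated Ca²⁺ channel, a plasma-membrane H⁺ pump, a 2H⁺/Cl⁻ symporter,
a depolarisation-activated anion channel, and turgor-gated stretch-activated
Ca²⁺ and K⁺ channels whose opening rate grows as $e^{k_a P}$. Channel
currents use the Goldman–Hodgkin–Katz constant-field form (zero at the
Nernst potential, bounded as a pool depletes); the membrane potential $V$
closes the loop through charge balance over the specific capacitance $C_m$.

## Where the oscillation lives

The detailed kinetics of the six voltage-gated transporters are published
elsewhere and are represented here by generic kernels. A design question we
had to settle was whether purely instantaneous (Boltzmann) voltage gating
suffices. It does not: with no slow variable inside the transporter set,
the only possible oscillations are turgor-gated pool-discharge cycles, and
those cannot simultaneously produce (i) turgor oscillations below the
0.0009 MPa detection bound, (ii) a cellular osmotic pressure that stays
nearly constant when the medium is diluted, and (iii) periods that scale
with osmolarity. We therefore gave the outward-rectifier K⁺ channel a slow
first-order activation gate $n(t)$ with time constant $\tau_n$
(Morris–Lecar structure), consistent with the slow gating in the ion models
this architecture descends from. The voltage subsystem then supports a
robust relaxation oscillation: a depolarising phase carried by the Ca²⁺ and
anion channels vents KCl and admits a Ca²⁺ pulse (which drives secretion
and wall softening), and the delayed rectifier repolarises the membrane
while the shank exchange refills the pools.

Turgor modulates this oscillator through the stretch-activated channels:
higher mean turgor opens them, adds inward current, and shortens the cycle.
Because turgor itself is a heavily filtered integral of the osmotic
imbalance (soft elastic modulus, large cell volume), its own oscillation
amplitude stays near 0.0006 MPa even though the growth rate oscillates by
around 10 percent — reconciling the pressure-probe observation of "no
turgor oscillation" with strongly oscillatory growth.

## What the scenarios reproduce, and one honest failure

With the shipped calibrated parameter set the model reproduces, from one
configuration:

- isotonic (0.36 Osm) growth of about 3.9 µm/min oscillating at about 50 s,
  with mean turgor 0.214 MPa and turgor amplitude about 0.0006 MPa;
- a halved period (about 25 s) and smaller turgor amplitude (about
  0.0002 MPa) after a shift to 0.18 Osm, with the cycle-mean turgor rising
  to about 0.233 MPa and the extensibility from 0.045 to about
  0.053 MPa⁻¹s⁻¹, while the cellular osmotic pressure stays nearly
  constant;
- the regulation-coefficient pattern: for the osmotic comparison the media
  osmotic pressure dominates the water side ($R^w_{\pi_o} \approx 1.06$)
  and turgor the wall side, whereas for the wall-viscosity comparison
  (125 vs 225 MPa s) extensibility dominates the wall side
  ($R^c_\phi \approx 3.9$) with a negative turgor coefficient and
  $R^w_P \approx 1$ on the water side — the context-dependence of turgor
  control;
- an approximately 19-fold span of volume change across media osmolarities
  0.06–0.46 Osm at low wall viscosity, over a turgor range of only a few
  hundredths of a MPa;
- slower growth of the membrane-trafficking mutant scenario and continued
  oscillation under raised media calcium or lowered media pH.

The hypertonic scenario (1.16 Osm) is the honest failure: sustaining growth
there requires the cytosol to raise its osmolarity by roughly 0.7 M. In
this implementation the tip pools exchange with fixed shank set-points —
the same choice that keeps the cellular osmotic pressure constant under
dilution, as the printed regulation coefficients imply — so the cell
cannot adjust, turgor falls below the yield threshold and growth stalls
instead of oscillating at the observed longer period. A model that meets
the hypertonic observation needs an osmotic-adjustment pathway (for
instance, set-points that track the medium) that the published equations do
not specify.

## Parameters, units and numerical choices

All internal arithmetic is strict SI (Pa, m, s; concentrations in molar
with explicit conversion to mol m⁻³ where needed); configuration files may
use MPa, µm, mM and Osm (`units: user`). The full catalogue with admissible
ranges is `paramTable()`. Values printed in the experimental literature are
fixed: $L_p = 10^{-12}$ m s⁻¹ Pa⁻¹, $k_{2a} = 2.15\times10^{-14}$
m³ M⁻¹ s⁻¹, radii and media compositions, and the 100-fold fusion-rate
reduction of the trafficking-mutant scenario. Two printed numbers conflict:
$k_{2a}/r^2$ at $r = 5$ µm gives $8.6\times10^{-4}$, not the
$4.1\times10^{-4}$ m M⁻¹ s⁻¹ quoted alongside; we implement the literal
$k_2 = k_{2a}/r^2$. Everything not printed is a calibration output
(`calibratedParams()`), recovered during development by staged design plus
Latin-hypercube screening against the stated experimental constraints;
`calibrate()` exposes the same seeded workflow (screening then Nelder–Mead
polish) at desk scale.

Numerical choices worth knowing:

- the stiff integrator is `deSolve::lsoda` at `rtol = 1e-8` with per-state
  absolute tolerances, restarted at protocol breakpoints; step protocols
  are encoded as 1 s linear ramps so the right-hand side stays continuous;
- the stretch-gate opening rate $k^0_{CO} e^{k_a P}$ is capped at
  $10^4$ s⁻¹ — the open fraction saturates long before, and the cap keeps
  the gate equation integrable during extreme turgor transients;
- wall thickness is floored at 1 nm inside the right-hand side (with a
  warning on output) because the viscosity equation divides by $h$;
- the GHK current switches to its series limit for $|zV/V_{ref}| < 10^{-6}$;
- the buffering terms of the ion balance are linear relaxations toward the
  set-points with shipped strength zero: cytosolic Ca²⁺ and pH buffering are
  folded into the fast relaxation rates $k_{Ca}, k_H$, which is why those
  two rates are orders of magnitude larger than the K⁺/Cl⁻ exchange rates;
- exact-period averaging uses trapezoidal means over the window from one
  (large-)peak maximum to the next; peaks are found with a prominence
  threshold of 5 % of the analysed range, alternating large/small peaks are
  classified by a 0.5 prominence-ratio threshold, and the period is the
  mean peak spacing (robust to sampling quantisation);
- the surface-to-volume scaling property (equal ion dynamics when $OV$ is
  scaled up and conductances down) holds exactly when the capacitive
  loading is scaled with the conductances, since the membrane-potential
  closure is ours rather than part of the original four-ion balance.

## What the scenario engine emulates — and what it does not

Scenario protocols are piecewise-linear time courses of everything the
experimenter controls: media composition, equilibrium wall viscosity,
cellular non-ionic osmolyte (oil injection), fusion-rate scale and the
prescribed radius trajectory. The radius is an input, not an emergent
quantity; volume change is converted to elongation through the cylinder
geometry, including the radius-ramp term. Simulations in this vignette and
in the tests start from the stored calibrated limit-cycle state, so figures
need no burn-in; cold starts (`initState()`) converge to the same cycle, a
property the test suite checks with ±10 % perturbed initial conditions.

Passing tests show that the deterministic, regular-waveform model behaves
as designed. Real growth-rate records have irregular shapes and secondary
frequencies that this model intentionally does not produce, there is no
spatial resolution of the tip, no stochastic channel gating, and no
vesicle-trafficking detail beyond the fusion-rate scale. Conclusions about
real tubes should lean on the reproduced aggregate observables (periods,
amplitudes, mean turgor, regulation coefficients), not on waveform details.

## Problem sizes

The shipped analyses integrate 7 200–15 000 s of model time per scenario at
a 0.25 s sampling interval; a full scenario takes on the order of a second
of wall time with the compiled right-hand side, and the complete
reproduction script (`scripts/acceptance.R`) runs in well under a minute.

## A worked run

```{r, eval = FALSE}
library(pollentube)

params <- calibratedParams()
sc <- buildScenario("isotonic", params = params, t_end = 7200)
traj <- runSimulation(sc$params, sc$protocol, init = calibratedInit(),
                      solver = solverSettings(sample_dt = 0.25))

oscillationOf(traj, "growth_um_min")
#> OscillationSummary 'growth_um_min': period 49.56 s, amplitude 0.2831,
#>   baseline 3.88772
#>   72 cycles, simple peak pattern

hypo <- buildScenario("osmolarity_sweep", params = params, t_end = 7200,
                      overrides = list(Osm_total = 0.18))
traj18 <- runSimulation(hypo$params, hypo$protocol, init = calibratedInit(),
                        solver = solverSettings(sample_dt = 0.25))
regulationReport(traj, traj18, labels = c("0.36 Osm", "0.18 Osm"))
```
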