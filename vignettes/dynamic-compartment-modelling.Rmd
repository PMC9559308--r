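---
title: "Data-based dynamic compartment modelling of a fed-batch bubble column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-based dynamic compartment modelling of a fed-batch bubble column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomp)
```

## The problem

Industrial fed-batch fermentations in large bubble columns are not well
mixed: the broth volume grows continuously, the gas flow (and with it
the liquid circulation) changes over the process, and substrate fed at
the surface must travel tens of metres before reaching cells at the
bottom. `dyncomp` builds a *dynamic compartment model* of such a vessel
directly from data logged by neutrally buoyant flow-following sensor
devices, and couples it to fermentation kinetics so that mixing
performance and concentration gradients can be simulated cheaply over a
whole process.

The pipeline has five stages, each usable on its own:

1. **Trace processing** — pressure/temperature logs to axial kinematics.
2. **Compartment building** — kinematics to a time-resolved network of
   ideally mixed zones exchanging liquid.
3. **Tracer simulation** — 95% mixing times for arbitrary feed points.
4. **Fermentation simulation** — biomass/substrate/product/DO fields
   with oxygen transfer and surface feeding.
5. **Calibration** — derivative-free fitting of the kinetic parameters
   to sampled concentrations.

A sixth component, the synthetic virtual plant, generates all of these
inputs with known ground truth; every quantitative claim made by the
package's tests is made against that ground truth.

## From pressure to position

A flow-follower carried by the broth logs absolute pressure at 1 Hz.
Hydrostatics (Pascal's law) turns pressure into depth below the
surface, so the axial position above the vessel bottom is

$$z(t) = \frac{P_{max}(t) - P(t)}{\rho_f\, g},$$

where $P_{max}$ is the pressure at the vessel bottom and $\rho_f$ the
density of the gas–liquid dispersion. Neither is constant: the
headspace pressure drifts, the liquid level rises as feed accumulates,
and the gas hold-up changes with the aeration rate. The package
therefore:

* estimates $P_{max}(t)$ as a **rolling maximum** of the measured
  pressure over a 1-hour window (the device visits the bottom at least
  once per window), smoothed by a 600 s rolling mean to remove the
  staircase artifacts of the maximum filter. The smoothing window is
  not dictated by the physics; 600 s is short enough to follow the
  volume ramp (about 0.3 m/hr in the reference scenario) and long
  enough to suppress the sawtooth of the maximum filter. Both windows
  are arguments.
* estimates the gas hold-up from the superficial gas velocity with the
  heterogeneous-regime correlation
  $\epsilon = v_s / (0.25 + 0.45\,(g\,v_s\,D)^{1/3})$, and the
  dispersion density as the volume-weighted mean
  $\rho_f = (1-\epsilon)\rho_l + \epsilon\rho_g$ with
  $\rho_l = 1030$ kg/m³.
* corrects the normalised gas flow to in-situ conditions by ideal-gas
  scaling. By default the pressure used here is the device pressure
  averaged over the baseline window: the device sweeps the whole
  height within that window, so this approximates the column-mean
  pressure, which is the quantity consistent with the single
  instantaneous $\rho_f$ that the position formula assumes. Using the
  raw local pressure instead (`vs_correction = "instantaneous"`)
  imprints the vertical density profile onto $z$ and costs roughly 2%
  of the liquid height in systematic error on synthetic data.

The rolling-maximum baseline absorbs headspace-pressure offsets and
drifts slower than twice its window, but not perfectly: the same
pressure also enters the gas-velocity correction, where an offset is
indistinguishable from real pressurisation, so a 21 kPa back-pressure
step shifts recovered positions by a few tenths of a percent of the
liquid height (through $\epsilon$ and $\rho_f$) rather than zero.

Axial velocity is obtained by central finite differences after a 5 s
moving average of $z$; at 1 Hz sampling and pressure noise of order
100–200 Pa, the position noise (~2 cm) is far below the metre-scale
motion, and the 5 s window suppresses it without erasing the
circulation velocities (0.2–2.5 m/s in the reference field). The cost
is resolution: the velocity estimate at a height mixes information
over a span of roughly twice the local speed times the stencil length
(2 s unsmoothed, up to 7 s with the default window), i.e. metres at
circulation speeds of 1–2 m/s. Mean speeds are biased low near
direction reversals (order 10% for 30 s runs under the default
window), and sharp spatial changes in the field are smeared over the
stencil's reach. The flow-recovery tests therefore use fields whose
structure is wider than the stencil support and disable the extra
smoothing; on fields with fine structure the estimated exchange flows
are best read as stencil-averaged.

## The dynamic compartment model

Every update step (default 1 hr) gets its own axial discretisation:

* the liquid height is the pressure swing seen by the pooled devices in
  the window, $(P_{max}-P_{min})/(\rho_f g)$, which assumes each device
  traverses the full height within the step (a warning is raised when
  the observed swing covers less than 90% of the previous height);
* interfaces are laid every $\Delta z_0 = 0.5$ m; a remainder shorter
  than $0.25\,\Delta z_0$ is absorbed into the top compartment rather
  than forming a sliver;
* the mean speed $\langle|v_z|\rangle$ is collected at each internal
  interface from samples within a capture band of one compartment
  height, and the bidirectional exchange flow through the interface is
  $Q = A\,(1-\epsilon)\,\langle|v_z|\rangle/2$ — half up, half down, so
  the closed column has zero net axial flow;
* interfaces with fewer than 30 velocity samples are dropped, locally
  doubling the compartment height; two consecutive deficient interfaces
  abort the build with an error naming the step and height, rather than
  silently interpolating flows.

Compartments are then merged bottom-up into ideally mixed *zones*: a
zone grows while its residence time (zone volume over the smallest
internal interface flow) stays below the critical residence time
$\tau_{crit} = 1.5$ s. The greedy bottom-up, first-fit order is a
choice; it is deterministic, and scaling all flows up can only merge
further (a property the tests assert on random networks). Volumes and
flows are scaled by the liquid fraction $(1-\epsilon)$ throughout, and
each zone carries the mean pressure and temperature of the samples that
fell in it, which later set the local oxygen saturation and kLa.

Within a step, volumes and flows are frozen; between steps, species
masses are re-binned conservatively onto the next geometry in three
stages (concentration to mass; geometry scaled by the total-volume
ratio; mass split by fractional volume overlap). The overlap map is
exact, so re-binning conserves mass to machine precision regardless of
how the zone boundaries move.

## Mixing times

A pulse of passive tracer is injected into one zone and the linear
exchange ODEs are integrated (LSODA). The homogenised concentration is
taken as the volume-weighted mean 10 min after the pulse, and the
deviation metric is the volume-weighted root-mean-square of
$\log_{10}$ normalised responses,

$$m(t) = \Big(\sum_k w_k \log_{10}^2 \frac{C_k(t)}{C_\infty}\Big)^{1/2},
\qquad w_k = V_k / \textstyle\sum_j V_j,$$

with the 95% threshold $|\log_{10} 0.95| \approx 0.0223$ chosen so that
the scalar criterion coincides with "every compartment within ±5%" in
the single-worst-compartment limit. The mixing time $t_{m95}$ is the
last crossing of the threshold, linearly interpolated on the output
grid; the horizon doubles adaptively (capped at $10^5$ s) and an
isolated zone yields `Inf`, never a silent number. Volume weighting is
a choice — an unweighted variant is available (`weighted = FALSE`) —
and normalised responses are floored at $10^{-6}$ so the metric stays
finite ahead of the tracer front. Because the system is linear, the
pulse magnitude is arbitrary and $t_{m95}$ scales exactly as $1/\alpha$
when all flows are scaled by $\alpha$; the tests assert both, and check
two- and three-zone transients against matrix-exponential closed forms.

## Fermentation kinetics

Each zone carries biomass, substrate, product and dissolved oxygen.
Growth is Monod in substrate and oxygen with linear product inhibition,

$$\mu = \mu_{max}\,\frac{C_s}{C_s+K_s}\,\frac{C_o}{C_o+K_o}
\Big(1-\frac{C_p}{K_p}\Big),$$

negative above the critical product concentration $K_p$ (cell death).
Product formation follows Luedeking–Piret,
$r_p = Y_{px}\mu + r_{x,p}$; substrate and oxygen uptake are
yield-linked, $r_s = \mu/Y_{xs} + r_p/Y_{ps} + r_{m,s}$ and
$r_o = r_s/Y_{so} + r_{m,o}$. Feed enters the top zone (or any
configured set of zones) as a mass rate constant within each step, and
oxygen transfer is $k_La\,(C_o^* - C_o)$ with $C_o^*$ from Henry's law
at the zone's mean pressure ($x_{O_2} = 0.2095$,
$H^{cp} = 0.0015$ mol/L/atm at 306 K) and $k_La = c\,v_s$ from the
local superficial gas velocity.

Two starvation gates close the model where the literal equations are
silent: the substrate-consuming terms that do not vanish with the Monod
factor ($r_{x,p}$ and $r_{m,s}$) are multiplied by
$C_s/(C_s + 10^{-3}\,\mathrm{kg/m^3})$, and the whole oxygen uptake by
$C_o/(C_o + 10^{-5}\,\mathrm{kg/m^3})$. Without the gates the solver
drives depleted species below zero (maintenance would consume substrate
that is not there, respiration oxygen that is not there); with them,
uptake shuts down over a concentration range far below measurement
resolution. Reported concentrations are additionally floored at zero to
remove solver undershoot within tolerance.

On the printed coefficient $c = 0.288$ (1/hr)/(m/s): taken at face
value it yields $k_La \approx 0.06$ 1/hr at the reference gas
velocities — orders of magnitude below what any aerobic production
vessel achieves, and too small to sustain measurable oxygen transfer.
`local_kla()` keeps 0.288 as its default so the correlation is exactly
as stated, but the coefficient is an argument everywhere, and the
reference scenario uses $c = 3000$ (1/hr)/(m/s), i.e.
$k_La \approx 0.08$ 1/s at $v_s \approx 0.1$ m/s, consistent with
standard bubble-column correlations.

The solver is LSODA with a banded Jacobian: states are ordered
zone-major (four species per zone) so neighbour coupling sits four
diagonals away, and the right-hand side is implemented in C (an R
reference implementation is kept and the two are asserted equal in the
tests). Default tolerances are `rtol 1e-8`, `atol 1e-10`; the
conservation tests tighten them to `1e-11/1e-13` to expose the chain's
own drift rather than the integrator's.

## Calibration

Parameters are fitted by Nelder–Mead on the sum of squared errors
between simulation and observations: biomass, substrate and product
against the volume-weighted height-average concentration, dissolved
oxygen against the zone containing the probe height (5.85 m). Because
the variables differ by orders of magnitude (130 kg/m³ of product vs.
0.01 kg/m³ of DO), the default weights are the reciprocal variance of
each variable's observations; plain unweighted SSE is available
(`weights = "none"`). The search runs in log space to keep parameters
positive without imposing stoichiometric constraints; raw-space search
is a flag. A failed simulation returns a large finite penalty so the
simplex can retreat.

Identifiability is verified by recovery, not asserted: the reference
scenario is simulated at the truth, observed at 15 times with 5%
multiplicative lognormal noise, and refitted from a deliberately
displaced start (+50% $\mu_{max}$, −30% $K_p$, +40% $Y_{px}$) for ten
noise realisations. Median recovery errors for $\mu_{max}$, $K_p$ and
$Y_{px}$ are a few percent. $K_o$ is practically unidentifiable in this
design — dissolved oxygen is never limiting at the probe — and is
reported as such by `recovery_report()` rather than forced.

## The synthetic plant

The virtual plant emulates the study conditions: a 5.3 m diameter
column, gassed liquid height ramping 16 m to 26 m over a 32 hr
fed-batch, a gas-flow profile holding 4.75 Nm³/s through mid-process
and ramping down late, a slowly drifting headspace pressure around
121 kPa, and a single-peak axial circulation field (weak near the ends,
up to ~2.3 m/s mid-column, scaling with the gas flow to the 2/3 power).
Devices are modelled as telegraph random walkers: they move with the
local field speed, reverse direction at a mean run time of 30 s, and
reflect at the bottom and the rising surface — this reproduces the only
statistics the pipeline consumes (interface-crossing speeds, occupancy,
full-height sweeps within an hour) at trivial cost. Emitted pressure is
hydrostatic with the instantaneous column-mean dispersion density plus
Gaussian sensor noise (200 Pa by default); temperature is fixed at
306 K. Truth kinetics are order-of-magnitude literature-style values
for an aerobic glucose→1,3-propanediol *E. coli* process, chosen to
give early substrate depletion, persistent DO gradients and a final
product concentration near 135 kg/m³.

What the plant does *not* emulate: radial motion, bubble-scale physics,
device slip and buoyancy transients, thermal gradients, non-hydrostatic
pressure fluctuations, and broth rheology. Passing round-trip tests on
this plant therefore demonstrates the pipeline's internal consistency
and its noise robustness — not that a real vessel satisfies the
hydrostatic and full-sweep assumptions.

## Numerical choices and degenerate inputs

* Rolling max/min are computed with an $O(n)$ two-pass block scan with
  exact centred partial windows; 12 hours of 1 Hz data processes in
  well under a second.
* Problem sizes used in the packaged tests and the acceptance script:
  three devices at 1 Hz for 32 hr (~350k samples), 32 update steps of
  33–53 initial compartments, tracer networks of 2–9 zones for the
  analytic oracles, ten calibration refits of three parameters.
* Positions implying $z < 0$ clip to 0, and $z > H_L$ to the
  instantaneous height; both occur only through noise at the extremes.
* A trace shorter than the baseline window, an empty update-step
  window, empty observation sets, non-positive volumes and a
  `tau_crit <= 0` all raise immediate errors naming the offending
  quantity.
* Ties in the greedy zoning cannot occur with continuous flows; equal
  residence time exactly at `tau_crit` merges (the rule is `<=`).

## Limitations

The compartment network is exclusively axial — radial homogeneity is
assumed, which is reasonable at height-to-diameter ratios of 3–5 but
untested here. The bottom head is treated as cylindrical, slightly
overestimating the bottom volume. Gas-phase oxygen depletion along the
height is ignored (constant $x_{O_2}$), oxygen solubility is that of
pure water, and CO₂ inhibition and the glycerol intermediate are out of
scope. Cells adapt instantly to local conditions — no memory of the
fluctuations a circulating cell actually experiences — so gradient
effects on physiology are, if anything, underestimated.
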