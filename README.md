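# dyncomp — data-based dynamic compartment modelling of bubble-column bioreactors

`dyncomp` builds reduced-order flow models of large (hundreds of m³)
bubble-column fermenters directly from the pressure logs of
flow-following sensor devices — instrumented, neutrally buoyant spheres
carried around by the broth — and uses them to answer process-engineering
questions that are impractical to answer with CFD over a whole fed-batch:
how long does mixing take at each stage of the process, where should the
feed enter, and what concentration gradients do the cells actually see?

It is written for fermentation and bioprocess engineers working with
Lagrangian sensor data (or wanting to prototype against a synthetic
plant before a campaign), and implements the full chain:

1. **Trace processing.** Hydrostatics converts a device's pressure log
   into axial position, `z(t) = (P_max − P(t)) / (ρ_f g)`, with a
   rolling-maximum baseline absorbing headspace-pressure drift and
   volume growth, gas hold-up from the heterogeneous-regime correlation
   `ε = v_s / (0.25 + 0.45 (g v_s D)^{1/3})`, and dispersion density
   `ρ_f = (1−ε) ρ_l + ε ρ_g`.
2. **Dynamic compartment model.** Per update step (default 1 hr) the
   column is sliced into 0.5 m compartments; bidirectional exchange
   flows `Q = A (1−ε) ⟨|v_z|⟩ / 2` are estimated from the velocity
   samples at each interface; slices are auto-merged into ideally mixed
   zones wherever the local residence time `V/Q` stays below
   `τ_crit = 1.5 s`.
3. **Mixing-time simulation.** Pulse-tracer ODEs on the zone network;
   `t_m95` from the volume-weighted RMS of log-normalised responses.
4. **Fed-batch fermentation simulation.** Per-zone balances for
   biomass, substrate, product and dissolved oxygen with Monod growth
   (`μ = μ_max · C_s/(C_s+K_s) · C_o/(C_o+K_o) · (1 − C_p/K_p)`),
   Luedeking–Piret production (`r_p = Y_px μ + r_xp`), yield-linked
   uptake, Henry's-law oxygen saturation, `kLa = c·v_s`, surface (or
   arbitrary) feeding, and conservative re-binning of species masses
   between update steps as the geometry evolves.
5. **Calibration.** Nelder–Mead minimisation of the (variance-weighted)
   SSE between simulated and observed concentrations, with
   recovery-based identifiability reporting.
6. **Synthetic plant.** A virtual reactor (telegraph random-walk
   devices in a prescribed circulation field, with truth kinetics) that
   generates every input with known ground truth — the basis of all
   packaged tests.

## Worked example

```r
library(dyncomp)

# 1. Synthetic plant: three flow-followers logged over the first 6 hr
spec <- reference_plant()
ds   <- plant_dataset(spec, n_devices = 3, seed = 42, duration = 6 * 3600)

# 2. Pressure traces -> axial kinematics
kins <- lapply(ds$traces, process_trace,
               geometry = spec$geometry, gas_profile = spec$Q_g)

# 3. Kinematics -> dynamic compartment model (1-hr update steps)
model <- build_dynamic_model(kins, spec$geometry)
model
#> Dynamic compartment model: 6 update steps, H_L 16.4 -> 17.9 m, 23-24 zones per step, tau_crit = 1.50 s

# 4. 95% mixing time for surface vs. mid-height feeding
scan <- feed_point_scan(model, c(surface = Inf, mid = 8))
print(scan[, c("step", "feed_label", "feed_zone", "t_m95_s")], digits = 3)
#>    step feed_label feed_zone t_m95_s
#> 1     1    surface        23   152.9
#> 2     1        mid        12    50.4
#> 3     2    surface        23   142.7
#> 4     2        mid        12    46.8
#> ...
```

The model print shows the liquid height rising as feed accumulates and
the fine 0.5 m slices merging into ~23 mixed zones. The scan shows the
headline engineering result: feeding at mid-height homogenises a pulse
roughly three times faster (~50 s vs. ~150 s) than feeding at the
surface, because the axial flows are strongest mid-column and the
tracer's travel distance is halved.

From here, `simulate_fermentation()` couples the model to kinetics
(returning per-zone trajectories, height-averaged summaries and the
volumetric productivity `q_p`), `make_observations()` samples noisy
synthetic assay data, and `fit_parameters()` recovers kinetic
parameters from such data.

A command-line front end wrapping the same pipeline is installed at
`inst/cli/dyncomp.R` (stages `synth | process | build | mix | simulate
| fit`, JSON configuration).

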