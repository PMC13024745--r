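# gelsolv

Solubilization analytics for drug–ligand small-molecule hydrogels.

Poorly water-soluble drugs (BCS class II, e.g. the NSAID sulindac) can be
solubilized by co-assembly with a small-molecule ligand such as meglumine
(N-methyl-D-glucamine): the pair forms a 1:1 complex in solution and, at the
right ratio, a supramolecular hydrogel that releases the drug in a sustained,
supersaturated state. gelsolv implements the quantitative layer of that
formulation workflow for R users:

* **Miscibility screening** — group-contribution Hansen solubility
  parameters, `δ² = δd² + δp² + δh²` with
  `δd = Σ nᵢF_dᵢ / V`, `δp = √(Σ nᵢF_pᵢ²) / V`, `δh = √(Σ nᵢE_hᵢ / V)`,
  and the screening rule *miscible iff |δ_a − δ_b| < 7 MPa^½*.
* **Phase-solubility analysis** — the 1:1 Higuchi–Connors model
  `S_T = S₀ + [K₁:₁S₀/(1 + K₁:₁S₀)]·L_T`, stability-constant estimation
  `K₁:₁ = slope / (S₀(1 − slope))`, mass-action speciation, A_L/A_N diagram
  classification with statistically calibrated breakpoint detection, and a
  free-ligand aggregation model for the negative deviation at high ligand
  concentration.
* **Dissolution analytics** — sampling-corrected cumulative release for
  withdraw-and-replace protocols, `A_n = C_nV + v·Σ_{i<n}C_i`;
  apparent-solubility enhancement ratios; supersaturation folds, C_max and
  AUC.
* **Synthetic data** — generators for both experiment types with exported
  ground truth, so every estimator is validated end-to-end without
  laboratory data.

## Worked example

```r
library(gelsolv)

# Hansen parameters from the shipped group decompositions
sul <- compute_hansen(read_composition(
  system.file("extdata", "sulindac_groups.csv", package = "gelsolv")))
sul
#> Hansen solubility parameters for sulindac
#>   delta_d =  21.75  delta_p =   5.21  delta_h =   8.44  MPa^0.5
#>   delta_total = 23.91 MPa^0.5   (V = 244.2 cm^3/mol)

# Miscibility screen on the reported component deltas
miscibility_screen(23.74, 25.89)
#> Miscibility screen: |23.74 - 25.89| = 2.15 MPa^0.5 (threshold 7.0)
#>   verdict: miscible

# Phase-solubility diagram: simulate an A_N-type experiment and re-fit it
sim <- simulate_phase_solubility(K11 = 1.5, S0 = 0.04, beta = 0.2, seed = 42)
fit_K11(sim$data)
#> 1:1 complexation fit (8 points, ligand 0.04883-6.25 mM)
#>   slope = 0.0569, intercept = 0.04206 mM, R^2 = 0.9978
#>   K1:1 = 1.508 mM^-1 (S0 = 0.04 mM)  [A_N diagram]

# Apparent-solubility enhancement: hydrogel vs crystalline drug (ug/mL)
enhancement_ratio(6432.13, 11.77)
#> [1] 546.49

# Cumulative release under the 900 mL / 2 mL-aliquot paddle protocol
simd <- simulate_dissolution(seed = 42)
prof <- cumulative_release(paddle_sink_protocol(), simd$series)
round(profile_summary(prof, c(20, 120)), 2)
#>   t20  t120
#> 30.22 81.91
```

Reading the output: the sulindac fixture's total solubility parameter
(23.91 MPa^½) comes out within 1% of the published 23.74; the 2.15 MPa^½
difference between the two components is far below the 7 MPa^½ cutoff, so
the pair is predicted miscible. The simulated phase-solubility diagram is
correctly classified A_N with its linear region ending at 6.25 mM, and the
generating constant K₁:₁ = 1.5 mM⁻¹ is recovered within 1% despite 5% assay
noise. The release profile shows ~30% of the dose dissolved by 20 min and
~82% by 120 min under the simulated sink protocol.

A thin command-line wrapper over the same functions ships in
`inst/cli/gelsolv.R` (subcommands `hsp`, `phasesol`, `release`, `simulate`,
`reproduce`; exit codes 0 ok / 2 validation error / 64 usage error), and
`reproduce_report()` runs all worked-example checks in one call.

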