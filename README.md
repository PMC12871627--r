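# smfretr

An R package for single-molecule FRET (smFRET) trace analysis of
membrane-protein conformational states, built around the measurement
chain used to map Ca²⁺-depletion-driven rearrangements of the ER calcium
sensor STIM1: two-channel donor/acceptor intensity traces →
photobleaching quality control and per-molecule γ correction →
efficiency histograms → Gaussian mixture decomposition → Förster-relation
distances — plus an accessible-volume dye simulator for
structure-derived distance predictions, and quantification of TIRF
puncta time courses and crosslinking gels.

No raw trace data for this system are publicly deposited, so the
package ships a first-class synthetic trace generator with known ground
truth; every stage is validated by parameter recovery on ensembles it
generated and by independent brute-force oracles.

## The model

For each molecule, the FRET efficiency at every frame is

```
E = I_A / (I_A + γ I_D)
```

where `I_A`, `I_D` are background-subtracted acceptor and donor
intensities and γ is the per-molecule detection-correction factor
measured from the intensity jumps at acceptor photobleaching.  Molecules
are analyzable only if they show a single acceptor bleach followed by a
single donor bleach (one FRET pair, with a usable γ calibration jump).
Efficiencies from all accepted molecules are pooled in a 40-bin
histogram from −0.25 to 1.25, each molecule contributing total weight 1,
and decomposed into a sum of Gaussians whose fractional areas are the
state occupancies.  Peak efficiencies convert to inter-dye distances via
the Förster relation

```
E = 1 / (1 + (R/R0)^6),   R0 = 5.8 nm (calibrated working value)
```

Dye-accessible volumes on atomic structures are sampled by seeded
rejection sampling inside the linker sphere with a hard-clash rule,
giving mean inter-dye distances for candidate structural models.

## Worked example

Simulate a two-state ensemble (states E = 0.3 and 0.8, equal weights,
γ ~ N(1, 0.1), 5% channel noise), run the full pipeline, and read off
the recovered states and distances:

```r
library(smfretr)
cfg <- run_config(
  simulate = list(n_molecules = 300, states = list(c(0.3, 0.5), c(0.8, 0.5)),
                  gamma_mean = 1, gamma_sd = 0.1,
                  total_intensity = 500, noise_sd = 25),
  fit = list(n_components = 2), seed = 1)
report <- run_pipeline(cfg, quiet = TRUE)
report$qc_summary
#>           accepted no_acceptor_bleach    no_donor_bleach         multi_step
#>                123                 10                 91                  7
#>    order_violation          too_short      gamma_invalid
#>                 69                  0                  0
report$distances
#>   component    mean_E fractional_area distance_nm distance_nm_reported clamped
#> 1         1 0.3006893       0.4969005    6.676057                  6.7   FALSE
#> 2         2 0.8003285       0.5030995    4.601887                  4.6   FALSE
```

123 of 300 simulated molecules pass the single-acceptor-then-donor
bleach selection (the others never bleach within the 80-s record, bleach
in the wrong order, or show multiple steps).  The two fitted components
recover the generating efficiencies to three decimals and split the
occupancy evenly, as generated; at R₀ = 5.8 nm they correspond to 6.7 nm
and 4.6 nm inter-dye distances.

## Analysis workflow

The `analysis/` scripts chain the stages over synthetic data and write
plain-text tables under `results/` (each is a thin driver over package
functions and prints what it found):

```
Rscript analysis/01_simulate_traces.R    # two-state ensemble + ground truth
Rscript analysis/02_qc_select.R          # bleach QC, gamma table, recovery scores
Rscript analysis/03_fret_histogram.R     # summed trace-normalized histogram
Rscript analysis/04_mixture_fits.R       # mixture fits incl. published-legend refits
Rscript analysis/05_distances.R          # R0 calibration check + distance table
Rscript analysis/06_dye_distances.R      # accessible-volume distances vs grid oracle
Rscript analysis/07_puncta_crosslink.R   # puncta time courses, crosslink efficiency
```

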