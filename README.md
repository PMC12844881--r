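# thermofate

Analysis of cortical neuron activity across fever-range temperature
elevations, for electrophysiologists studying thermal stability of neural
circuits. When brain temperature rises from 30 °C through 36 °C into the
fever range (39 °C), spike threshold (ST) depolarises and input resistance
(R_in) falls, yet population firing can stay stable because a subset of
neurons — **STAY** cells — keep firing by scaling their synaptic
depolarization to track the rising threshold. `thermofate` implements the
full analysis chain for such experiments on three data streams:

- **Intracellular current-clamp sweeps** (30/36/39 °C): resting membrane
  potential, spike threshold by the second-derivative criterion (the V_m at
  which d²V_m/dt² exceeds mean + 5 SD of the pre-stimulus distribution),
  depolarization-to-threshold (ST − baseline), evoked PSP peak and late
  (net-inhibitory) component, input resistance (ΔV/ΔI on the step steady
  state), rheobase, F–I curves, spike height, afterhyperpolarization.
- **Thermal fates**: each cell is NEVER / STOP / STAY / START across the
  temperature series (or the pairwise 36→39 °C scheme), with exact
  two-tailed binomial tests for fate-proportion contrasts.
- **Extracellular single units**: trough-to-peak duration of the band-passed
  (300–6000 Hz) mean waveform; Hartigan's dip test of bimodality (authored
  here: taut-string geometry + bisection, uniform-null bootstrap p); exact
  1-D 2-means narrow/wide split; per-period firing rates (last 25 min of
  each 45-min baseline / fever / recovery period) normalized to baseline.
- **Body-temperature telemetry**: median and fluctuations, fever-episode
  detection (> 38 °C runs), heating rates, and latencies around loss of
  postural control (LPC) and seizure onset.

A seeded synthetic-data generator reproduces the temperature-dependent
structure of all three streams with known ground truth (including TRPV3
blocker / knockout variants: flat PSP gain, ~3 mV hyperpolarised RMP), so
every estimator is testable end to end without recorded data.

## Worked example

```r
library(thermofate)

## a mixed-fate cohort of 12 cells at 30/36/39 degrees C
cfg <- sim_config(seed = 42, n_cells = 12, condition = "none",
                  include_steps = FALSE)
pop <- simulate_cell_population(cfg)
features <- extract_features(pop)
fates <- classify_fates(features, scheme = "three_temp")
fate_proportions(fates, condition = "none")
#>   label count  percent
#> 1 NEVER     3 25.00000
#> 2  STOP     4 33.33333
#> 3  STAY     3 25.00000
#> 4 START     2 16.66667

percent_spiking_by_temperature(features)
#>   temperature  n n_spiking  percent
#> 1          30 12         7 58.33333
#> 2          36 12         3 25.00000
#> 3          39 12         5 41.66667

## is 2 STAY cells of 26 under blocker compatible with a 10/37 reference?
binomial_compare(k = 2, n = 26, p0 = 10/37)
#> [1] 0.02578941

## spike-duration bimodality and the narrow/wide split, study scale
units <- simulate_units(n_units = 633, narrow_frac = 0.22, seed = 7)
durs <- sapply(units, function(u)
  trough_to_peak_ms(bandpass_waveform(u$mean_waveform, u$waveform_fs),
                    u$waveform_fs))
dip_test(durs, n_boot = 2000, seed = 1)
#> Hartigan dip test of unimodality
#>   dip = 0.07103, n = 633
#>   bootstrap p-value = 0 (2000 uniform-null draws)

table(classify_units(units)$unit_class)
#> narrow   wide
#>    152    481
```

The fate table says 25 % of this cohort stayed active across the whole
temperature series while roughly equal fractions stopped and started — the
STAY cells carry the stability of the population output. The binomial p of
0.026 says a drop from 10/37 to 2/26 STAY cells is unlikely to be sampling
noise. The dip test rejects unimodality of the duration distribution
(p < 0.001), and the 2-means split recovers the planted ~22 % narrow-spiking
(putative interneuron) fraction with its boundary near 0.6 ms.

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` executes every
stage and writes `features.csv`, `fates.csv`, `proportions.csv`,
`units_classified.csv`, `fever_episodes.csv`, `tb_summary.csv` and a
`manifest.yaml` with the fully resolved configuration.

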