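#!/usr/bin/env Rscript
# Experiment 3: flow sweeps with onset/offset hysteresis.
#
# Simulates the full crossed design (3 larynx presets x anechoic/resonant
# x 3 sweeps x 2 repetitions; resonant tract at f_R1 = 500 Hz). Each
# sweep ramps the mean flow to 550 mL/s and back; oscillation switches on
# and off at the (noisy) per-sweep threshold pressures, with the resonant
# condition lowering offsets by the configured 0.89 factor and f_o by the
# 106/126 ratio. The detector then recovers onset/offset pressures from
# the subglottal pressure alone, and frame-wise f_o/SPL-versus-pressure
# tables are built from the first sweep of each cell.
#
# Expectations: detected onset > offset in every sweep; f_o lower and SPL
# higher in the resonant condition at matched pressures.

library(subglottalsim)

cfg <- study_defaults(seed = 1)
out <- "results/sweeps"
sw <- suppressWarnings(run_sweep_experiment(cfg, out_dir = out))

cat("Measured threshold table (first rows):\n")
print(utils::head(sw$thresholds), row.names = FALSE, digits = 4)
cat(sprintf("\nHysteresis: onset > offset in %d / %d sweeps\n",
            sum(sw$thresholds$onset_pressure >
                  sw$thresholds$offset_pressure),
            nrow(sw$thresholds)))
cat("\nPer-larynx mean radiated-SPL difference above 8 hPa",
    "(resonant - anechoic, dB):\n")
print(unlist(sw$spl_differences), digits = 2)
cat("\nThreshold table, tracks and stats written under", out, "\n")
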