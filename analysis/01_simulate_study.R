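#!/usr/bin/env Rscript

# Step 1: simulate the dose-response MEA study.
#
# Three fentanyl conditions (0, 0.01, 10 uM) x 6 wells x 7 timepoints
# (baseline, 30 min, 1 h, 24/48/72/96 h), one recording per well and
# timepoint. Untreated wells keep multiplier 1 throughout; the low dose dips
# to 0.8 in the first hour and recovers from 24 h; the high dose is held at
# 0.2 at every post-dose timepoint. Recordings are written in the CSV spike
# dialect under scratch/study_csv together with a manifest of the true
# simulation parameters (ground truth for step 2's recovery check).
#
# The recording length defaults to 600 s here to keep the driver quick; pass
# a duration in seconds as the first argument for full 1800 s sessions.

library(meanet)

args <- commandArgs(trailingOnly = TRUE)
duration <- if (length(args) >= 1) as.numeric(args[1]) else 600
seed <- if (length(args) >= 2) as.integer(args[2]) else 20260925L

model <- network_model()
study <- generate_study(model, dose_design(), n_wells_per_condition = 6,
                        duration = duration, seed = seed)

out <- file.path("scratch", "study_csv")
manifest <- write_study(study, out, format = "csv")

message(sprintf("simulated %d recordings (%g s each, %d electrodes/well)",
                length(study$recordings), duration, model$n_electrodes))
message(sprintf("expected per-electrode rate at baseline: %.2f Hz",
                expected_rate(model)))
counts <- vapply(study$recordings, function(r) sum(spike_counts(r)), numeric(1))
message(sprintf("total spikes: %.0f (per-recording median %.0f)",
                sum(counts), median(counts)))
message("wrote ", nrow(manifest), " files + manifest.json under ", out)
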