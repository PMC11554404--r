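#!/usr/bin/env Rscript
# Stage 1 — generate the working survey.
#
# Simulates a year-long, 651-site camera-trap survey from the package's
# default truth (coat-category field driven by elevation, FPAR, vegetation
# and isothermality; new-moon activity advantage for all coat types except
# orange) and writes it, with its ground truth, under results/survey/.

suppressMessages(library(feralcoats))

seed <- 20240501
sv <- simulate_survey(sim_config(), seed = seed)

cat("sites:      ", nrow(sv$sites), "\n")
cat("detections: ", nrow(sv$detections), "images\n")
cat("deployments:", nrow(sv$deployments),
    sprintf("(%d short, < 83 nights)\n",
            sum(sv$deployments$operating_days < 83)))
cat("true black individuals:", sv$truth$n_black_individuals, "\n")

write_survey(sv, "results/survey")
cat("written: results/survey/\n")
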