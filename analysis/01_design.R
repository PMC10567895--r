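#!/usr/bin/env Rscript
# Enumerate the two acquisition designs (DSLR and smartphone) and record
# their photograph counts.

suppressPackageStartupMessages(library(facefd))
dir.create("results", showWarnings = FALSE)

dslr <- dslr_study_config()
design_dslr <- study_design(dslr)
write_estimates(design_dslr, "results/design_dslr.csv", seed = dslr$seed,
                config_hash = dslr$hash)

phone <- smartphone_study_config()
design_phone <- study_design(phone)
write_estimates(design_phone, "results/design_smartphone.csv", seed = phone$seed,
                config_hash = phone$hash)

per_body <- nrow(design_dslr) / (dslr$n_participants * nrow(dslr$bodies))
message(sprintf(
  "DSLR design: %d photographs (%d participants x 3 bodies x 5 focal-length configs x 6 distances x 2 views x 2 exposures); %d per body per participant.",
  nrow(design_dslr), dslr$n_participants, per_body
))
message(sprintf(
  "Smartphone design: %d photographs (4 front cameras x 9 distances + 5 back cameras x 8 distances, 2 views x 2 exposures, minus 2 participant/camera dropouts).",
  nrow(design_phone)
))
message("Wrote results/design_dslr.csv and results/design_smartphone.csv")
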