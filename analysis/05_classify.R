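#!/usr/bin/env Rscript
# Step 5 -- dual-readout mechanism classification and report.
#
# Runs the full convergent pipeline on the reference screen: normalization,
# gating, Dunnett testing of both readouts, three-state calls with the 80/120
# cut-offs, and the mechanism decision table. Writes the report bundle.

suppressMessages(library(exomod))

wells <- read_plate_csv("results/fixture_wells.csv")
report <- run_convergent_screen(wells)
print(report)
write_screen_report(report, "results/report")
cat("report bundle -> results/report/\n")
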