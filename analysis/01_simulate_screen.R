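#!/usr/bin/env Rscript
# Step 1 -- simulate the screen inputs.
#
# Generates (a) a default synthetic 96-well plate with assay controls, used
# for Z'-factor QC, and (b) the deterministic two-context reference screen:
# 14 test compounds + 3 mechanism reference compounds, 6 wells per condition,
# dual readouts (AlphaScreen counts + LBPA granules per cell), plus the MCF7
# dose-response series.

suppressMessages(library(exomod))
dir.create("results", showWarnings = FALSE)

plate <- generate_screen_plate(screen_sim_config(seed = 1))
write_plate_csv(plate$wells, "results/plate_default.csv")
cat("default plate:", nrow(plate$wells), "wells ->",
    "results/plate_default.csv\n")

fx <- reference_screen_fixture()
write_plate_csv(fx$wells, "results/fixture_wells.csv")
write_plate_csv(fx$dose_response, "results/fixture_dose_response.csv")
utils::write.csv(fx$classes, "results/fixture_classes.csv", row.names = FALSE)
cat("reference screen:", nrow(fx$wells), "wells across",
    length(unique(fx$wells$context)), "contexts;",
    nrow(fx$dose_response), "dose-response wells\n")
cat("true effect classes (test compounds):\n")
print(table(fx$classes$context[fx$classes$role == "test"],
            fx$classes$class[fx$classes$role == "test"]))
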