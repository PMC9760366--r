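#!/usr/bin/env Rscript
# Step 2 -- normalization and assay QC.
#
# Per-nucleus normalization, percent-of-control against the vehicle wells of
# each context, Z'-factor from the assay control wells, and the viability
# (toxicity) gate.

suppressMessages(library(exomod))

wells <- read_plate_csv("results/fixture_wells.csv")

tab <- percent_of_control(wells)
tab <- viability_gate(tab, max_toxicity = 0.20)
utils::write.csv(tab, "results/screen_normalized.csv", row.names = FALSE)

qc <- plate_zprime(wells)
for (ctx in names(qc)) {
  cat(sprintf("Z' (%s): %.3f  (needs >= 0.5 for a usable assay)\n",
              ctx, qc[[ctx]]$zprime))
}
qc_tab <- do.call(rbind, lapply(names(qc), function(ctx) {
  q <- qc[[ctx]]
  data.frame(context = ctx, mu_p = q$mu_p, sigma_p = q$sigma_p,
             mu_n = q$mu_n, sigma_n = q$sigma_n, zprime = q$zprime)
}))
utils::write.csv(qc_tab, "results/qc_zprime.csv", row.names = FALSE)

cat("conditions below the 80% viability floor:",
    sum(!tab$viability_pass), "\n")
cat("vehicle anchors (must be exactly 100):",
    paste(round(tab$mean_percent[tab$condition == "vehicle"], 10),
          collapse = ", "), "\n")
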