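#!/usr/bin/env Rscript
# Step 4 -- statistics.
#
# Dunnett many-to-one comparisons of every condition against the vehicle
# wells (both readouts, per context), and the permutation trend test on the
# MCF7 dose-response ladders.

suppressMessages(library(exomod))

wells <- read_plate_csv("results/fixture_wells.csv")
dr <- read_plate_csv("results/fixture_dose_response.csv")

pw <- well_percent_signals(wells)
exo_stats <- screen_dunnett(pw)
tab <- viability_gate(percent_of_control(wells))
utils::write.csv(stats_report(tab, exo_stats),
                 "results/stats_exoscreen.csv", row.names = FALSE)
cat("ExoScreen Dunnett: ", sum(exo_stats$significant), "of",
    nrow(exo_stats), "conditions differ from control (famwise alpha 0.05)\n")

lb <- lbpa_well_percent(wells)
lb_stats <- screen_dunnett(lb)
utils::write.csv(stats_report(lbpa_percent_of_control(wells), lb_stats),
                 "results/stats_lbpa.csv", row.names = FALSE)
cat("LBPA Dunnett:      ", sum(lb_stats$significant), "of",
    nrow(lb_stats), "conditions differ from control\n")

pw_dr <- well_percent_signals(dr)
trends <- do.call(rbind, lapply(
  unique(pw_dr$compound[pw_dr$role == "test"]), function(cp) {
    w <- pw_dr[pw_dr$compound == cp, ]
    trend_test(w$dose, w$percent, n_perm = 10000, seed = 1, compound = cp)
  }
))
utils::write.csv(trends, "results/trend_tests.csv", row.names = FALSE)
cat("\ndose-dependent inhibition (decreasing trend, permutation p):\n")
print(as.data.frame(trends[, c("compound", "statistic", "p", "monotone")]))
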