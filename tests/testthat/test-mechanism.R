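test_that("readout states follow the strict cut-off rule", {
  # boundary values stay UNCHANGED; 79.99 is LOW without needing significance
  expect_equal(readout_state(c(80, 79.99, 100, 120, 120.01, 150),
                             significant = c(F, F, F, F, T, F)),
               c("UNCHANGED", "LOW", "UNCHANGED", "UNCHANGED", "HIGH",
                 "UNCHANGED"))
  # the LBPA convention requires significance in both directions
  expect_equal(readout_state(c(70, 70, 150, 150), c(TRUE, FALSE, TRUE, FALSE),
                             require_sig_low = TRUE, require_sig_high = TRUE),
               c("LOW", "UNCHANGED", "HIGH", "UNCHANGED"))
})

test_that("the decision table is total and fixes the three defined mechanisms", {
  states <- c("LOW", "UNCHANGED", "HIGH")
  grid <- expand.grid(exo = states, lbpa = states, stringsAsFactors = FALSE)
  calls <- classify_mechanism(grid$exo, grid$lbpa)
  expect_equal(length(calls), 9)
  expect_false(any(is.na(calls)))
  expect_true(all(calls %in% c("RELEASE_INHIBITOR", "BIOGENESIS_INHIBITOR",
                               "BIOGENESIS_ACTIVATOR", "INACTIVE",
                               "UNCLASSIFIED")))
  expect_equal(classify_mechanism("LOW", "HIGH"), "RELEASE_INHIBITOR")
  expect_equal(classify_mechanism("LOW", "LOW"), "BIOGENESIS_INHIBITOR")
  expect_equal(classify_mechanism("HIGH", "HIGH"), "BIOGENESIS_ACTIVATOR")
  expect_equal(classify_mechanism("UNCHANGED", "UNCHANGED"), "INACTIVE")
  # unchanged extracellular signal is inactive whatever the LBPA state
  expect_equal(classify_mechanism("UNCHANGED", c("LOW", "HIGH")),
               c("INACTIVE", "INACTIVE"))
  # discordant pairs carry no defined mechanism
  expect_equal(classify_mechanism(c("HIGH", "LOW", "HIGH"),
                                  c("LOW", "UNCHANGED", "UNCHANGED")),
               rep("UNCLASSIFIED", 3))
  expect_error(classify_mechanism("low", "HIGH"), "states")
})

test_that("the classifier is pure", {
  expect_identical(classify_mechanism("LOW", "HIGH"),
                   classify_mechanism("LOW", "HIGH"))
})

test_that("fixture hit calling recovers the printed identities per context", {
  fx <- reference_screen_fixture()
  rep <- suppressMessages(run_convergent_screen(fx$wells))
  calls <- rep$calls
  mda <- calls[calls$context == "MDA-MB-453" & calls$role == "test", ]
  mcf <- calls[calls$context == "MCF7" & calls$role == "test", ]
  expect_setequal(mda$compound[mda$exo_state == "LOW"],
                  c("docetaxel", "biscurcumin", "primaquine", "doxorubicin"))
  expect_setequal(mcf$compound[mcf$exo_state == "LOW"],
                  c("docetaxel", "biscurcumin", "primaquine", "doxorubicin",
                    "dinaciclib"))
  # the five MCF7 hits all score as release inhibitors (low outside, high
  # LBPA inside); dinaciclib does so only in MCF7
  expect_true(all(mcf$call[mcf$exo_state == "LOW"] == "RELEASE_INHIBITOR"))
  expect_equal(mda$call[mda$compound == "dinaciclib"], "UNCLASSIFIED")
})

test_that("the Go6983 reference control is labeled a release inhibitor", {
  fx <- reference_screen_fixture()
  rep <- suppressMessages(run_convergent_screen(fx$wells))
  go <- rep$calls[rep$calls$compound == "Go6983", ]
  expect_true(all(go$call == "RELEASE_INHIBITOR"))
  spiro <- rep$calls[rep$calls$compound == "spiroepoxide", ]
  expect_true(all(spiro$call == "BIOGENESIS_INHIBITOR"))
})

test_that("report counts per context match the fixture screen outcome", {
  fx <- reference_screen_fixture()
  rep <- suppressMessages(run_convergent_screen(fx$wells))
  s <- rep$summary
  expect_equal(s$n_inhibitors[s$context == "MDA-MB-453"], 4)
  expect_equal(s$n_inhibitors[s$context == "MCF7"], 5)
  expect_output(print(rep), "ExoScreen inhibitor")
})

test_that("an empty screen produces an empty report without error", {
  exo <- tibble::tibble(context = character(), condition = character(),
                        compound = character(), dose = numeric(),
                        role = character(), mean_percent = numeric(),
                        significant = logical(), exo_state = character())
  rep <- screen_report(exo)
  expect_equal(nrow(rep$calls), 0)
  expect_equal(nrow(rep$summary), 0)
})

test_that("missing stats for a called condition is an error", {
  fx <- reference_screen_fixture()
  tab <- suppressMessages(viability_gate(percent_of_control(fx$wells)))
  pw <- well_percent_signals(fx$wells)
  stats <- screen_dunnett(pw)
  stats <- stats[stats$condition != "docetaxel@1", ]
  expect_error(call_exoscreen_hits(tab, stats), "missing from stats")
})

test_that("exo state moves monotonically with the simulated effect size", {
  states <- vapply(c(0.5, 1.0, 1.6), function(m) {
    p <- tiny_plate(compounds = "x", effect_multiplier = m, noise_cv = 0,
                    seed = 1)
    w <- p$wells
    # noiseless percent; significance judged on a minimally jittered copy so
    # the Dunnett statistic is defined
    w$alpha_counts <- w$alpha_counts * (1 + 1e-6 * seq_len(nrow(w)))
    rep <- suppressMessages(run_convergent_screen(w))
    rep$calls$exo_state
  }, character(1))
  expect_equal(states, c("LOW", "UNCHANGED", "HIGH"))
})
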