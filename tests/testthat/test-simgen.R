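test_that("plate generation is deterministic under a fixed seed", {
  p1 <- tiny_plate(seed = 5)
  p2 <- tiny_plate(seed = 5)
  expect_identical(p1$wells, p2$wells)
  p3 <- tiny_plate(seed = 6)
  expect_false(identical(p1$wells$alpha_counts, p3$wells$alpha_counts))
})

test_that("noiseless plates reproduce effect multipliers exactly", {
  p <- tiny_plate(effect_multiplier = c(0.5, 1.5), noise_cv = 0)
  pw <- well_percent_signals(p$wells)
  expect_equal(unique(pw$percent[pw$compound == "drugA"]), 50)
  expect_equal(unique(pw$percent[pw$compound == "drugB"]), 150)
  expect_equal(mean(pw$percent[pw$condition == "vehicle"]), 100)
})

test_that("noisy treated wells land within 3 SEM of the true percent", {
  p <- tiny_plate(compounds = "half", effect_multiplier = 0.5,
                  noise_cv = 0.05, seed = 3)
  tab <- percent_of_control(p$wells)
  half <- tab[tab$compound == "half", ]
  # percent-of-control adds control-mean noise on top of the well SEM; 3x the
  # group SEM is the agreed recovery band for the 6-well design
  expect_lt(abs(half$mean_percent - 50), 3 * half$sem_percent + 3)
})

test_that("viability factor scales nuclei and alpha counts jointly", {
  p <- tiny_plate(compounds = "tox", effect_multiplier = 1,
                  viability_factor = 0.7, noise_cv = 0)
  w <- p$wells
  expect_equal(unique(w$nuclei[w$compound == "tox"]),
               round(0.7 * unique(w$nuclei[w$condition == "vehicle"])))
  # per-nucleus signal is viability-invariant when the effect is inert
  pw <- well_percent_signals(w)
  expect_equal(unique(round(pw$percent[pw$compound == "tox"], 6)), 100)
})

test_that("control-well noise CV matches the configured noise_cv", {
  cvs <- vapply(1:200, function(s) {
    p <- generate_screen_plate(screen_sim_config(
      compounds = character(0), noise_cv = 0.1, seed = s,
      wells_per_condition = 6
    ))
    ctrl <- p$wells$alpha_counts[p$wells$condition == "vehicle"]
    sd(ctrl) / mean(ctrl)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.1) / 0.1, 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(screen_sim_config(noise_cv = -1), "noise_cv")
  expect_error(screen_sim_config(wells_per_condition = 1), "wells_per_condition")
  expect_error(screen_sim_config(viability_factor = 0), "viability_factor")
  expect_error(screen_sim_config(baseline_alpha = NaN), "finite")
})

test_that("field generation bookkeeping is self-consistent", {
  out <- generate_field_image(small_field_config(seed = 2, n_artifact_spots = 3))
  tr <- out$truth
  expect_equal(sum(tr$cells$n_granules), sum(tr$granules$cell > 0))
  expect_equal(sum(tr$granules$cell == 0), 3)
  # every in-cell granule lies within its cell's disk
  g <- tr$granules[tr$granules$cell > 0, ]
  cc <- tr$cells[match(g$cell, tr$cells$cell), ]
  expect_true(all(sqrt((g$row - cc$row)^2 + (g$col - cc$col)^2) <= cc$radius))
  # artifacts lie outside every cell disk
  a <- tr$granules[tr$granules$cell == 0, ]
  for (i in seq_len(nrow(a))) {
    d <- sqrt((tr$cells$row - a$row[i])^2 + (tr$cells$col - a$col[i])^2)
    expect_true(all(d > tr$cells$radius))
  }
})

test_that("empty and granule-free fields are handled", {
  out0 <- generate_field_image(small_field_config(n_cells = 0, seed = 1,
                                                  n_artifact_spots = 0))
  expect_equal(nrow(out0$truth$cells), 0)
  expect_lt(max(out0$field$cyto), 400 + 6 * 40)  # background + noise only
  out5 <- generate_field_image(small_field_config(granules_per_cell = 0,
                                                  n_artifact_spots = 5, seed = 1))
  expect_equal(sum(out5$truth$cells$n_granules), 0)
  expect_equal(sum(out5$truth$granules$cell == 0), 5)
})

test_that("fields are reproducible and impossible packings error", {
  a <- generate_field_image(small_field_config(seed = 9))
  b <- generate_field_image(small_field_config(seed = 9))
  expect_identical(a$field$granule, b$field$granule)
  expect_error(
    generate_field_image(image_sim_config(field_shape = c(200, 200),
                                          n_cells = 50, cell_radius_px = 45)),
    "non-overlapping"
  )
})

test_that("the reference fixture is deterministic and complete", {
  f1 <- reference_screen_fixture()
  f2 <- reference_screen_fixture()
  expect_identical(f1, f2)
  for (ctx in c("MDA-MB-453", "MCF7")) {
    w <- f1$wells[f1$wells$context == ctx, ]
    expect_equal(length(unique(w$compound[w$role == "test"])), 14)
    expect_setequal(unique(w$condition[w$role %in%
                                         c("vehicle", "pos_ctrl", "neg_ctrl")]),
                    c("vehicle", "pos_ctrl", "neg_ctrl"))
  }
  # docetaxel signal sits below the 80% cut-off in both contexts
  pw <- well_percent_signals(f1$wells)
  doc <- tapply(pw$percent[pw$compound == "docetaxel"],
                pw$context[pw$compound == "docetaxel"], mean)
  expect_true(all(doc < 80))
})

test_that("fixture dose-response series cover the MCF7 hits", {
  dr <- reference_screen_fixture()$dose_response
  expect_setequal(unique(dr$compound[dr$role == "test"]),
                  c("biscurcumin", "doxorubicin", "dinaciclib",
                    "docetaxel", "primaquine"))
  expect_equal(length(unique(dr$dose[dr$role == "test"])), 4)
})
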