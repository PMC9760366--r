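test_that("blank fields give empty masks and empty granule lists", {
  blank <- matrix(round(400 + pmax(rnorm(300 * 300, 0, 30), -400)), 300, 300)
  expect_equal(max(segment_nuclei(blank)), 0)
  expect_equal(nrow(detect_granules(blank)), 0)
  # uniform nonzero background: the top-hat removes it entirely
  flat <- matrix(1234, 200, 200)
  expect_equal(nrow(detect_granules(flat)), 0)
  # no seeds -> empty cell mask
  expect_equal(max(segment_cells(blank, matrix(0L, 300, 300))), 0)
})

test_that("nucleus segmentation recovers disjoint nuclei and splits a touching pair", {
  out <- generate_field_image(small_field_config(seed = 3))
  nuc <- segment_nuclei(out$field$nuclei)
  expect_equal(max(nuc), nrow(out$truth$cells))
  # two overlapping disks with distinct centres: watershed yields 2 labels
  img <- matrix(0, 200, 200)
  img <- exomod:::paint_disk(img, 100, 90, 14, 12000)
  img <- exomod:::paint_disk(img, 100, 112, 14, 12000)
  img <- exomod:::clip16(img + 400 + rnorm(200 * 200, 0, 30))
  expect_equal(max(segment_nuclei(img)), 2)
})

test_that("cell segmentation labels match their seed nuclei", {
  out <- generate_field_image(small_field_config(seed = 5))
  nuc <- segment_nuclei(out$field$nuclei)
  cells <- segment_cells(out$field$cyto, nuc)
  expect_setequal(unique(cells[cells > 0]), unique(nuc[nuc > 0]))
  # each nucleus is contained in its own cell
  inside <- nuc > 0
  expect_true(all(cells[inside] == nuc[inside]))
  # cells tile disjointly by construction of a label mask; every truth centre
  # falls in the cell carrying granules assigned to it
  expect_equal(max(cells), nrow(out$truth$cells))
})

test_that("granule detection at default SNR has high recall and precision", {
  out <- generate_field_image(image_sim_config(seed = 13, n_cells = 6,
                                               granules_per_cell = 5))
  det <- detect_granules(out$field$granule)
  tr <- out$truth$granules
  d2 <- outer(tr$row, det$row, "-")^2 + outer(tr$col, det$col, "-")^2
  recall <- mean(apply(d2, 1, min) <= 3^2)
  precision <- mean(apply(d2, 2, min) <= 3^2)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("granule detection is invariant to doubling all intensities", {
  out <- generate_field_image(small_field_config(seed = 17))
  d1 <- detect_granules(out$field$granule)
  d2 <- detect_granules(exomod:::clip16(out$field$granule * 2))
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$row, d2$row, tolerance = 0.1)
})

test_that("saturated fields warn and are flagged low confidence", {
  sat <- matrix(65535, 128, 128)
  sat[1:20, 1:20] <- 400
  expect_warning(res <- detect_granules(sat), "low confidence")
  expect_true(attr(res, "low_confidence"))
})

test_that("granules are assigned by centroid and artifacts never count", {
  out <- generate_field_image(small_field_config(seed = 23,
                                                 n_artifact_spots = 5))
  res <- analyze_field(out$field)
  expect_equal(res$n_extracellular, 5)
  # in-cell + extracellular covers every detected granule exactly once
  expect_equal(sum(res$profiles$n_granules) + res$n_extracellular,
               nrow(res$granules))
  # painting extra artifact spots outside every cell onto the same field
  # leaves all per-cell metrics untouched
  f2 <- out$field
  tr <- out$truth$cells
  spots <- list(c(10, 10), c(10, 290), c(290, 10))
  for (s in spots) {
    d <- sqrt((tr$row - s[1])^2 + (tr$col - s[2])^2)
    expect_true(all(d > tr$radius + 10))
    f2$granule <- exomod:::clip16(
      exomod:::paint_spot(f2$granule, s[1], s[2], 1.5, 8000))
  }
  res2 <- analyze_field(f2)
  expect_equal(res2$profiles, res$profiles)
  expect_equal(res2$n_extracellular, res$n_extracellular + 3)
})

test_that("per-cell counts recover the generator truth", {
  errs <- c(); truths <- c()
  for (s in c(29, 31)) {
    out <- generate_field_image(image_sim_config(seed = s))
    res <- analyze_field(out$field)
    # match each true cell to the segmented label under its centre pixel
    tc <- out$truth$cells
    lab <- res$cell_mask[cbind(round(tc$row), round(tc$col))]
    expect_true(all(lab > 0))
    est <- res$profiles$n_granules[match(lab, res$profiles$cell)]
    errs <- c(errs, abs(est - tc$n_granules))
    truths <- c(truths, tc$n_granules)
  }
  expect_lte(mean(errs), 0.1 * mean(truths))
})

test_that("well quantification pools fields as a ratio of totals", {
  # synthetic profiles: 1 field, 10 cells, 40 in-cell granules -> 4.0
  f <- generate_field_image(image_sim_config(seed = 41, n_cells = 10))$field
  res <- analyze_field(f)
  q <- quantify_well(list(f), well = "W1")
  expect_equal(q$granules_per_cell, sum(res$profiles$n_granules) / res$n_nuclei)
  expect_equal(q$n_fields, 1)
  # a well whose fields contain no cells is invalid
  blankcfg <- small_field_config(n_cells = 0, n_artifact_spots = 0, seed = 2)
  blank <- generate_field_image(blankcfg)$field
  expect_error(quantify_well(list(blank)), "invalid well")
})

test_that("segmentation is deterministic on identical input", {
  f <- generate_field_image(small_field_config(seed = 37))$field
  expect_identical(analyze_field(f)$cell_mask, analyze_field(f)$cell_mask)
})

test_that("LBPA percent-of-control anchors control at 100 and scales linearly", {
  wells <- tibble::tibble(
    well = paste0("W", 1:6),
    condition = rep(c("vehicle", "treated@1"), each = 3),
    granules_per_cell = c(4, 4, 4, 6, 6, 6)
  )
  tab <- lbpa_percent_of_control(wells)
  expect_equal(tab$mean_percent[tab$condition == "vehicle"], 100.0)
  expect_equal(tab$mean_percent[tab$condition == "treated@1"], 150.0)
  expect_error(
    lbpa_percent_of_control(tibble::tibble(well = "w", condition = "vehicle",
                                           granules_per_cell = 0)),
    "zero"
  )
})

test_that("estimated dose ladder of granule levels preserves truth ordering", {
  gpc <- vapply(c(2, 4, 8), function(lam) {
    wf <- generate_well_fields(image_sim_config(granules_per_cell = lam,
                                                seed = 100 + lam),
                               n_fields = 2)
    quantify_well(wf$fields, well = "W")$granules_per_cell
  }, numeric(1))
  expect_true(all(diff(gpc) > 0))
})
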