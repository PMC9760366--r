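#' Segmentation and granule-detection parameters
#'
#' Tunable parameters of the per-cell LBPA quantification pipeline. All image
#' operators (smoothing, Otsu thresholding, top-hat filtering, watershed) run
#' on these settings; defaults are matched to the synthetic field generator's
#' scale and are documented per argument.
#'
#' @param nucleus_smooth_sigma Gaussian sigma (px) applied to the nuclei
#'   channel before thresholding.
#' @param min_nucleus_area smallest retained nucleus object (px).
#' @param nucleus_watershed_tolerance,nucleus_watershed_ext distance-map
#'   watershed parameters used to split touching nuclei.
#' @param cyto_smooth_sigma Gaussian sigma (px) for the cytoplasm channel.
#' @param min_contrast minimum normalized channel range (on the 0..1 scale)
#'   required before Otsu thresholding; a flatter channel is treated as blank.
#' @param tophat_radius radius (px) of the disc structuring element of the
#'   white top-hat granule background suppression; should exceed the granule
#'   radius.
#' @param mad_k threshold the top-hat image at `median + mad_k * MAD`
#'   (default 5).
#' @param min_granule_area,max_granule_area granule component size bounds (px).
#' @param split_tolerance intensity-watershed tolerance (grey levels) used to
#'   split merged granule spots; larger values split less.
#' @return list of class `granule_params`.
#' @export
granule_params <- function(nucleus_smooth_sigma = 2,
                           min_nucleus_area = 100,
                           nucleus_watershed_tolerance = 2,
                           nucleus_watershed_ext = 1,
                           cyto_smooth_sigma = 2,
                           min_contrast = 0.02,
                           tophat_radius = 7,
                           mad_k = 5,
                           min_granule_area = 4,
                           max_granule_area = 400,
                           split_tolerance = 500) {
  p <- as.list(environment())
  class(p) <- "granule_params"
  p
}

# EBImage operators may return Image objects; work with plain matrices.
as_mat <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

as_intensity <- function(channel) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (any(channel < 0 | channel > 65535)) {
    stop("channel values must lie in the 16-bit range 0..65535")
  }
  channel / 65535
}

label_matrix <- function(x) {
  m <- as_mat(x)
  storage.mode(m) <- "integer"
  m
}

#' Segment nuclei from the Hoechst channel
#'
#' Gaussian smoothing, global Otsu threshold, removal of objects below
#' `min_nucleus_area`, then a distance-transform watershed to split touching
#' nuclei. A blank (low-contrast) field yields an empty mask, not an error.
#'
#' @param nuclei_channel 2-D 16-bit matrix.
#' @param params a [granule_params()].
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclei_channel, params = granule_params()) {
  x <- as_intensity(nuclei_channel)
  xs <- as_mat(EBImage::gblur(x, sigma = params$nucleus_smooth_sigma))
  if (diff(range(xs)) < params$min_contrast) {
    return(matrix(0L, nrow(x), ncol(x)))
  }
  mask <- xs > EBImage::otsu(xs, range = range(xs))
  lab <- as_mat(EBImage::bwlabel(mask))
  areas <- tabulate(as.integer(lab))
  keep <- which(areas >= params$min_nucleus_area)
  mask2 <- matrix(as.integer(lab %in% keep), nrow(x), ncol(x))
  if (!any(mask2 > 0)) return(matrix(0L, nrow(x), ncol(x)))
  ws <- EBImage::watershed(as_mat(EBImage::distmap(mask2)),
                           tolerance = params$nucleus_watershed_tolerance,
                           ext = params$nucleus_watershed_ext)
  label_matrix(ws)
}

#' Segment cells from the phalloidin channel, seeded by nuclei
#'
#' Foreground is the smoothed cytoplasm channel above its Otsu threshold,
#' united with the nucleus pixels; cells are grown from the nucleus seeds by
#' seeded propagation over the cytoplasm intensity (the seeded-watershed
#' operator of this stack), so each cell label equals its seed nucleus label
#' and adjacent cells are separated along the propagation boundary. A nucleus
#' falling outside the cytoplasm foreground keeps a cell consisting of the
#' nucleus region only.
#'
#' @param cyto_channel 2-D 16-bit matrix (same field as the nucleus mask).
#' @param nucleus_mask integer label matrix from [segment_nuclei()].
#' @param params a [granule_params()].
#' @return integer cell label matrix; labels match nucleus labels.
#' @export
segment_cells <- function(cyto_channel, nucleus_mask, params = granule_params()) {
  x <- as_intensity(cyto_channel)
  stopifnot(all(dim(x) == dim(nucleus_mask)))
  if (max(nucleus_mask) == 0L) {
    return(matrix(0L, nrow(x), ncol(x)))
  }
  xs <- as_mat(EBImage::gblur(x, sigma = params$cyto_smooth_sigma))
  fg <- if (diff(range(xs)) < params$min_contrast) {
    matrix(FALSE, nrow(x), ncol(x))
  } else {
    xs > EBImage::otsu(xs, range = range(xs))
  }
  fg <- (fg | nucleus_mask > 0L) * 1
  cells <- EBImage::propagate(xs, seeds = nucleus_mask, mask = fg)
  label_matrix(cells)
}

#' Detect granule spots in the FITC channel
#'
#' White top-hat filtering at the granule scale suppresses background, the
#' result is thresholded at `median + mad_k * MAD` (a data-adaptive, scale
#' invariant cut), merged spots are split by an intensity watershed, and
#' components are filtered to `[min_granule_area, max_granule_area]`.
#'
#' @param granule_channel 2-D 16-bit matrix.
#' @param params a [granule_params()].
#' @return tibble with one row per granule: `granule, row, col` (intensity
#'   weighted sub-pixel centroid), `area` (px), `mean_intensity` (raw grey
#'   levels), `cell` (`NA` until assigned). If more than half the pixels are
#'   saturated a warning is raised and the attribute `low_confidence` is set.
#' @export
detect_granules <- function(granule_channel, params = granule_params()) {
  stopifnot(is.matrix(granule_channel))
  saturated <- mean(granule_channel >= 65535) > 0.5
  if (saturated) {
    warning("more than 50% of pixels saturated; granule results are low confidence")
  }
  x <- granule_channel * 1.0
  brush <- EBImage::makeBrush(2L * ceiling(params$tophat_radius) + 1L, "disc")
  th <- as_mat(EBImage::whiteTopHat(x, brush))
  cut <- stats::median(th) + params$mad_k * stats::mad(th)
  mask <- th > cut
  empty <- tibble::tibble(granule = integer(), row = numeric(), col = numeric(),
                          area = numeric(), mean_intensity = numeric(),
                          cell = integer())
  if (!any(mask)) {
    attr(empty, "low_confidence") <- saturated
    return(empty)
  }
  # intensity watershed declumps touching spots; background stays 0
  ws <- EBImage::watershed(ifelse(mask, th, 0),
                           tolerance = params$split_tolerance, ext = 1)
  lab <- as.integer(as_mat(ws))
  keep_px <- lab > 0L
  if (!any(keep_px)) {
    attr(empty, "low_confidence") <- saturated
    return(empty)
  }
  idx <- which(keep_px)
  rows <- (idx - 1L) %% nrow(x) + 1L
  cols <- (idx - 1L) %/% nrow(x) + 1L
  lb <- lab[idx]
  wts <- th[idx]
  area <- tapply(wts, lb, length)
  swt <- tapply(wts, lb, sum)
  crow <- tapply(wts * rows, lb, sum) / swt
  ccol <- tapply(wts * cols, lb, sum) / swt
  mint <- tapply(x[idx], lb, mean)
  out <- tibble::tibble(
    granule = as.integer(names(area)),
    row = as.numeric(crow), col = as.numeric(ccol),
    area = as.numeric(area), mean_intensity = as.numeric(mint),
    cell = NA_integer_
  )
  out <- out[out$area >= params$min_granule_area &
               out$area <= params$max_granule_area, , drop = FALSE]
  out$granule <- seq_len(nrow(out))
  attr(out, "low_confidence") <- saturated
  out
}

#' Link granules to cells and build per-cell profiles
#'
#' Each granule is assigned to the cell label under its centroid pixel;
#' granules over background (label 0) are extracellular artifacts, counted
#' separately and excluded from every per-cell metric.
#'
#' @param granules tibble from [detect_granules()].
#' @param cell_mask integer label matrix from [segment_cells()].
#' @return list with `profiles` (tibble: `cell, n_granules, total_area,
#'   mean_intensity`, one row per segmented cell, zeros when a cell has no
#'   granule), `granules` (input with `cell` filled in) and
#'   `n_extracellular`.
#' @export
assign_granules_to_cells <- function(granules, cell_mask) {
  stopifnot(is.matrix(cell_mask))
  n_cells <- max(cell_mask)
  labels <- if (n_cells > 0) sort(unique(cell_mask[cell_mask > 0L])) else integer()
  if (nrow(granules)) {
    ri <- pmin(pmax(round(granules$row), 1L), nrow(cell_mask))
    ci <- pmin(pmax(round(granules$col), 1L), ncol(cell_mask))
    granules$cell <- cell_mask[cbind(ri, ci)]
  }
  inc <- granules[granules$cell %in% labels & !is.na(granules$cell), , drop = FALSE]
  profiles <- tibble::tibble(
    cell = labels,
    n_granules = vapply(labels, function(l) sum(inc$cell == l), integer(1)),
    total_area = vapply(labels, function(l) sum(inc$area[inc$cell == l]), numeric(1)),
    mean_intensity = vapply(labels, function(l) {
      v <- inc$mean_intensity[inc$cell == l]
      if (length(v)) mean(v) else 0
    }, numeric(1))
  )
  list(profiles = profiles, granules = granules,
       n_extracellular = sum(granules$cell == 0L, na.rm = TRUE))
}

# Full single-field pipeline: segment, detect, link.
analyze_field <- function(field, params = granule_params()) {
  stopifnot(inherits(field, "field_image"))
  nuc <- segment_nuclei(field$nuclei, params)
  cells <- segment_cells(field$cyto, nuc, params)
  gr <- detect_granules(field$granule, params)
  res <- assign_granules_to_cells(gr, cells)
  res$n_nuclei <- max(nuc)
  res$nucleus_mask <- nuc
  res$cell_mask <- cells
  res
}

#' Well-level LBPA metrics from a set of fields
#'
#' Runs the segmentation/detection pipeline on every field of a well and
#' pools totals across fields before dividing (a ratio of totals, robust to
#' sparse fields): granules per cell = total in-cell granules / total nuclei,
#' plus the fraction of cells with at least one granule and mean granule
#' area/intensity.
#'
#' @param fields list of `field_image` objects (one well; the acquisition
#'   default is 20 fields per well).
#' @param params a [granule_params()].
#' @param well well id for the output row (defaults to the first field's id).
#' @return one-row tibble: `well, n_fields, n_cells, n_granules,
#'   granules_per_cell, frac_cells_with_granule, mean_granule_area,
#'   mean_granule_intensity, n_extracellular`.
#' @export
quantify_well <- function(fields, params = granule_params(), well = NULL) {
  stopifnot(is.list(fields), length(fields) >= 1)
  res <- lapply(fields, analyze_field, params = params)
  n_cells <- sum(vapply(res, function(r) nrow(r$profiles), integer(1)))
  n_nuclei <- sum(vapply(res, function(r) r$n_nuclei, integer(1)))
  if (n_nuclei == 0) {
    stop("invalid well: no nuclei detected in any field")
  }
  prof <- dplyr::bind_rows(lapply(res, function(r) r$profiles))
  n_gran <- sum(prof$n_granules)
  tibble::tibble(
    well = well %||% fields[[1]]$well,
    n_fields = length(fields),
    n_cells = n_cells,
    n_granules = n_gran,
    granules_per_cell = n_gran / n_nuclei,
    frac_cells_with_granule = mean(prof$n_granules >= 1),
    mean_granule_area = if (n_gran > 0)
      sum(prof$total_area) / n_gran else 0,
    mean_granule_intensity = if (n_gran > 0)
      sum(prof$mean_intensity[prof$n_granules > 0] *
            prof$n_granules[prof$n_granules > 0]) / n_gran else 0,
    n_extracellular = sum(vapply(res, function(r) r$n_extracellular, integer(1)))
  )
}

#' Percent-of-control LBPA signal
#'
#' Normalizes well-level granules-per-cell to the vehicle-control mean of the
#' same context: control wells average exactly 100%.
#'
#' @param wells tibble with columns `condition`, `granules_per_cell` and
#'   optionally `context`, `compound`, `dose`, `role` (e.g. rows from
#'   [quantify_well()] joined to plate metadata, or the fixture's LBPA
#'   columns).
#' @param control_label vehicle condition label.
#' @return tibble per (context, condition): `n, mean_percent, sem_percent`.
#' @export
lbpa_percent_of_control <- function(wells, control_label = "vehicle") {
  stopifnot(is.data.frame(wells), "granules_per_cell" %in% names(wells))
  wells <- wells[!is.na(wells$granules_per_cell), , drop = FALSE]
  if (!"context" %in% names(wells)) wells$context <- "all"
  if (!"compound" %in% names(wells)) wells$compound <- wells$condition
  if (!"dose" %in% names(wells)) wells$dose <- NA_real_
  if (!"role" %in% names(wells)) wells$role <- NA_character_
  out <- lapply(split(wells, wells$context), function(w) {
    ctrl <- w$granules_per_cell[w$condition == control_label]
    if (!length(ctrl)) {
      stop("context '", w$context[1], "': no '", control_label,
           "' control wells with LBPA data")
    }
    if (mean(ctrl) == 0) {
      stop("context '", w$context[1], "': control granules-per-cell mean is zero")
    }
    w$percent <- w$granules_per_cell / mean(ctrl) * 100
    w
  })
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$context, .data$condition, .data$compound,
                    .data$dose, .data$role) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent = mean(.data$percent),
      sem_percent = stats::sd(.data$percent) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Per-well percent LBPA signals (unaggregated)
#'
#' Same normalization as [lbpa_percent_of_control()] but returning one row
#' per well, as needed by the per-condition statistical comparisons.
#'
#' @inheritParams lbpa_percent_of_control
#' @return input wells with a `percent` column added.
#' @export
lbpa_well_percent <- function(wells, control_label = "vehicle") {
  stopifnot(is.data.frame(wells), "granules_per_cell" %in% names(wells))
  wells <- wells[!is.na(wells$granules_per_cell), , drop = FALSE]
  if (!"context" %in% names(wells)) wells$context <- "all"
  out <- lapply(split(wells, wells$context), function(w) {
    ctrl <- w$granules_per_cell[w$condition == control_label]
    if (!length(ctrl) || mean(ctrl) == 0) {
      stop("context '", w$context[1], "': missing or degenerate '",
           control_label, "' LBPA control")
    }
    w$percent <- w$granules_per_cell / mean(ctrl) * 100
    w
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}
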