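#' Configuration for a synthetic three-channel imaging field
#'
#' Describes one simulated epifluorescence field as acquired for the
#' intracellular LBPA readout: a Hoechst nuclei channel, a FITC granule
#' channel and a TRITC phalloidin cytoplasm channel, 16-bit. Cells are
#' non-overlapping disks (slightly jittered radius) each containing one
#' nucleus disk; LBPA granules are Gaussian spots placed inside the
#' cytoplasm; `n_artifact_spots` identical spots are placed outside every
#' cell to emulate extracellular staining artifacts. Gaussian read noise is
#' added to all channels.
#'
#' @param field_shape image size in pixels, `c(rows, cols)`.
#' @param n_cells number of cells to place.
#' @param granules_per_cell expected granule count per cell (Poisson mean).
#' @param granule_radius_px nominal granule radius; the Gaussian spot sigma is
#'   `granule_radius_px / 2`.
#' @param granule_intensity spot peak amplitude in grey levels above
#'   background.
#' @param nucleus_radius_px,cell_radius_px nucleus / cell disk radii
#'   (`nucleus_radius_px < cell_radius_px`).
#' @param nucleus_intensity,cyto_intensity foreground grey levels of the
#'   nucleus and cytoplasm channels.
#' @param background_level additive background grey level, all channels.
#' @param background_noise_sd Gaussian read-noise SD in grey levels.
#' @param n_artifact_spots granule-like spots placed outside all cells.
#' @param seed integer RNG seed.
#' @return object of class `image_sim_config`.
#' @export
image_sim_config <- function(field_shape = c(500, 500),
                             n_cells = 10,
                             granules_per_cell = 5,
                             granule_radius_px = 3,
                             granule_intensity = 8000,
                             nucleus_radius_px = 12,
                             cell_radius_px = 45,
                             nucleus_intensity = 12000,
                             cyto_intensity = 3000,
                             background_level = 400,
                             background_noise_sd = 40,
                             n_artifact_spots = 2,
                             seed = 1) {
  for (nm in c("granules_per_cell", "granule_radius_px", "granule_intensity",
               "nucleus_radius_px", "cell_radius_px", "background_level",
               "background_noise_sd")) {
    check_finite(get(nm), nm)
  }
  stopifnot(length(field_shape) == 2, all(field_shape >= 64))
  if (nucleus_radius_px >= cell_radius_px) {
    stop("nucleus_radius_px must be smaller than cell_radius_px")
  }
  if (min(granule_radius_px, nucleus_radius_px, cell_radius_px) <= 0) {
    stop("all radii must be > 0")
  }
  if (background_level + granule_intensity > 65535 ||
      background_level + max(nucleus_intensity, cyto_intensity) > 65535) {
    stop("intensities must fit the 16-bit range")
  }
  cfg <- list(field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
              granules_per_cell = granules_per_cell,
              granule_radius_px = granule_radius_px,
              granule_intensity = granule_intensity,
              nucleus_radius_px = nucleus_radius_px,
              cell_radius_px = cell_radius_px,
              nucleus_intensity = nucleus_intensity,
              cyto_intensity = cyto_intensity,
              background_level = background_level,
              background_noise_sd = background_noise_sd,
              n_artifact_spots = as.integer(n_artifact_spots),
              seed = as.integer(seed))
  class(cfg) <- "image_sim_config"
  cfg
}

# Paint a filled disk into matrix `img` (value `val`), returning the matrix.
paint_disk <- function(img, row, col, radius, val) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(img), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(img), ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sub <- img[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- val
  img[rr, cc] <- sub
  img
}

# Add a Gaussian spot of amplitude `amp` and stated sigma at (row, col).
paint_spot <- function(img, row, col, sigma, amp) {
  ext <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - ext)); r1 <- min(nrow(img), ceiling(row + ext))
  c0 <- max(1L, floor(col - ext)); c1 <- min(ncol(img), ceiling(col + ext))
  rr <- r0:r1; cc <- c0:c1
  g <- amp * exp(-outer((rr - row)^2, (cc - col)^2, "+") / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + g
  img
}

clip16 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

#' Generate one synthetic three-channel field with ground truth
#'
#' Places `n_cells` non-overlapping cell disks (bounded random retries; an
#' error reports the achieved count if placement fails), draws a Poisson
#' number of granules inside each cell's cytoplasm, adds extracellular
#' artifact spots, and composes the three 16-bit channels with Gaussian read
#' noise.
#'
#' @param config an [image_sim_config()].
#' @return list with `field` (class `field_image`: list of matrices `nuclei`,
#'   `granule`, `cyto` plus metadata) and `truth` (list with `cells` and
#'   `granules` tibbles; artifact spots have `cell = 0`).
#' @export
generate_field_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  with_local_seed(config$seed, {
    R <- config$cell_radius_px
    margin <- R + 2
    centers <- matrix(numeric(0), ncol = 3)  # row, col, radius
    tries <- 0L; max_tries <- 500L * max(1L, config$n_cells)
    while (nrow(centers) < config$n_cells && tries < max_tries) {
      tries <- tries + 1L
      rad <- R * runif(1, 0.9, 1.05)
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin), rad)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
              centers[, 3] + rad + 4)) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < config$n_cells) {
      stop("could only place ", nrow(centers), " of ", config$n_cells,
           " non-overlapping cells; reduce n_cells or cell_radius_px")
    }

    nuclei_ch <- matrix(0, nr, nc)
    cyto_ch <- matrix(0, nr, nc)
    gran_ch <- matrix(0, nr, nc)
    sigma <- config$granule_radius_px / 2
    gr_margin <- 4 * sigma + 2

    cells <- list(); grans <- list()
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; rad <- centers[i, 3]
      cyto_ch <- paint_disk(cyto_ch, cy, cx, rad, config$cyto_intensity)
      nuclei_ch <- paint_disk(nuclei_ch, cy, cx, config$nucleus_radius_px,
                              config$nucleus_intensity)
      k <- rpois(1, config$granules_per_cell)
      placed <- 0L
      gpos <- matrix(numeric(0), ncol = 2)
      while (placed < k) {
        # uniform in the disk, kept clear of the cell boundary
        a <- runif(1, 0, 2 * pi)
        d <- sqrt(runif(1)) * (rad - gr_margin)
        gy <- cy + d * sin(a); gx <- cx + d * cos(a)
        gran_ch <- paint_spot(gran_ch, gy, gx, sigma, config$granule_intensity)
        gpos <- rbind(gpos, c(gy, gx))
        placed <- placed + 1L
      }
      cells[[i]] <- tibble::tibble(cell = i, row = cy, col = cx, radius = rad,
                                   n_granules = k)
      if (k > 0) {
        grans[[i]] <- tibble::tibble(cell = i, row = gpos[, 1], col = gpos[, 2])
      }
    }

    # artifact spots: granule-like, strictly outside every cell disk
    art <- matrix(numeric(0), ncol = 2)
    atries <- 0L
    while (nrow(art) < config$n_artifact_spots && atries < 10000L) {
      atries <- atries + 1L
      cand <- c(runif(1, gr_margin, nr - gr_margin),
                runif(1, gr_margin, nc - gr_margin))
      dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (length(dd) == 0 || all(dd > centers[, 3] + gr_margin + 2)) {
        gran_ch <- paint_spot(gran_ch, cand[1], cand[2], sigma,
                              config$granule_intensity)
        art <- rbind(art, cand)
      }
    }
    if (nrow(art) < config$n_artifact_spots) {
      stop("could not place all artifact spots outside cells")
    }
    if (nrow(art) > 0) {
      grans[[length(grans) + 1L]] <-
        tibble::tibble(cell = 0L, row = art[, 1], col = art[, 2])
    }

    noise <- function(ch) {
      clip16(ch + config$background_level +
               rnorm(nr * nc, 0, config$background_noise_sd))
    }
    field <- structure(
      list(nuclei = noise(nuclei_ch), granule = noise(gran_ch),
           cyto = noise(cyto_ch), well = NA_character_, field = NA_integer_),
      class = "field_image"
    )
    truth <- list(
      cells = if (length(cells)) dplyr::bind_rows(cells) else
        tibble::tibble(cell = integer(), row = numeric(), col = numeric(),
                       radius = numeric(), n_granules = integer()),
      granules = if (length(grans)) dplyr::bind_rows(grans) else
        tibble::tibble(cell = integer(), row = numeric(), col = numeric())
    )
    list(field = field, truth = truth)
  })
}

#' Generate all fields of one imaged well
#'
#' Draws `n_fields` independent fields (the acquisition default is twenty
#' fields per well) from one [image_sim_config()], advancing the field seed
#' deterministically from the config seed.
#'
#' @param config an [image_sim_config()].
#' @param n_fields number of fields to image (default 20).
#' @param well well id stamped on each field.
#' @return list with `fields` (list of `field_image`) and `truth` (list of
#'   per-field truth objects).
#' @export
generate_well_fields <- function(config, n_fields = 20, well = "W1") {
  stopifnot(n_fields >= 1)
  fields <- vector("list", n_fields)
  truths <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + (i - 1L) * 1009L
    out <- generate_field_image(cfg_i)
    out$field$well <- well
    out$field$field <- i
    fields[[i]] <- out$field
    truths[[i]] <- out$truth
  }
  list(fields = fields, truth = truths)
}
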