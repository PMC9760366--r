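#' Write / read a three-channel field as multi-page TIFF
#'
#' Fields are stored as 16-bit unsigned multi-page TIFFs with page order
#' (nuclei/Hoechst, granule/FITC, cytoplasm/TRITC). Ground truth, when given,
#' is written to a JSON sidecar next to the image.
#'
#' @param field a `field_image`.
#' @param path output `.tif` path.
#' @param truth optional truth object from [generate_field_image()]; written
#'   to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, truth = NULL) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(list(field$nuclei, field$granule, field$cyto),
                  function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(cells = truth$cells, granules = truth$granules),
      paste0(path, ".truth.json"), digits = NA, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_field_tiff
#' @param well,field_index metadata stamped on the restored object.
#' @export
read_field_tiff <- function(path, well = NA_character_, field_index = NA_integer_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) {
    stop("expected a 3-page TIFF (nuclei, granule, cytoplasm): ", path)
  }
  to16 <- function(m) round(m * 65535)
  structure(
    list(nuclei = to16(pages[[1]]), granule = to16(pages[[2]]),
         cyto = to16(pages[[3]]), well = well, field = field_index),
    class = "field_image"
  )
}

#' Plate table CSV round trip
#'
#' Plates use the column layout
#' `well,row,col,condition,compound,dose,replicate,alpha_counts,nuclei,context`
#' (plus any extra columns such as `role` or `granules_per_cell`).
#'
#' @param wells plate tibble.
#' @param path CSV path.
#' @return `path` / tibble.
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read an imaging manifest
#'
#' A manifest CSV (`well,field,path`) lists the per-field TIFFs of a run;
#' paths are resolved relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return tibble with absolute `path` column.
#' @export
read_field_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well", "field", "path") %in% names(man)))
  abs <- file.path(dirname(normalizePath(path)), man$path)
  man$path <- ifelse(file.exists(man$path), man$path, abs)
  tibble::as_tibble(man)
}

#' Quantify every well listed in a manifest
#'
#' @param manifest tibble from [read_field_manifest()].
#' @param params a [granule_params()].
#' @return tibble with one [quantify_well()] row per well.
#' @export
quantify_manifest <- function(manifest, params = granule_params()) {
  dplyr::bind_rows(lapply(split(manifest, manifest$well), function(m) {
    fields <- mapply(read_field_tiff, m$path, m$well, m$field, SIMPLIFY = FALSE)
    quantify_well(fields, params, well = m$well[1])
  }))
}

#' Read a screen configuration YAML
#'
#' Recognized keys: `control_label`, `max_toxicity`, `low_cut`, `high_cut`,
#' `alpha`; unknown keys are kept. Missing keys get the pipeline defaults.
#'
#' @param path YAML path (or `NULL` for pure defaults).
#' @return named list of settings.
#' @export
read_screen_config <- function(path = NULL) {
  defaults <- list(control_label = "vehicle", max_toxicity = 0.20,
                   low_cut = 80, high_cut = 120, alpha = 0.05)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

#' Write a screen report to disk
#'
#' Emits `calls.csv`, `summary.csv`, optional `stats.csv` and `qc.csv`, and a
#' JSON summary `report.json` into `dir`.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$calls, file.path(dir, "calls.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$stats)) {
    utils::write.csv(report$stats, file.path(dir, "stats.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$qc)) {
    qcs <- if (inherits(report$qc, "zprime_qc")) list(all = report$qc) else report$qc
    qc_tab <- dplyr::bind_rows(lapply(names(qcs), function(nm) {
      q <- qcs[[nm]]
      tibble::tibble(context = nm, mu_p = q$mu_p, sigma_p = q$sigma_p,
                     mu_n = q$mu_n, sigma_n = q$sigma_n, zprime = q$zprime)
    }))
    utils::write.csv(qc_tab, file.path(dir, "qc.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
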