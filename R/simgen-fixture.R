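#' Deterministic reference screen fixture
#'
#' Builds the packaged two-context reference screen: fourteen FDA-approved
#' test compounds plus three mechanism reference compounds (Go6983, GW4869,
#' spiroepoxide), vehicle wells and assay positive/negative control wells, in
#' the MDA-MB-453 and MCF7 cell-line contexts, six replicate wells per
#' condition. Each well carries both readouts of the convergent screen: raw
#' AlphaScreen counts with nuclei (extracellular, ExoScreen) and LBPA-positive
#' granules per cell (intracellular, high-content imaging). A dose-response
#' series in the MCF7 context covers the five MCF7 hit compounds.
#'
#' Effect magnitudes are synthetic: they are chosen to reproduce each
#' compound's qualitative effect class (release inhibitor, biogenesis
#' inhibitor, activator, or ExoScreen-only activator), not any particular
#' printed percentage. The fourteenth panel member is a synthetic placeholder
#' (`panel14`, an ExoScreen-only activator): the screened panel is larger than
#' the set of individually identifiable compounds. The fixture is fully
#' deterministic: it uses an internal fixed RNG state and takes no seed, so
#' regeneration is always bit-identical.
#'
#' @return list with
#'   \describe{
#'     \item{wells}{tibble, one row per well, columns `well,row,col,condition,
#'       compound,dose,replicate,alpha_counts,nuclei,context,role,
#'       granules_per_cell` (granules are `NA` for the cell-free assay control
#'       wells).}
#'     \item{dose_response}{tibble of MCF7 dose-series wells (same columns).}
#'     \item{classes}{tibble of the true per-compound, per-context effect
#'       classes -- metadata for validation only, never consumed by the
#'       analysis.}
#'   }
#' @export
reference_screen_fixture <- function() {
  w <- 6L
  noise_cv <- 0.04
  baseline_alpha <- 50000
  baseline_nuclei <- 2000
  baseline_gpc <- 5.0  # vehicle-level LBPA granules per cell

  # exo: released-exosome signal as fraction of vehicle;
  # lbpa: intracellular granule level as fraction of vehicle.
  panel <- function(context, exo, lbpa) {
    nm <- names(exo)
    tibble::tibble(
      compound = nm, context = context,
      exo = unname(exo), lbpa = unname(lbpa[nm]),
      role = ifelse(nm %in% c("Go6983", "GW4869", "spiroepoxide"),
                    "reference", "test")
    )
  }
  mda <- panel(
    "MDA-MB-453",
    exo = c(docetaxel = 0.45, biscurcumin = 0.55, primaquine = 0.60,
            doxorubicin = 0.65, dinaciclib = 1.40, exemestane = 1.35,
            alendronate = 1.60, fasudil = 1.45, dasatinib = 1.50,
            neratinib = 1.33, tamoxifen = 1.40, afatinib = 1.32,
            fulvestrant = 1.30, panel14 = 1.30,
            Go6983 = 0.40, GW4869 = 0.55, spiroepoxide = 0.50),
    lbpa = c(docetaxel = 1.8, biscurcumin = 1.6, primaquine = 1.7,
             doxorubicin = 1.5, dinaciclib = 1.0, exemestane = 1.0,
             alendronate = 1.5, fasudil = 1.45, dasatinib = 1.4,
             neratinib = 1.0, tamoxifen = 1.35, afatinib = 1.0,
             fulvestrant = 1.0, panel14 = 1.0,
             Go6983 = 1.9, GW4869 = 0.50, spiroepoxide = 0.45)
  )
  mcf7 <- panel(
    "MCF7",
    exo = c(docetaxel = 0.50, biscurcumin = 0.45, primaquine = 0.62,
            doxorubicin = 0.58, dinaciclib = 0.70, exemestane = 1.40,
            alendronate = 1.55, fasudil = 1.35, dasatinib = 1.50,
            neratinib = 1.30, tamoxifen = 1.35, afatinib = 1.30,
            fulvestrant = 1.30, panel14 = 1.30,
            Go6983 = 0.42, GW4869 = 0.52, spiroepoxide = 0.48),
    lbpa = c(docetaxel = 1.7, biscurcumin = 1.8, primaquine = 1.6,
             doxorubicin = 1.6, dinaciclib = 1.5, exemestane = 1.4,
             alendronate = 1.5, fasudil = 1.0, dasatinib = 1.45,
             neratinib = 1.0, tamoxifen = 1.0, afatinib = 1.0,
             fulvestrant = 1.0, panel14 = 1.0,
             Go6983 = 1.85, GW4869 = 0.55, spiroepoxide = 0.50)
  )

  build_context <- function(tab) {
    conds <- rbind(
      data.frame(compound = c("vehicle", "pos_ctrl", "neg_ctrl"),
                 exo = c(1, 2, 0.02), lbpa = c(1, NA, NA),
                 role = c("vehicle", "pos_ctrl", "neg_ctrl"),
                 viability = 1, stringsAsFactors = FALSE),
      data.frame(compound = tab$compound, exo = tab$exo, lbpa = tab$lbpa,
                 role = tab$role,
                 viability = ifelse(tab$role == "reference", 0.95, 0.92),
                 stringsAsFactors = FALSE)
    )
    conds$dose <- ifelse(conds$role %in% c("test", "reference"), 1, 0)
    conds$condition <- ifelse(conds$dose > 0,
                              paste0(conds$compound, "@", conds$dose),
                              conds$compound)
    idx <- rep(seq_len(nrow(conds)), each = w)
    n <- length(idx)
    out <- well_ids(n)
    out$condition <- conds$condition[idx]
    out$compound <- conds$compound[idx]
    out$dose <- conds$dose[idx]
    out$replicate <- rep(seq_len(w), times = nrow(conds))
    out$alpha_counts <- baseline_alpha * conds$exo[idx] *
      conds$viability[idx] * lognormal_factor(n, noise_cv)
    out$nuclei <- round(baseline_nuclei * conds$viability[idx] *
                          lognormal_factor(n, noise_cv))
    out$context <- tab$context[1]
    out$role <- conds$role[idx]
    out$granules_per_cell <- baseline_gpc * conds$lbpa[idx] *
      lognormal_factor(n, noise_cv)
    tibble::as_tibble(out)
  }

  # MCF7 dose ladders for the five MCF7 hits (percent of vehicle at each
  # dose): biscurcumin falls monotonically across the whole range;
  # doxorubicin and dinaciclib lose the trend at the top dose; docetaxel and
  # primaquine inhibit without dose dependence.
  dr_levels <- list(
    biscurcumin = c(0.90, 0.72, 0.55, 0.42),
    doxorubicin = c(0.88, 0.70, 0.58, 0.64),
    dinaciclib  = c(0.92, 0.75, 0.62, 0.68),
    docetaxel   = c(0.55, 0.52, 0.56, 0.50),
    primaquine  = c(0.68, 0.72, 0.66, 0.70)
  )
  doses <- c(0.25, 0.5, 1, 2)
  build_dose_response <- function() {
    conds <- do.call(rbind, c(
      list(data.frame(compound = "vehicle", dose = 0, exo = 1,
                      role = "vehicle", stringsAsFactors = FALSE)),
      lapply(names(dr_levels), function(cp) {
        data.frame(compound = cp, dose = doses, exo = dr_levels[[cp]],
                   role = "test", stringsAsFactors = FALSE)
      })
    ))
    conds$condition <- ifelse(conds$role == "vehicle", "vehicle",
                              paste0(conds$compound, "@", conds$dose))
    idx <- rep(seq_len(nrow(conds)), each = w)
    n <- length(idx)
    out <- well_ids(n)
    out$condition <- conds$condition[idx]
    out$compound <- conds$compound[idx]
    out$dose <- conds$dose[idx]
    out$replicate <- rep(seq_len(w), times = nrow(conds))
    out$alpha_counts <- baseline_alpha * conds$exo[idx] * 0.92 *
      lognormal_factor(n, noise_cv)
    out$nuclei <- round(baseline_nuclei * 0.92 * lognormal_factor(n, noise_cv))
    out$context <- "MCF7"
    out$role <- conds$role[idx]
    out$granules_per_cell <- NA_real_
    tibble::as_tibble(out)
  }

  with_local_seed(914213L, {
    wells <- dplyr::bind_rows(build_context(mda), build_context(mcf7))
    dose_response <- build_dose_response()
    classes <- dplyr::bind_rows(mda, mcf7)
    classes$class <- with(classes, ifelse(
      exo < 1 & lbpa > 1, "release_inhibitor",
      ifelse(exo < 1 & lbpa < 1, "biogenesis_inhibitor",
             ifelse(exo > 1 & lbpa > 1, "biogenesis_activator",
                    ifelse(exo > 1, "exoscreen_activator", "inert")))))
    list(wells = wells, dose_response = dose_response,
         classes = tibble::as_tibble(classes))
  })
}
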