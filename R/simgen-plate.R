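#' Configuration for a synthetic screening plate
#'
#' Describes one simulated 96-well screen: a vehicle-control group, assay
#' positive/negative control groups used for Z'-factor QC, and one group of
#' `wells_per_condition` replicate wells per test compound. Each well carries
#' a raw AlphaScreen-type count (`alpha_counts`) and a nuclei count; both are
#' perturbed by independent multiplicative log-normal well noise with
#' coefficient of variation `noise_cv`.
#'
#' The assay controls emulate an exosome-enriched supernatant
#' (`pos_ctrl_multiplier`, signal well above vehicle) against a medium-only
#' background (`neg_ctrl_multiplier`, a few percent of vehicle signal), the
#' standard max/min signal pair used to compute a plate Z'-factor.
#'
#' @param compounds character vector of compound names (length defines the
#'   number of test conditions).
#' @param wells_per_condition replicate wells per condition (default 6).
#' @param baseline_alpha expected raw counts for an untreated well.
#' @param baseline_nuclei expected nuclei per well for an untreated well.
#' @param effect_multiplier per-compound factor applied to the released-exosome
#'   signal (1 = inert, < 1 inhibition, > 1 activation); recycled to
#'   `length(compounds)`.
#' @param viability_factor per-compound survival fraction in (0, 1]; recycled.
#' @param noise_cv coefficient of variation of the log-normal well noise.
#' @param pos_ctrl_multiplier,neg_ctrl_multiplier signal multipliers for the
#'   assay positive / negative control wells.
#' @param dose nominal dose recorded for the test wells (single value or one
#'   per compound; arbitrary units, metadata only).
#' @param context cell-line context label recorded on every well.
#' @param seed integer RNG seed; the same seed yields a bit-identical plate.
#' @return object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(compounds = paste0("cmpd", seq_len(4)),
                              wells_per_condition = 6,
                              baseline_alpha = 50000,
                              baseline_nuclei = 2000,
                              effect_multiplier = 1,
                              viability_factor = 1,
                              noise_cv = 0.04,
                              pos_ctrl_multiplier = 2,
                              neg_ctrl_multiplier = 0.02,
                              dose = 1,
                              context = "cellA",
                              seed = 1) {
  stopifnot(length(compounds) >= 0, is.character(compounds))
  check_finite(baseline_alpha, "baseline_alpha")
  check_finite(baseline_nuclei, "baseline_nuclei")
  check_finite(effect_multiplier, "effect_multiplier")
  check_finite(viability_factor, "viability_factor")
  check_finite(noise_cv, "noise_cv")
  check_finite(pos_ctrl_multiplier, "pos_ctrl_multiplier")
  check_finite(neg_ctrl_multiplier, "neg_ctrl_multiplier")
  if (wells_per_condition < 2) stop("wells_per_condition must be >= 2")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(viability_factor <= 0 | viability_factor > 1)) {
    stop("viability_factor must lie in (0, 1]")
  }
  if (any(effect_multiplier < 0)) stop("effect_multiplier must be >= 0")
  n <- length(compounds)
  cfg <- list(
    compounds = compounds,
    wells_per_condition = as.integer(wells_per_condition),
    baseline_alpha = baseline_alpha,
    baseline_nuclei = baseline_nuclei,
    effect_multiplier = rep_len(effect_multiplier, n),
    viability_factor = rep_len(viability_factor, n),
    noise_cv = noise_cv,
    pos_ctrl_multiplier = pos_ctrl_multiplier,
    neg_ctrl_multiplier = neg_ctrl_multiplier,
    dose = rep_len(dose, n),
    context = context,
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_sim_config"
  cfg
}

well_ids <- function(n) {
  plate <- (seq_len(n) - 1L) %/% 96L + 1L
  idx <- (seq_len(n) - 1L) %% 96L
  row <- idx %/% 12L + 1L
  col <- idx %% 12L + 1L
  data.frame(
    well = sprintf("P%d-%s%02d", plate, LETTERS[row], col),
    row = row, col = col
  )
}

#' Generate one synthetic screening plate
#'
#' Draws raw counts for every well of the configured screen:
#' `alpha_counts = baseline_alpha * multiplier * viability * lognormal(1, cv)`
#' and `nuclei = round(baseline_nuclei * viability * lognormal(1, cv))`, with
#' the two noise draws independent. The plate contains vehicle wells
#' (multiplier 1), assay positive/negative control wells and
#' `wells_per_condition` wells per compound.
#'
#' @param config a [screen_sim_config()].
#' @return list with `wells` (tibble, one row per well: `well,row,col,
#'   condition,compound,dose,replicate,alpha_counts,nuclei,context,role`) and
#'   `truth` (tibble of per-condition true multipliers, viability and effect
#'   class).
#' @export
generate_screen_plate <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  w <- config$wells_per_condition
  conditions <- data.frame(
    condition = c("vehicle", "pos_ctrl", "neg_ctrl",
                  if (length(config$compounds))
                    paste0(config$compounds, "@", config$dose)),
    compound = c("vehicle", "pos_ctrl", "neg_ctrl", config$compounds),
    dose = c(0, 0, 0, config$dose),
    multiplier = c(1, config$pos_ctrl_multiplier, config$neg_ctrl_multiplier,
                   config$effect_multiplier),
    viability = c(1, 1, 1, config$viability_factor),
    role = c("vehicle", "pos_ctrl", "neg_ctrl",
             rep("test", length(config$compounds))),
    stringsAsFactors = FALSE
  )
  n_wells <- nrow(conditions) * w
  wells <- with_local_seed(config$seed, {
    idx <- rep(seq_len(nrow(conditions)), each = w)
    noise_a <- lognormal_factor(n_wells, config$noise_cv)
    noise_n <- lognormal_factor(n_wells, config$noise_cv)
    out <- well_ids(n_wells)
    out$condition <- conditions$condition[idx]
    out$compound <- conditions$compound[idx]
    out$dose <- conditions$dose[idx]
    out$replicate <- rep(seq_len(w), times = nrow(conditions))
    out$alpha_counts <- config$baseline_alpha * conditions$multiplier[idx] *
      conditions$viability[idx] * noise_a
    out$nuclei <- round(config$baseline_nuclei * conditions$viability[idx] *
                          noise_n)
    out$context <- config$context
    out$role <- conditions$role[idx]
    out
  })
  truth <- conditions
  truth$class <- ifelse(truth$role != "test", truth$role,
                        ifelse(truth$multiplier < 1, "inhibitor",
                               ifelse(truth$multiplier > 1, "activator",
                                      "inert")))
  truth$context <- config$context
  list(wells = tibble::as_tibble(wells), truth = tibble::as_tibble(truth))
}
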