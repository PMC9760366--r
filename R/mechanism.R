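#' Three-state readout classification
#'
#' Applies the screen's cut-off rule to a percent-of-control value:
#' `LOW` if the value falls strictly below `low_cut`, `HIGH` if it lies
#' strictly above `high_cut`, otherwise `UNCHANGED`; either side can
#' additionally be required to reach Dunnett significance. Boundary values
#' (exactly 80 or 120 by default) are `UNCHANGED`.
#'
#' @param value percent-of-control values (vectorized).
#' @param significant logical Dunnett significance per value.
#' @param low_cut,high_cut percent cut-offs (defaults 80 / 120).
#' @param require_sig_low,require_sig_high whether `LOW` / `HIGH` calls
#'   require significance.
#' @return character vector of states `LOW | UNCHANGED | HIGH`.
#' @export
readout_state <- function(value, significant,
                          low_cut = 80, high_cut = 120,
                          require_sig_low = FALSE, require_sig_high = TRUE) {
  stopifnot(low_cut < high_cut, length(value) == length(significant))
  ifelse(value < low_cut & (significant | !require_sig_low), "LOW",
         ifelse(value > high_cut & (significant | !require_sig_high), "HIGH",
                "UNCHANGED"))
}

#' Call ExoScreen hits from a normalized, gated screen table
#'
#' Conditions with mean percent-of-control signal strictly below `low_cut`
#' are reduced-signal hits (exosome inhibitors); conditions significantly
#' above `high_cut` are increased-signal hits (activators); the rest are
#' unchanged. Only the activator side requires Dunnett significance by
#' default. Conditions failing the viability gate are excluded from calling.
#'
#' @param table gated screen table ([percent_of_control()] then
#'   [viability_gate()]).
#' @param stats Dunnett results ([screen_dunnett()]) covering every gated
#'   condition.
#' @param low_cut,high_cut percent cut-offs (defaults 80 / 120).
#' @param require_sig_low,require_sig_high significance requirements per side.
#' @return tibble per (context, condition): `compound, dose, role,
#'   mean_percent, significant, exo_state`.
#' @export
call_exoscreen_hits <- function(table, stats, low_cut = 80, high_cut = 120,
                                require_sig_low = FALSE,
                                require_sig_high = TRUE) {
  stopifnot(is.data.frame(table))
  tab <- table[!table$condition %in% c("vehicle", "pos_ctrl", "neg_ctrl"), ,
               drop = FALSE]
  if ("viability_pass" %in% names(tab)) {
    dropped <- tab$condition[!tab$viability_pass]
    if (length(dropped)) {
      message("excluding ", length(dropped),
              " condition(s) failing the viability gate from hit calling")
    }
    tab <- tab[tab$viability_pass, , drop = FALSE]
  }
  key <- paste(tab$context, tab$condition)
  skey <- paste(stats$context, stats$condition)
  if (!all(key %in% skey)) {
    stop("conditions missing from stats: ",
         paste(utils::head(setdiff(key, skey), 5), collapse = ", "))
  }
  tab$significant <- stats$significant[match(key, skey)]
  tab$exo_state <- readout_state(tab$mean_percent, tab$significant,
                                 low_cut, high_cut,
                                 require_sig_low, require_sig_high)
  dplyr::select(tab, "context", "condition", "compound", "dose", "role",
                "mean_percent", "significant", "exo_state")
}

#' Classify the intracellular LBPA readout
#'
#' Applies the same three-state rule to normalized LBPA granules-per-cell
#' percentages. Both directions require Dunnett significance by default (the
#' intracellular comparisons are starred in both directions).
#'
#' @param table aggregated LBPA table ([lbpa_percent_of_control()]).
#' @param stats Dunnett results on the per-well LBPA percents.
#' @inheritParams call_exoscreen_hits
#' @return tibble per (context, condition): `compound, dose, role,
#'   mean_percent, significant, lbpa_state`.
#' @export
lbpa_state <- function(table, stats, low_cut = 80, high_cut = 120,
                       require_sig_low = TRUE, require_sig_high = TRUE) {
  out <- call_exoscreen_hits(table, stats, low_cut, high_cut,
                             require_sig_low, require_sig_high)
  names(out)[names(out) == "exo_state"] <- "lbpa_state"
  out
}

# The dual-readout decision table (total over all 9 state pairs).
mechanism_table <- function() {
  tibble::tibble(
    exo_state = rep(c("LOW", "UNCHANGED", "HIGH"), each = 3),
    lbpa_state = rep(c("LOW", "UNCHANGED", "HIGH"), times = 3),
    call = c(
      "BIOGENESIS_INHIBITOR", "UNCLASSIFIED", "RELEASE_INHIBITOR",   # exo LOW
      "INACTIVE", "INACTIVE", "INACTIVE",                            # exo UNCHANGED
      "UNCLASSIFIED", "UNCLASSIFIED", "BIOGENESIS_ACTIVATOR"         # exo HIGH
    )
  )
}

#' Dual-readout mechanism classification
#'
#' Combines the extracellular (ExoScreen) and intracellular (LBPA) states
#' into a mechanism call via a total decision table: low released-exosome
#' signal with elevated intracellular LBPA means vesicles are made but not
#' released (`RELEASE_INHIBITOR`); low signal on both sides means vesicles
#' are not made (`BIOGENESIS_INHIBITOR`); elevated on both sides means
#' `BIOGENESIS_ACTIVATOR`. An unchanged extracellular signal is `INACTIVE`
#' regardless of the LBPA state; the remaining discordant pairs are
#' `UNCLASSIFIED` (the screen defines no mechanism for them). The classifier
#' is pure: identical states always produce the identical call.
#'
#' @param exo_state,lbpa_state character vectors of states
#'   (`LOW | UNCHANGED | HIGH`), recycled to a common length.
#' @return character vector of calls.
#' @export
classify_mechanism <- function(exo_state, lbpa_state) {
  n <- max(length(exo_state), length(lbpa_state))
  exo_state <- rep_len(exo_state, n)
  lbpa_state <- rep_len(lbpa_state, n)
  tab <- mechanism_table()
  idx <- match(paste(exo_state, lbpa_state),
               paste(tab$exo_state, tab$lbpa_state))
  if (any(is.na(idx))) {
    stop("states must be LOW, UNCHANGED or HIGH")
  }
  tab$call[idx]
}

#' Assemble the screen report
#'
#' Joins the per-condition ExoScreen and LBPA states, applies the mechanism
#' decision table, and summarises per-context hit counts. An ExoScreen
#' "inhibitor" is any test compound with a `LOW` extracellular state
#' (whatever its mechanism call); reference compounds are reported but not
#' counted among the screen hits.
#'
#' @param exo_calls tibble from [call_exoscreen_hits()].
#' @param lbpa_calls tibble from [lbpa_state()]; conditions absent here get
#'   an `UNCHANGED` LBPA state.
#' @param qc optional Z' QC objects (list by context) carried into the report.
#' @param stats optional stats report table carried into the report.
#' @return object of class `screen_report`: list with `calls` (per-condition
#'   tibble incl. `call`), `summary` (per-context hit counts), `qc`, `stats`.
#' @export
screen_report <- function(exo_calls, lbpa_calls = NULL, qc = NULL, stats = NULL) {
  calls <- dplyr::rename(exo_calls, exo_percent = "mean_percent",
                         exo_significant = "significant")
  if (!is.null(lbpa_calls) && nrow(lbpa_calls)) {
    lb <- dplyr::select(lbpa_calls, "context", "condition",
                        lbpa_percent = "mean_percent",
                        lbpa_significant = "significant", "lbpa_state")
    calls <- dplyr::left_join(calls, lb, by = c("context", "condition"))
  } else {
    calls$lbpa_percent <- NA_real_
    calls$lbpa_significant <- NA
    calls$lbpa_state <- NA_character_
  }
  calls$lbpa_state[is.na(calls$lbpa_state)] <- "UNCHANGED"
  calls$call <- classify_mechanism(calls$exo_state, calls$lbpa_state)
  is_test <- if ("role" %in% names(calls)) {
    !is.na(calls$role) & calls$role == "test"
  } else {
    rep(TRUE, nrow(calls))
  }
  summarise_ctx <- function(w, test) {
    tibble::tibble(
      context = w$context[1],
      n_conditions = nrow(w),
      n_inhibitors = sum(test & w$exo_state == "LOW"),
      n_release_inhibitors = sum(test & w$call == "RELEASE_INHIBITOR"),
      n_biogenesis_inhibitors = sum(test & w$call == "BIOGENESIS_INHIBITOR"),
      n_biogenesis_activators = sum(test & w$call == "BIOGENESIS_ACTIVATOR"),
      inhibitors = paste(sort(w$compound[test & w$exo_state == "LOW"]),
                         collapse = ";")
    )
  }
  summary <- dplyr::bind_rows(lapply(
    split(seq_len(nrow(calls)), calls$context),
    function(i) summarise_ctx(calls[i, , drop = FALSE], is_test[i])
  ))
  out <- list(calls = calls, summary = summary, qc = qc, stats = stats)
  class(out) <- "screen_report"
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Convergent exosome-modulator screen report\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: %d ExoScreen inhibitor(s) [%s]; %d release / %d biogenesis inhibitor(s), %d biogenesis activator(s)\n",
                s$context, s$n_inhibitors, s$inhibitors,
                s$n_release_inhibitors, s$n_biogenesis_inhibitors,
                s$n_biogenesis_activators))
  }
  if (!is.null(x$qc)) {
    qcs <- if (inherits(x$qc, "zprime_qc")) list(x$qc) else x$qc
    for (nm in seq_along(qcs)) {
      cat(sprintf("  Z' (%s): %.3f\n",
                  names(qcs)[nm] %||% as.character(nm), qcs[[nm]]$zprime))
    }
  }
  invisible(x)
}

#' Run the full convergent screen analysis
#'
#' End-to-end pipeline on a dual-readout plate table: per-nucleus
#' normalization and percent-of-control, Z' assay QC, viability gating,
#' per-context Dunnett comparisons for both readouts, three-state calls and
#' the mechanism decision table.
#'
#' @param wells plate well tibble carrying `alpha_counts`, `nuclei` and
#'   (optionally) `granules_per_cell` per well.
#' @param control_label vehicle condition label.
#' @param max_toxicity viability gate threshold (default 0.20).
#' @param low_cut,high_cut percent cut-offs (defaults 80 / 120).
#' @param alpha significance level.
#' @param seed seed for the Dunnett multivariate-t integration.
#' @return a `screen_report`.
#' @export
run_convergent_screen <- function(wells, control_label = "vehicle",
                                  max_toxicity = 0.20,
                                  low_cut = 80, high_cut = 120,
                                  alpha = 0.05, seed = 1L) {
  per_well <- well_percent_signals(wells, control_label)
  table <- percent_of_control(wells, control_label)
  table <- viability_gate(table, max_toxicity)
  qc <- tryCatch(plate_zprime(wells), error = function(e) NULL)
  exo_stats <- screen_dunnett(per_well, control_label, alpha = alpha, seed = seed)
  exo_calls <- call_exoscreen_hits(table, exo_stats, low_cut, high_cut)
  lbpa_calls <- NULL
  if ("granules_per_cell" %in% names(wells) &&
      any(!is.na(wells$granules_per_cell))) {
    lb_well <- lbpa_well_percent(wells, control_label)
    lb_tab <- lbpa_percent_of_control(wells, control_label)
    lb_stats <- screen_dunnett(lb_well, control_label, alpha = alpha, seed = seed)
    lb_gated <- lb_tab
    lb_gated$viability_pass <- TRUE
    lbpa_calls <- lbpa_state(lb_gated, lb_stats, low_cut, high_cut)
  }
  screen_report(exo_calls, lbpa_calls, qc = qc,
                stats = stats_report(table, exo_stats))
}
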