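#' Per-nucleus signal of a well
#'
#' Raw AlphaScreen counts are normalized to cell viability by dividing by the
#' well's nuclei count, so supernatant signal is expressed per surviving cell.
#'
#' @param alpha_counts raw counts, finite and >= 0 (vectorized).
#' @param nuclei nuclei counts, > 0.
#' @return `alpha_counts / nuclei`.
#' @export
per_nucleus_signal <- function(alpha_counts, nuclei) {
  check_finite(alpha_counts, "alpha_counts")
  check_finite(nuclei, "nuclei")
  if (any(alpha_counts < 0)) stop("alpha_counts must be >= 0")
  if (any(nuclei <= 0)) {
    stop("invalid well: nuclei count is zero; exclude the well upstream")
  }
  alpha_counts / nuclei
}

# Drop wells that cannot be normalized (zero nuclei), reporting them.
drop_invalid_wells <- function(wells) {
  bad <- wells$nuclei <= 0 | !is.finite(wells$alpha_counts) |
    wells$alpha_counts < 0
  if (any(bad)) {
    message("excluding ", sum(bad), " invalid well(s) (zero nuclei or bad counts): ",
            paste(utils::head(wells$well[bad], 10), collapse = ", "))
    wells <- wells[!bad, , drop = FALSE]
  }
  wells
}

#' Per-well percent-of-control signals
#'
#' Computes each well's per-nucleus signal divided by the mean per-nucleus
#' signal of the vehicle-control wells of the same cell-line context, times
#' 100. The vehicle group therefore averages exactly 100 by construction.
#'
#' @param wells tibble of well records (columns `well, condition, compound,
#'   alpha_counts, nuclei, context`, optionally `role, dose`).
#' @param control_label condition label of the vehicle-control group.
#' @return input wells (invalid wells dropped) with columns
#'   `per_nucleus` and `percent` added.
#' @export
well_percent_signals <- function(wells, control_label = "vehicle") {
  stopifnot(is.data.frame(wells))
  wells <- drop_invalid_wells(wells)
  wells$per_nucleus <- wells$alpha_counts / wells$nuclei
  out <- lapply(split(wells, wells$context), function(w) {
    ctrl <- w$per_nucleus[w$condition == control_label]
    if (length(ctrl) < 2) {
      stop("context '", w$context[1], "': needs >= 2 '", control_label,
           "' control wells, found ", length(ctrl))
    }
    w$percent <- w$per_nucleus / mean(ctrl) * 100
    w
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' Condition-level percent-of-control screen table
#'
#' Aggregates per-well percent-of-control signals to one row per
#' (context, condition): mean percent, SEM, replicate count, and the
#' condition's viability fraction (condition mean nuclei / vehicle mean
#' nuclei), the quantity later used by the toxicity gate.
#'
#' @inheritParams well_percent_signals
#' @return tibble with columns `context, condition, compound, dose, role, n,
#'   mean_percent, sem_percent, viability`.
#' @export
percent_of_control <- function(wells, control_label = "vehicle") {
  pw <- well_percent_signals(wells, control_label)
  if (!"role" %in% names(pw)) pw$role <- NA_character_
  if (!"dose" %in% names(pw)) pw$dose <- NA_real_
  tab <- pw |>
    dplyr::group_by(.data$context, .data$condition, .data$compound,
                    .data$dose, .data$role) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent = mean(.data$percent),
      sem_percent = stats::sd(.data$percent) / sqrt(dplyr::n()),
      mean_nuclei = mean(.data$nuclei),
      .groups = "drop"
    )
  ctrl_nuc <- tab |>
    dplyr::filter(.data$condition == control_label) |>
    dplyr::select("context", ctrl_nuclei = "mean_nuclei")
  tab <- dplyr::left_join(tab, ctrl_nuc, by = "context")
  tab$viability <- tab$mean_nuclei / tab$ctrl_nuclei
  tab$mean_nuclei <- tab$ctrl_nuclei <- NULL
  tab
}

#' Z'-factor assay quality
#'
#' The standard plate-assay separation statistic
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}}
#' computed from the means and sample standard deviations (n-1 denominator)
#' of the positive and negative assay-control wells. Z' is at most 1; values
#' above 0.5 indicate an excellent assay.
#'
#' @param pos,neg numeric vectors (>= 2 values each) of control signals.
#' @return object of class `zprime_qc`: list with `mu_p, sigma_p, mu_n,
#'   sigma_n, zprime, n_p, n_n`.
#' @export
zprime <- function(pos, neg) {
  check_finite(pos, "pos")
  check_finite(neg, "neg")
  if (length(pos) < 2 || length(neg) < 2) {
    stop("zprime needs >= 2 values per control group")
  }
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) {
    stop("undefined separation: positive and negative control means are equal")
  }
  sigma_p <- stats::sd(pos); sigma_n <- stats::sd(neg)
  out <- list(mu_p = mu_p, sigma_p = sigma_p, mu_n = mu_n, sigma_n = sigma_n,
              zprime = 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n),
              n_p = length(pos), n_n = length(neg))
  class(out) <- "zprime_qc"
  out
}

#' @export
print.zprime_qc <- function(x, ...) {
  cat(sprintf("Z'-factor: %.4f  (mu_p=%.3g sd_p=%.3g | mu_n=%.3g sd_n=%.3g)\n",
              x$zprime, x$mu_p, x$sigma_p, x$mu_n, x$sigma_n))
  invisible(x)
}

#' Z'-factor of a plate's assay-control wells
#'
#' Convenience wrapper: extracts the positive and negative assay-control
#' wells of one plate table and computes [zprime()] on their per-nucleus
#' signals.
#'
#' @param wells plate well tibble.
#' @param pos_label,neg_label condition labels of the control groups.
#' @return `zprime_qc` object (one per context if several are present, as a
#'   named list; a bare object for a single context).
#' @export
plate_zprime <- function(wells, pos_label = "pos_ctrl", neg_label = "neg_ctrl") {
  wells <- drop_invalid_wells(wells)
  res <- lapply(split(wells, wells$context), function(w) {
    pos <- per_nucleus_signal(w$alpha_counts[w$condition == pos_label],
                              w$nuclei[w$condition == pos_label])
    neg <- per_nucleus_signal(w$alpha_counts[w$condition == neg_label],
                              w$nuclei[w$condition == neg_label])
    zprime(pos, neg)
  })
  if (length(res) == 1L) res[[1]] else res
}

#' Viability (toxicity) gate
#'
#' Flags conditions whose viability fraction falls below `1 - max_toxicity`.
#' Compounds were to be screened at non-toxic concentrations; wells violating
#' that are excluded from hit calling, and the exclusion is reported.
#'
#' @param table screen table from [percent_of_control()].
#' @param max_toxicity maximum tolerated toxicity fraction (default 0.20,
#'   i.e. viability must be >= 0.80).
#' @return `table` with logical column `viability_pass` added.
#' @export
viability_gate <- function(table, max_toxicity = 0.20) {
  stopifnot(is.data.frame(table), "viability" %in% names(table))
  stopifnot(max_toxicity >= 0, max_toxicity < 1)
  table$viability_pass <- table$viability >= 1 - max_toxicity
  excl <- table$condition[!table$viability_pass]
  if (length(excl)) {
    message("viability gate (max toxicity ", max_toxicity, "): excluding ",
            length(excl), " condition(s): ",
            paste(unique(excl), collapse = ", "))
  }
  table
}
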