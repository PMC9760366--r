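#' Dunnett many-to-one comparisons against a shared control
#'
#' Two-sided Dunnett test: each treatment group is compared to the common
#' control with familywise error control. Test statistics use the pooled
#' within-group variance across all groups; adjusted p-values are
#' \eqn{1 - P(\max_j |T_j| \le |t_i|)} under the multivariate t distribution
#' with correlation \eqn{\rho_{ij} = \sqrt{\lambda_i \lambda_j}},
#' \eqn{\lambda_i = n_i / (n_i + n_0)}, evaluated by the Genz-Bretz
#' quasi-Monte-Carlo algorithm under a fixed seed (reproducible).
#'
#' @param groups named list of numeric vectors, one per treatment condition
#'   (each of length >= 2).
#' @param control numeric vector of control values (length >= 2).
#' @param alpha familywise significance level for the `significant` flag.
#' @param seed seed for the multivariate-t integration.
#' @return tibble with one row per group: `condition, n, estimate` (mean
#'   difference from control), `t, df, p_raw, p_adj, significant, direction`
#'   (`"above"`/`"below"` control) and `stars`.
#' @export
dunnett_many_to_one <- function(groups, control, alpha = 0.05, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1, is.numeric(control))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  n0 <- length(control)
  if (n0 < 2 || any(ns < 2)) stop("each group needs n >= 2")
  k <- length(groups)
  all_vals <- c(list(control), groups)
  ssw <- sum(vapply(all_vals, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- sum(ns) + n0 - (k + 1)
  s2 <- ssw / df
  if (s2 <= 0) {
    stop("degenerate input: zero within-group variance in every group")
  }
  m0 <- mean(control)
  est <- unname(vapply(groups, mean, numeric(1))) - m0
  se <- sqrt(s2 * (1 / unname(ns) + 1 / n0))
  tstat <- est / se
  lam <- ns / (ns + n0)
  corr <- sqrt(outer(lam, lam))
  diag(corr) <- 1
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  p_adj <- with_local_seed(seed, vapply(abs(tstat), function(q) {
    pr <- mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k), df = df,
                        corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-5))
    1 - as.numeric(pr)
  }, numeric(1)))
  p_adj <- pmin(1, pmax(p_adj, p_raw))
  tibble::tibble(
    condition = names(groups), n = ns, estimate = est, t = tstat,
    df = df, p_raw = p_raw, p_adj = p_adj,
    significant = p_adj <= alpha,
    direction = ifelse(est >= 0, "above", "below"),
    stars = p_stars(p_adj)
  )
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way F test (equal-variance), as used for the
#' overall condition effect before the many-to-one comparisons.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `f`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs n >= 2")
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw <= 0) stop("degenerate input: zero within-group variance")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value))
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (a < b) of
# #{x_b > x_a} + 0.5 #{ties}; large values indicate an increasing trend.
jt_statistic <- function(values, group_index, n_levels) {
  s <- 0
  for (a in seq_len(n_levels - 1)) {
    xa <- values[group_index == a]
    for (b in (a + 1):n_levels) {
      xb <- values[group_index == b]
      cmp <- outer(xb, xa, "-")
      s <- s + sum(cmp > 0) + 0.5 * sum(cmp == 0)
    }
  }
  s
}

#' Dose-response trend test (Jonckheere-Terpstra, permutation p)
#'
#' Ordered-alternative rank test against the dose order, with the null
#' distribution obtained by permuting well labels across dose groups
#' (seeded). Designed for dose ladders of percent-of-control signals; the
#' `monotone` flag marks a significant decreasing trend (dose-dependent
#' inhibition).
#'
#' @param doses numeric dose per observation (>= 3 distinct levels, each with
#'   replicates).
#' @param values response per observation (e.g. percent of control).
#' @param n_perm number of label permutations (default 10000).
#' @param alternative `"decreasing"` (default), `"increasing"` or
#'   `"two.sided"`.
#' @param alpha level for the `monotone` flag.
#' @param seed permutation seed.
#' @param compound optional label carried into the result.
#' @return tibble row: `compound, n_levels, statistic, p, alternative,
#'   monotone` (significant decreasing trend at `alpha`).
#' @export
trend_test <- function(doses, values, n_perm = 10000, alternative = "decreasing",
                       alpha = 0.05, seed = 1L, compound = NA_character_) {
  stopifnot(length(doses) == length(values))
  alternative <- match.arg(alternative, c("decreasing", "increasing", "two.sided"))
  lev <- sort(unique(doses))
  if (length(lev) < 3) stop("trend test needs >= 3 dose levels")
  gi <- match(doses, lev)
  if (any(tabulate(gi, length(lev)) < 2)) {
    stop("each dose level needs >= 2 replicates")
  }
  obs <- jt_statistic(values, gi, length(lev))
  perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    jt_statistic(values, sample(gi), length(lev))
  }, numeric(1)))
  p_dec <- (1 + sum(perm <= obs)) / (n_perm + 1)
  p_inc <- (1 + sum(perm >= obs)) / (n_perm + 1)
  p <- switch(alternative,
              decreasing = p_dec,
              increasing = p_inc,
              two.sided = min(1, 2 * min(p_dec, p_inc)))
  tibble::tibble(
    compound = compound, n_levels = length(lev), statistic = obs,
    p = p, alternative = alternative,
    monotone = p_dec <= alpha
  )
}

#' Dunnett comparisons for every condition of a screen
#'
#' Convenience layer over [dunnett_many_to_one()]: builds per-condition value
#' groups from per-well percent signals and runs the many-to-one comparison
#' against the vehicle wells, separately per context (readouts are tested
#' separately, each against its own control wells).
#'
#' @param per_well tibble with columns `context, condition, percent` (from
#'   [well_percent_signals()] or [lbpa_well_percent()]).
#' @param control_label vehicle condition label.
#' @param alpha familywise level.
#' @param seed integration seed.
#' @return tibble of [dunnett_many_to_one()] results with a `context` column.
#' @export
screen_dunnett <- function(per_well, control_label = "vehicle",
                           alpha = 0.05, seed = 1L) {
  stopifnot(all(c("context", "condition", "percent") %in% names(per_well)))
  out <- lapply(split(per_well, per_well$context), function(w) {
    ctrl <- w$percent[w$condition == control_label]
    treats <- setdiff(unique(w$condition), control_label)
    treats <- setdiff(treats, c("pos_ctrl", "neg_ctrl"))
    if (!length(treats)) return(NULL)
    groups <- lapply(treats, function(cd) w$percent[w$condition == cd])
    names(groups) <- treats
    res <- dunnett_many_to_one(groups, ctrl, alpha = alpha, seed = seed)
    res$context <- w$context[1]
    res
  })
  dplyr::bind_rows(out)
}

#' Formatted statistics report table
#'
#' One row per condition: mean percent, SEM and the Dunnett comparison with
#' conventional significance stars.
#'
#' @param table aggregated screen table ([percent_of_control()] or
#'   [lbpa_percent_of_control()]).
#' @param stats Dunnett results from [screen_dunnett()].
#' @return tibble joining both on (context, condition).
#' @export
stats_report <- function(table, stats) {
  dplyr::left_join(
    table,
    dplyr::select(stats, "context", "condition", "p_raw", "p_adj",
                  "significant", "direction", "stars"),
    by = c("context", "condition")
  )
}
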