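# Small shared generators; everything is built in code at test time.

tiny_plate <- function(compounds = c("drugA", "drugB"),
                       effect_multiplier = c(0.5, 1.5),
                       viability_factor = 1,
                       noise_cv = 0.04, seed = 11, ...) {
  generate_screen_plate(screen_sim_config(
    compounds = compounds, effect_multiplier = effect_multiplier,
    viability_factor = viability_factor, noise_cv = noise_cv, seed = seed, ...
  ))
}

small_field_config <- function(n_cells = 4, ...) {
  # reduced field keeps the imaging tests quick
  image_sim_config(field_shape = c(300, 300), n_cells = n_cells,
                   cell_radius_px = 40, ...)
}

# pooled-variance two-sample t-test p (oracle for the k = 1 Dunnett case)
pooled_t_p <- function(x, y) {
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

# Monte-Carlo permutation maxT oracle for many-to-one comparisons
perm_maxt_p <- function(groups, control, B = 20000, seed = 2) {
  vals <- c(control, unlist(groups))
  grp <- factor(rep(seq_len(length(groups) + 1), c(length(control),
                                                   lengths(groups))))
  k <- length(groups)
  tstats <- function(v, g) {
    ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
    s2 <- ssw / (length(v) - (k + 1))
    m <- tapply(v, g, mean)
    n <- tapply(v, g, length)
    (m[-1] - m[1]) / sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  }
  obs <- abs(tstats(vals, grp))
  withr::with_seed(seed, {
    maxT <- replicate(B, max(abs(tstats(vals, sample(grp)))))
    vapply(obs, function(t) mean(maxT >= t), numeric(1))
  })
}
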