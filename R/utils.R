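#' @importFrom stats rlnorm rnorm rpois sd median mad pt var runif
#' @importFrom utils head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps generator calls reproducible without disturbing the user's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Multiplicative log-normal noise factors with mean 1 and coefficient of
# variation `cv` (sdlog chosen so E[X] = 1, CV[X] = cv exactly).
lognormal_factor <- function(n, cv) {
  stopifnot(is.numeric(cv), length(cv) == 1L, is.finite(cv), cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 levels.
p_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite and numeric", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
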