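# Internal helpers shared across modules.

# Run `expr` with R's RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

abort_annotmix <- function(msg, class) {
  stop(structure(class = c(class, "annotmix_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Weighted mean / sd with normalized weights; weights must be non-negative,
# not all zero. sd uses the population form (1/sum w), matching the
# strength-weighted moments used throughout.
weighted_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  list(mean = m, sd = sqrt(v))
}

# Weighted Pearson correlation of two vectors (population-weighted moments).
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxy <- sum(w * (x - mx) * (y - my)) / sw
  sx <- sqrt(sum(w * (x - mx)^2) / sw)
  sy <- sqrt(sum(w * (y - my)^2) / sw)
  if (sx <= 0 || sy <= 0)
    abort_annotmix("degenerate residual variance: zero weighted variance in correlation input",
                   "annotmix_degenerate_error")
  sxy / (sx * sy)
}
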