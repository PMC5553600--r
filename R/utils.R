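## Internal helpers: seed management and small numeric utilities.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic sub-seed derivation: master seed plus a stream of small
# integer keys (patient index, reader index, stage code). Kept below 2^31.
derive_seed <- function(master, ...) {
  keys <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in keys) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# stage codes used for per-(patient, reader, stage) seed derivation
STAGE <- c(phantom = 1L, contours = 2L, size = 3L, corrections = 4L,
           manual = 5L, manual_isi = 6L, visual = 7L, visual_isi = 8L)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# angular difference wrapped to [0, 360)
ang_wrap <- function(a) ((a %% 360) + 360) %% 360

# absolute angular distance (degrees) on the circle, in [0, 180]
ang_dist <- function(a, b) {
  d <- abs(ang_wrap(a) - ang_wrap(b))
  pmin(d, 360 - d)
}
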