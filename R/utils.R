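# Internal helpers shared across modules.

# classed errors so callers/tests can discriminate failure modes
stop_pbsvr <- function(class, msg, call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "pbsvr_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cnd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# wrap an angle (degrees) into (-180, 180]
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

# absolute wrapped angular difference in [0, 180]
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop_pbsvr("pbsvr_degenerate_geometry", "zero-length vector")
  v / n
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# run a block with a temporarily seeded, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
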