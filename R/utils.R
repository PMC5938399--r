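`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_pq <- function(msg, class, data = NULL) {
  cond <- structure(
    class = c(class, "projquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

# Euclidean length of each row-segment p0 -> p1 (n x 3 matrices)
seg_lengths <- function(p0, p1) {
  d <- p1 - p0
  sqrt(rowSums(d * d))
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}
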