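# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# nearest odd integer to x, at least `lo`
round_odd <- function(x, lo = 3L) {
  o <- 2L * as.integer(round((x - 1) / 2)) + 1L
  max(lo, o)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite value in %s", what), call. = FALSE)
  invisible(x)
}

# coerce a frame (integer or double matrix) to a double matrix for the
# compiled kernels
as_image <- function(frame) {
  if (!is.matrix(frame)) stop("frame must be a 2D grayscale matrix", call. = FALSE)
  storage.mode(frame) <- "double"
  frame
}

frame_count <- function(frames) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be a height x width x n_frames array", call. = FALSE)
  d[3L]
}

get_frame <- function(frames, t) as_image(frames[, , t])
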