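# Internal helpers shared across modules.

# Reshape a 4-D (x,y,z,frame) array to a frames x voxels matrix and back.
.as_frame_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(4L, 1L, 2L, 3L)), nrow = d[4])
}

.as_series_array <- function(m, dims3) {
  aperm(array(m, c(nrow(m), dims3)), c(2L, 3L, 4L, 1L))
}

# extract one echo as a 4-D array without dropping singleton grid dims
.echo_array <- function(me, e) {
  arr <- me@data[, , , , e, drop = FALSE]
  dim(arr) <- dim(arr)[1:4]
  arr
}

# +1 on ASL control frames, -1 on label frames, for 1-based frame indices.
# "even-control" refers to 0-based frame numbering, matching the cos(pi*n)
# demodulation carrier with n = 0, 1, 2, ...
.parity_sign <- function(n, labelParity = "even-control") {
  s <- rep_len(c(1, -1), n)
  if (identical(labelParity, "odd-control")) -s else s
}

# Temporarily seed the RNG, restoring the caller's stream on exit.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Empty 3-D array of NAs on a given grid.
.na_map <- function(dims3) array(NA_real_, dims3)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
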