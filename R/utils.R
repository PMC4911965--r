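# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed derived from a master seed and a stream of
# integer/character tags. Counter-based so insertion order of other draws can
# never shift a substream.
derive_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.double(master %% 2147483647L)
  for (t in tags) {
    if (is.character(t)) t <- sum(utf8ToInt(t))
    for (v in as.double(t)) {
      # 32-bit-safe linear congruential fold (kept in double precision)
      h <- (h * 69069 + v + 1) %% 2147483647
    }
  }
  as.integer(h)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s", name, min, deparse(x)))
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.double(x)
}

# DFT frequencies in cycles/pixel for an n-point transform, in FFT order.
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= (n - 1L) %/% 2L, k, k - n) / n
}

# Flatten an ROI matrix to the vector layout used for channel matrices
# (column-major, R native). Kept as a single choke point.
flatten_roi <- function(roi) as.vector(roi)

# Coerce a collection of ROIs (3-D array [side, side, n], list of matrices,
# or a single matrix) to a side^2 x n matrix of flattened pixel columns.
roi_stack_matrix <- function(rois, side = NULL) {
  if (is.list(rois)) {
    rois <- array(unlist(rois, use.names = FALSE),
                  dim = c(nrow(rois[[1L]]), ncol(rois[[1L]]), length(rois)))
  }
  if (is.matrix(rois)) rois <- array(rois, dim = c(dim(rois), 1L))
  stopifnot(length(dim(rois)) == 3L)
  if (!is.null(side) && (dim(rois)[1L] != side || dim(rois)[2L] != side)) {
    abort(sprintf("ROI stack is %dx%d but %dx%d was expected",
                  dim(rois)[1L], dim(rois)[2L], side, side))
  }
  dim(rois) <- c(dim(rois)[1L] * dim(rois)[2L], dim(rois)[3L])
  rois
}
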