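#' Motion index of a grayscale frame stack
#'
#' The motion index (MI) summarises bulk motion in a well as the number of
#' pixels whose grayscale intensity changes by at least `threshold` units
#' between consecutive frames:
#' \deqn{m'(I^t) = \sum_{ij} 1\left[\,|I^t_{ij} - I^{t-1}_{ij}| \ge \theta\,\right]}
#' with the conventional threshold \eqn{\theta = 10}. For a stack of `T`
#' frames the trace has `T - 1` entries, one per consecutive frame pair.
#'
#' @param frames a numeric array of dimension `T x H x W` (frames first), or a
#'   list of `T` numeric `H x W` matrices, of non-negative grayscale
#'   intensities.
#' @param threshold minimum absolute per-pixel intensity change counted as
#'   motion, in intensity units. Default 10.
#' @param frame_rate optional frames-per-second metadata attached to the
#'   result; never used in the computation.
#' @param well_id optional well identifier metadata.
#' @return an integer vector of length `T - 1` of class `"mi_trace"`, each
#'   entry in `[0, H*W]`, with attributes `frame_rate` and `well_id`.
#' @examples
#' f <- array(0, dim = c(3, 4, 4))
#' f[2, 1, 1] <- 12     # one pixel jumps by 12 between frames 1 and 2
#' motion_index(f)      # c(1, 1): the pixel changes on the way up and down
#' @export
motion_index <- function(frames, threshold = 10, frame_rate = NULL, well_id = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_shape("all frames must share the same H x W shape")
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_shape("`frames` must be a T x H x W array or list of matrices")
  n <- dim(frames)[1L]
  if (n < 2L) stop_shape("need at least 2 frames, got ", n)
  d <- abs(frames[-1L, , , drop = FALSE] - frames[-n, , , drop = FALSE])
  mi <- as.integer(rowSums(d >= threshold, dims = 1L))
  structure(mi, class = "mi_trace", frame_rate = frame_rate, well_id = well_id)
}

#' Min-max normalize a trace to [0, 1]
#'
#' Rescales MI values by fixed dataset-wide bounds. The bounds are a property
#' of the dataset (conventionally 0 and 6750 MI units) and are frozen into a
#' trained model's configuration so that training and inference see the same
#' scale. Values outside `[lo, hi]` are clipped.
#'
#' @param x numeric vector or matrix (rows = traces) of MI values.
#' @param lo,hi normalization bounds in MI units, `hi > lo`.
#' @return `x` mapped through `(x - lo) / (hi - lo)` and clipped to `[0, 1]`.
#' @examples
#' normalize_trace(c(0, 3375, 6750), 0, 6750)  # 0, 0.5, 1
#' @export
normalize_trace <- function(x, lo = 0, hi = 6750) {
  if (!(is.numeric(lo) && is.numeric(hi)) || hi <= lo)
    stop_param("normalization bounds need hi > lo; got lo = ", lo, ", hi = ", hi)
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Subsample a trace at a fixed stride
#'
#' Keeps indices `1, 1 + stride, 1 + 2*stride, ...`; the output length is
#' `ceiling(length(x) / stride)`. Stride-5 subsampling of the canonical
#' 101,250-frame trace yields the 20,250-point model input.
#'
#' @param x numeric vector, or a matrix whose rows are traces.
#' @param stride positive integer step.
#' @return the subsampled vector/matrix.
#' @examples
#' subsample_trace(0:9, 3)  # 0 3 6 9
#' @export
subsample_trace <- function(x, stride = 5) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 || stride != floor(stride))
    stop_param("`stride` must be a positive integer, got ", stride)
  if (is.matrix(x)) {
    x[, seq(1L, ncol(x), by = stride), drop = FALSE]
  } else {
    x[seq(1L, length(x), by = stride)]
  }
}

# Unit-sum Hanning kernel of odd length `window`.
hanning_kernel <- function(window) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / (window - 1))
  w / sum(w)
}

#' Hanning smoothing of a trace
#'
#' Convolves the trace with a unit-sum Hanning window, suppressing
#' high-frequency content while preserving the slow stimulus-locked
#' structure. Edges use reflection padding so the output length equals the
#' input length. A window of 11 frames is the conventional setting for
#' ablating high-frequency components in shortcut-learning diagnostics.
#'
#' @param x numeric vector, or a matrix whose rows are traces.
#' @param window odd integer window length, `3 <= window <= length(x)`.
#' @return smoothed trace(s) with the original length.
#' @examples
#' smooth_hanning(rep(5, 20), window = 5)   # constant in, constant out
#' @export
smooth_hanning <- function(x, window = 11) {
  if (is.matrix(x)) return(t(apply(x, 1L, smooth_hanning, window = window)))
  n <- length(x)
  if (!is.numeric(window) || length(window) != 1L || window != floor(window) ||
      window %% 2 == 0 || window < 3 || window > n)
    stop_param("`window` must be odd, >= 3 and <= trace length (", n, "); got ", window)
  k <- hanning_kernel(window)
  h <- (window - 1L) %/% 2L
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  out <- stats::filter(padded, k, method = "convolution", sides = 2L)
  as.numeric(out[(h + 1L):(h + n)])
}
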