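#' Conventional phenotypic distances between traces
#'
#' Baseline metrics for comparing behavioral time series: correlation
#' distance (one minus the Pearson correlation, the canonical profile
#' distance in behavioral screening), plain Euclidean distance, and an
#' approximate dynamic-time-warping distance in the FastDTW family.
#'
#' `correlation_distance()` returns a value in `[0, 2]`; if either trace has
#' zero variance the correlation is undefined and the distance falls back to
#' 1 with a warning.
#'
#' @param a,b numeric traces of equal length (`dtw_distance` permits unequal
#'   lengths).
#' @return a non-negative scalar distance.
#' @seealso [dtw_distance()], [pairwise_distance_matrix()]
#' @examples
#' x <- sin(seq(0, 6, length.out = 50))
#' correlation_distance(x, 3 * x + 7)   # 0: Pearson r is affine-invariant
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_shape("trace lengths differ: ", length(a), " vs ", length(b))
  if (length(a) < 2L) stop_shape("need traces of length >= 2")
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    warning("zero-variance trace: correlation distance undefined, returning 1")
    return(1)
  }
  1 - stats::cor(a, b)
}

#' @rdname correlation_distance
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_shape("trace lengths differ: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

#' Dynamic time warping distance (FastDTW-style)
#'
#' Approximate dynamic-time-warping alignment cost between two traces, using
#' the multilevel FastDTW scheme: the series are recursively coarsened by
#' factor two, the optimal path of the coarse problem is projected back and
#' widened by `radius` cells, and the banded dynamic program is re-solved in
#' that window. `exact = TRUE` (or very short inputs) runs the full dynamic
#' program instead, which is the exact DTW cost. The local cost is the
#' absolute difference and the step pattern is the classic
#' diagonal/up/left with unit weights.
#'
#' @param a,b non-empty numeric traces (lengths may differ).
#' @param radius non-negative integer band refinement radius (default 1, the
#'   common FastDTW default).
#' @param exact if `TRUE`, solve the unrestricted dynamic program.
#' @return the non-negative alignment cost. `dtw_distance(x, x)` is 0, and
#'   the exact cost on equal-length traces never exceeds the unaligned sum of
#'   absolute differences.
#' @examples
#' dtw_distance(c(0, 1, 0), c(0, 0, 1, 0))          # warping absorbs the shift
#' dtw_distance(c(0, 1, 0), c(0, 0, 1, 0), exact = TRUE)
#' @export
dtw_distance <- function(a, b, radius = 1, exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L) stop_data("empty trace")
  if (!is.numeric(radius) || radius < 0 || radius != floor(radius))
    stop_param("`radius` must be a non-negative integer")
  a <- as.numeric(a); b <- as.numeric(b)
  if (exact) return(dtw_full(a, b, want_path = FALSE)$cost)
  fastdtw_rec(a, b, as.integer(radius), want_path = FALSE)$cost
}

dtw_full <- function(a, b, want_path) {
  n <- length(a); m <- length(b)
  .dtw_window(a, b, integer(n), rep(m - 1L, n), want_path)
}

# Multilevel FastDTW recursion; returns list(cost, i, j) with 0-based path.
fastdtw_rec <- function(a, b, radius, want_path = TRUE) {
  min_size <- radius + 2L
  n <- length(a); m <- length(b)
  if (n <= min_size || m <= min_size) return(dtw_full(a, b, want_path = TRUE))
  low <- fastdtw_rec(coarsen_half(a), coarsen_half(b), radius, want_path = TRUE)
  win <- expand_window(low$i, low$j, n, m, radius)
  .dtw_window(a, b, win$lo, win$hi, want_path = TRUE)
}

coarsen_half <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, x[n])
  (x[seq(1L, length(x), 2L)] + x[seq(2L, length(x), 2L)]) / 2
}

# Project a coarse path onto the fine grid and widen by `radius`,
# returning per-row inclusive column bounds (0-based).
expand_window <- function(pi, pj, n, m, radius) {
  lo <- rep.int(m, n)  # sentinel above any valid index
  hi <- rep.int(-1L, n)
  for (k in seq_along(pi)) {
    rows <- (2L * pi[k]):(2L * pi[k] + 1L)
    cmin <- 2L * pj[k] - radius
    cmax <- 2L * pj[k] + 1L + radius
    rows <- rows[rows >= 0L & rows < n]
    for (r in rows + 1L) {
      if (cmin < lo[r]) lo[r] <- cmin
      if (cmax > hi[r]) hi[r] <- cmax
    }
  }
  # radius in the row direction, then clamp and make contiguous/monotone
  if (radius > 0L) {
    lo2 <- lo; hi2 <- hi
    for (r in seq_len(n)) {
      rr <- max(1L, r - radius):min(n, r + radius)
      lo2[r] <- min(lo[rr]); hi2[r] <- max(hi[rr])
    }
    lo <- lo2; hi <- hi2
  }
  lo <- pmax(as.integer(lo), 0L)
  hi <- pmin(as.integer(hi), m - 1L)
  # guarantee row-to-row connectivity (monotone non-decreasing bounds)
  lo <- cummax(lo)
  for (r in (n - 1L):1L) hi[r] <- min(hi[r], hi[r + 1L])
  if (any(lo > hi)) { # degenerate projection; fall back to full rows there
    bad <- lo > hi
    lo[bad] <- 0L; hi[bad] <- m - 1L
  }
  list(lo = lo, hi = hi)
}

#' Pairwise distance matrix under an arbitrary metric
#'
#' Assembles a labeled symmetric distance matrix over traces or embeddings,
#' evaluating `metric` once per unordered pair, or a rectangular query-by-
#' library cross matrix when `Y` is supplied.
#'
#' @param X numeric matrix, rows = entities (traces or embedding vectors).
#' @param metric a function of two vectors returning a non-negative finite
#'   scalar, e.g. [correlation_distance()].
#' @param ids row labels; defaults to `rownames(X)` or `1..n`.
#' @param Y optional second matrix for a rectangular `nrow(X) x nrow(Y)`
#'   cross matrix (e.g. query set versus library).
#' @param ids_y labels for `Y` rows.
#' @return a numeric matrix with `dimnames`; square mode is symmetric with a
#'   zero diagonal and carries class `"distance_matrix"` plus a `metric`
#'   attribute.
#' @examples
#' X <- rbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
#' pairwise_distance_matrix(X, euclidean_distance)
#' @export
pairwise_distance_matrix <- function(X, metric, ids = NULL, Y = NULL, ids_y = NULL) {
  X <- as.matrix(X)
  metric_name <- deparse(substitute(metric))[1]
  check <- function(v, i, j) {
    if (!is.finite(v) || v < 0)
      stop_data("metric returned ", v, " for pair (", i, ", ", j, ")")
    v
  }
  if (is.null(Y)) {
    n <- nrow(X)
    if (n < 2L) stop_data("need at least 2 entities")
    ids <- ids %||% rownames(X) %||% as.character(seq_len(n))
    D <- fast_square_distance(X, metric)   # vectorized route where available
    if (is.null(D)) {
      D <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- check(metric(X[i, ], X[j, ]), i, j)
      }
    }
    dimnames(D) <- list(ids, ids)
    structure(D, class = c("distance_matrix", "matrix", "array"), metric = metric_name)
  } else {
    Y <- as.matrix(Y)
    if (nrow(X) < 1L || nrow(Y) < 1L) stop_data("empty query or library")
    ids <- ids %||% rownames(X) %||% as.character(seq_len(nrow(X)))
    ids_y <- ids_y %||% rownames(Y) %||% as.character(seq_len(nrow(Y)))
    D <- matrix(NA_real_, nrow(X), nrow(Y), dimnames = list(ids, ids_y))
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
      D[i, j] <- check(metric(X[i, ], Y[j, ]), i, j)
    }
    attr(D, "metric") <- metric_name
    D
  }
}

# Closed-form all-by-all matrices for the two standard metrics; falls back
# (returns NULL) for any other callable. Zero-variance rows take
# correlation distance 1 against everything, matching the scalar fallback.
fast_square_distance <- function(X, metric) {
  if (identical(metric, euclidean_distance)) {
    return(as.matrix(stats::dist(X)))
  }
  if (identical(metric, correlation_distance)) {
    sds <- apply(X, 1L, stats::sd)
    D <- matrix(1, nrow(X), nrow(X))
    ok <- sds > 0
    if (any(!ok)) warning("zero-variance trace(s): correlation distance set to 1")
    if (sum(ok) >= 2L) D[ok, ok] <- 1 - stats::cor(t(X[ok, , drop = FALSE]))
    diag(D) <- 0
    return(D)
  }
  NULL
}
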