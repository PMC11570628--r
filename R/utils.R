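# Internal helpers shared across modules.

# Run `expr` under a private, seeded RNG stream without disturbing the
# caller's RNG state. All stochastic operations in the package route their
# `seed` arguments through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a label, so that independent
# sub-draws (per plate, per drug, per class) are decoupled but reproducible.
# Kept below 2^31 - 1 at all times.
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utils::head(charToRaw(digest_chars(parts)), 4L)
  val <- sum(as.integer(bytes) * 256^(0:3))
  as.integer(val %% .Machine$integer.max)
}

# Tiny string hash (FNV-1a, 32-bit) -- avoids an external digest dependency.
digest_chars <- function(x) {
  h <- 2166136261
  for (b in as.integer(charToRaw(x))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  # spread to 8 chars
  paste0(
    rawToChar(as.raw(65 + (h %% 26))),
    formatC(as.integer(h), width = 10, flag = "0")
  )
}

#' Convert between alphanumeric and numeric well names
#'
#' Plate wells are stored internally with 0-based `row`/`col` indices.
#' `well_name()` renders them in the conventional "B03" style (row letter,
#' 1-based two-digit column); `parse_well_name()` inverts it.
#'
#' @param row,col 0-based integer indices.
#' @param name character vector of names such as `"B03"` or `"H12"`.
#' @return `well_name()`: character vector; `parse_well_name()`: a data.frame
#'   with 0-based `row` and `col` columns.
#' @examples
#' well_name(1, 2)            # "B03"
#' parse_well_name("B03")     # row 1, col 2
#' @export
well_name <- function(row, col) {
  stopifnot(all(row >= 0), all(col >= 0))
  paste0(LETTERS[row + 1L], formatC(col + 1L, width = 2, flag = "0"))
}

#' @rdname well_name
#' @export
parse_well_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z])([0-9]+)$", name))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable well name(s): ", paste(name[bad], collapse = ", "))
  data.frame(
    row = match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L,
    col = as.integer(vapply(m, `[`, "", 3L)) - 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_shape <- function(...) stop(structure(
  class = c("twinphen_shape_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))
))

stop_param <- function(...) stop(structure(
  class = c("twinphen_param_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))
))

stop_data <- function(...) stop(structure(
  class = c("twinphen_data_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))
))
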