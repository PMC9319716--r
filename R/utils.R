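#' Derive a reproducible sub-seed from a master seed and string tokens
#'
#' All randomness in the package flows from one integer master seed; per
#' limb/session/stage substreams are derived by hashing identifying tokens
#' into the 31-bit seed space, so adding a participant never reshuffles the
#' streams of the others.
#'
#' @param seed integer master seed.
#' @param ... character or numeric tokens identifying the substream
#'   (e.g. participant id, limb, session).
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(1, "P01", "L", 2)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# internal: scalar checks with uniform error text
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# internal: clamp a numeric vector
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# internal: row-wise maximum of a matrix (no matrixStats dependency)
row_max <- function(m) {
  if (ncol(m) == 1L) return(as.vector(m))
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
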