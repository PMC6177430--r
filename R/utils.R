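# internal helpers

deg2rad <- function(deg) deg * pi / 180

#' Decibel ratio of two amplitudes
#'
#' @param a numeric, numerator amplitude(s); must be non-negative.
#' @param b numeric, reference amplitude; must be strictly positive.
#' @return `20 * log10(a / b)` in dB. Values of `a` equal to zero return
#'   `-Inf` (a floor-flagged level); see [component_amplitude()] for the
#'   numerical-floor convention used on spectra.
#' @examples
#' db_ratio(1, 1)      # 0 dB
#' db_ratio(10, 1)     # 20 dB
#' db_ratio(0.5, 1)    # about -6.02 dB
#' @export
db_ratio <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(b)))
  if (any(b <= 0)) stop("db_ratio(): reference amplitude 'b' must be > 0")
  if (any(a < 0, na.rm = TRUE)) stop("db_ratio(): amplitudes must be >= 0")
  20 * log10(a / b)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministically derive a child seed from a master seed and a label,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_if_not_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
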