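#' Circular distance between hue indices
#'
#' The colour space is a circle of `n_hues` equally discriminable hues
#' (adjacent indices differ by roughly one just-noticeable difference, JND),
#' so index `0` is adjacent to index `n_hues - 1` and the largest possible
#' distance is `n_hues / 2`.
#'
#' @param a,b Hue indices in `[0, n_hues)`. Vectorised; recycled against each
#'   other.
#' @param n_hues Number of hues on the circle (default 48).
#' @return Numeric vector of circular distances in JND, in `[0, n_hues / 2]`.
#' @examples
#' circular_distance(5, 5)       # 0
#' circular_distance(0, 24)      # 24, antipodal
#' circular_distance(46, 2)      # 4, wraps around
#' @export
circular_distance <- function(a, b, n_hues = 48) {
  if (!is.numeric(n_hues) || length(n_hues) != 1L || n_hues < 2)
    stop("`n_hues` must be a single number >= 2", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("hue indices must be finite", call. = FALSE)
  if (any(a < 0 | a >= n_hues) || any(b < 0 | b >= n_hues))
    stop("hue indices must lie in [0, n_hues)", call. = FALSE)
  d <- abs(a - b)
  pmin(d, n_hues - d)
}

# wrap arbitrary integers onto the hue circle [0, n_hues)
wrap_hue <- function(h, n_hues) {
  ((h %% n_hues) + n_hues) %% n_hues
}
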