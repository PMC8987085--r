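#' Centered moving average with truncated, renormalized windows
#'
#' Uniform averaging kernel over a centered window. At the profile edges the
#' window is truncated and renormalized by its actual width, so constant
#' inputs are preserved exactly. For an even window the extra position is
#' taken on the left (`floor(w/2)` left, `w - 1 - floor(w/2)` right).
#'
#' @param x numeric vector
#' @param window window width in positions (default 21)
#' @return numeric vector of the same length
#' @export
movingAverage <- function(x, window = 21L) {
  n <- length(x)
  stopifnot(is.numeric(x), window >= 1)
  if (n == 0L) return(x)
  left <- window %/% 2L
  right <- window - 1L - left
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min-max rescaling to [0, 1]
#'
#' Constant vectors (zero range) map to all zeros.
#'
#' @param x numeric vector or matrix
#' @return rescaled object of the same shape
#' @export
minMaxScale <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# scale a non-negative vector to unit sum; all-zero stays zero
.normalizeSum <- function(x) {
  s <- sum(x)
  if (s > 0) x / s else x
}

# window of up-to-`window` positions centered at p: floor(window/2) to the
# left of p, window - 1 - floor(window/2) to the right, clipped to [1, n]
.centeredWindow <- function(p, n, window) {
  left <- window %/% 2L
  right <- window - 1L - left
  seq.int(max(1L, p - left), min(n, p + right))
}

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  x
}

# read a 2+ column TSV with no header requirement; tolerates gz
.readTable <- function(path, header = FALSE, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "", check.names = FALSE, ...)
}
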