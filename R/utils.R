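#' @importFrom rlang %||% abort warn .data
#' @importFrom stats density median quantile sd setNames approx fft nextn
#' @importFrom utils head tail
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# stop with class "focimetry_error" so callers can test errors precisely
fm_abort <- function(msg, class = "focimetry_error") {
  rlang::abort(msg, class = class)
}

fm_assert <- function(cond, msg) {
  if (!isTRUE(cond)) fm_abort(msg)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' One-dimensional Otsu threshold
#'
#' Threshold a numeric vector by exhaustive minimisation of intra-class
#' variance over a fixed histogram, as used for the EdU positive/negative
#' split (on log-transformed intensities) and anywhere a bimodal 1-D split
#' is needed.
#'
#' @param x numeric vector (non-finite values dropped).
#' @param n_bins number of histogram bins.
#' @return the threshold value; values strictly greater are "positive".
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  fm_assert(length(x) >= 2L, "need at least two finite values for a threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# mean-preserving multiplicative log-normal noise factors for a given CV
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

# linear-interpolated first crossing of `level` by y(t) in the given direction,
# optionally only after time `after`. Returns NA_real_ when never crossed.
first_crossing <- function(t, y, level, direction = c("up", "down"), after = -Inf) {
  direction <- match.arg(direction)
  fm_assert(length(t) == length(y) && !is.unsorted(t, strictly = TRUE),
            "time points must be strictly increasing and match y")
  for (i in seq_along(t)[-1]) {
    if (t[i] <= after) next
    y0 <- y[i - 1L]; y1 <- y[i]
    hit <- if (direction == "up") y0 < level && y1 >= level else y0 > level && y1 <= level
    if (isTRUE(hit)) {
      return(t[i - 1L] + (level - y0) / (y1 - y0) * (t[i] - t[i - 1L]))
    }
  }
  # level already satisfied at the first usable point
  usable <- which(t > after)
  if (length(usable)) {
    y0 <- y[usable[1]]
    if ((direction == "up" && y0 >= level) || (direction == "down" && y0 <= level)) {
      return(t[usable[1]])
    }
  }
  NA_real_
}

# stable content hash used for provenance stamping (rlang ships with the
# tidyverse; hash is xxHash-based and platform stable)
config_hash <- function(x) rlang::hash(x)
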