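#' Generate two-channel localization patterns with a planted shared fraction
#'
#' Plants `floor(f_coloc * min(n_r, n_g))` shared molecular positions,
#' sampled uniformly in a `domain_nm` square. The red channel sees them
#' exactly; the green channel sees them displaced by an isotropic Gaussian
#' jitter of root-mean-square radius `jitter_nm` (per-axis SD
#' `jitter_nm / sqrt(2)`), modelling chromatic registration error and linker
#' length. Remaining molecules in each channel are independent uniform
#' positions (complete spatial randomness), so `f_coloc = 0` is a pure CSR
#' null. Localization precision is stored per molecule for
#' precision-weighted rendering.
#'
#' @param n_r,n_g molecules per channel.
#' @param f_coloc planted colocalised fraction in [0, 1], relative to the
#'   smaller channel.
#' @param domain_nm side of the square field.
#' @param jitter_nm RMS displacement of shared positions in the green
#'   channel.
#' @param precision_nm localization precision written to the tables.
#' @param seed RNG seed.
#' @return list of class `smlm_pattern`: `red`, `green` (localization
#'   tibbles with `x_nm`, `y_nm`, `precision_nm`, `photons`, `frame`,
#'   `channel`), `truth` (shared-position table with the row indices of each
#'   channel and the planted fraction), and the generating parameters.
#' @export
synth_localization_patterns <- function(n_r = 2000, n_g = 2000, f_coloc = 0.5,
                                        domain_nm = 5000, jitter_nm = 0,
                                        precision_nm = 20, seed = 1L) {
  fm_assert(f_coloc >= 0 && f_coloc <= 1, "f_coloc must be in [0, 1]")
  fm_assert(domain_nm >= 10 * precision_nm,
            "domain too small relative to the localization precision")
  set.seed(seed)
  n_c <- floor(f_coloc * min(n_r, n_g))

  shared_x <- stats::runif(n_c, 0, domain_nm)
  shared_y <- stats::runif(n_c, 0, domain_nm)
  jit_sd <- jitter_nm / sqrt(2)

  make_table <- function(x, y) {
    n <- length(x)
    tibble::tibble(x_nm = x, y_nm = y,
                   precision_nm = rep(precision_nm, n),
                   photons = rep(1000, n),
                   frame = seq_len(n), channel = "0")
  }

  red <- make_table(c(shared_x, stats::runif(n_r - n_c, 0, domain_nm)),
                    c(shared_y, stats::runif(n_r - n_c, 0, domain_nm)))
  green <- make_table(c(shared_x + stats::rnorm(n_c, 0, jit_sd),
                        stats::runif(n_g - n_c, 0, domain_nm)),
                      c(shared_y + stats::rnorm(n_c, 0, jit_sd),
                        stats::runif(n_g - n_c, 0, domain_nm)))
  red$channel <- "1"
  green$channel <- "2"

  structure(list(red = red, green = green,
                 truth = tibble::tibble(shared = seq_len(n_c),
                                        red_row = seq_len(n_c),
                                        green_row = seq_len(n_c),
                                        x_nm = shared_x, y_nm = shared_y),
                 f_coloc = f_coloc, n_shared = n_c, domain_nm = domain_nm,
                 jitter_nm = jitter_nm, precision_nm = precision_nm,
                 seed = seed),
            class = "smlm_pattern")
}
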