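#' Match tolerance for an observed haplogroup frequency
#'
#' A simulated sample frequency is accepted as matching an observed one when
#' it lies within two standard errors of it.  The default (`variant =
#' "halved"`) evaluates `2 * sqrt(p * (1 - p) / (2 * n))`, i.e. the binomial
#' standard error with a halved variance argument; `variant = "classic"`
#' uses the textbook binomial standard error `2 * sqrt(p * (1 - p) / n)`
#' for sensitivity analysis.
#'
#' @param p observed frequency in `[0, 1]` (zero-adjust first with
#'   [zero_adjust()] when the observed count is 0).
#' @param n sample size, `>= 1`.
#' @param variant `"halved"` (default) or `"classic"`; see Details.
#' @return The tolerance (dimensionless, same scale as `p`).
#' @examples
#' tolerance(0.5, 50)        # 0.1
#' tolerance(0.13, 957)      # ~0.0154
#' @export
tolerance <- function(p, n, variant = c("halved", "classic")) {
  variant <- match.arg(variant)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  denom <- if (variant == "halved") 2 * n else n
  2 * sqrt(p * (1 - p) / denom)
}

#' Zero-frequency adjustment
#'
#' An observed frequency of exactly 0 gives a zero standard error, so no
#' simulated sample could ever match within tolerance.  The pseudo-count
#' adjustment replaces it by `1 / (n + 1)`; positive observed counts are
#' returned as `carriers / n` unchanged.
#'
#' @param carriers observed carrier count, `0 <= carriers <= n`.
#' @param n sample size.
#' @return Adjusted frequency.
#' @examples
#' zero_adjust(0, 2677)   # 1/2678
#' zero_adjust(4, 95)     # 4/95
#' @export
zero_adjust <- function(carriers, n) {
  if (any(carriers < 0) || any(carriers > n)) {
    stop("`carriers` must lie in [0, n]", call. = FALSE)
  }
  ifelse(carriers > 0, carriers / n, 1 / (n + 1))
}

#' Construct an observed population sample
#'
#' Bundles a population label, sample size and carrier count with the
#' derived quantities used by the match rule: the raw frequency `p`, the
#' zero-adjusted frequency `p_adjusted` and the match tolerance `tol`.
#'
#' @param label population (pool) label.
#' @param n sample size, `>= 1`.
#' @param carriers observed carrier count, `0 <= carriers <= n`.
#' @param tolerance_variant passed to [tolerance()].
#' @return An object of class `"observed_population"`.
#' @examples
#' observed_population("Indo-European", 2677, 0)
#' @export
observed_population <- function(label, n, carriers,
                                tolerance_variant = c("halved", "classic")) {
  tolerance_variant <- match.arg(tolerance_variant)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single value >= 1", call. = FALSE)
  }
  if (!is.numeric(carriers) || length(carriers) != 1L || is.na(carriers) ||
      carriers < 0 || carriers > n) {
    stop("`carriers` must be a single value in [0, n]", call. = FALSE)
  }
  n <- as.integer(round(n))
  carriers <- as.integer(round(carriers))
  p <- carriers / n
  p_adj <- zero_adjust(carriers, n)
  tol <- tolerance(p_adj, n, tolerance_variant)
  if (tol == 0) {
    warning(sprintf(
      "population '%s' has zero tolerance (p = %g); only exact matches are possible",
      label, p), call. = FALSE)
  }
  structure(
    list(label = label, n = n, carriers = carriers, p = p,
         p_adjusted = p_adj, tol = tol,
         tolerance_variant = tolerance_variant),
    class = "observed_population"
  )
}

#' @export
print.observed_population <- function(x, ...) {
  cat(sprintf("<observed_population> %s: %d/%d carriers (p = %.4g, adjusted %.4g, tol %.4g)\n",
              x$label, x$carriers, x$n, x$p, x$p_adjusted, x$tol))
  invisible(x)
}

#' Does a simulated sample frequency match an observed population?
#'
#' `TRUE` iff `|sim_freq - p_adjusted| <= tol` (closed interval).
#'
#' @param sim_freq simulated sample frequency (vectorised).
#' @param obs an [observed_population()].
#' @return Logical vector the length of `sim_freq`.
#' @export
matches <- function(sim_freq, obs) {
  stopifnot(inherits(obs, "observed_population"))
  abs(sim_freq - obs$p_adjusted) <= obs$tol
}

#' Default observed populations
#'
#' The three pooled samples the demographic models target by default:
#' Indo-European neighbours of the Hungarian Seklers (0 carriers of 2677,
#' zero-adjusted), Hungarian Seklers (4 of 95, about 4%), and Southern
#' Ural/West Siberian populations (124 of 957, about 13%).
#'
#' @inheritParams observed_population
#' @return Named list of three `observed_population` objects
#'   (`indo_european`, `sekler`, `ural_siberian`).
#' @export
default_observed <- function(tolerance_variant = c("halved", "classic")) {
  tolerance_variant <- match.arg(tolerance_variant)
  list(
    indo_european = observed_population("Indo-European", 2677, 0,
                                        tolerance_variant),
    sekler        = observed_population("Hungarian Sekler", 95, 4,
                                        tolerance_variant),
    ural_siberian = observed_population("Ural-Siberian", 957, 124,
                                        tolerance_variant)
  )
}
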