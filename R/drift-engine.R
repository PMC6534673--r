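#' Construct a population state
#'
#' A population is described by its carrier frequency for the focal
#' haplogroup (the "1" allele; every other haplogroup is the "0" allele) and
#' its haploid effective size `N`, the number of transmitting Y-chromosome
#' lineages.  For the Y chromosome each individual carries one haplotype, so
#' `N` individuals and `N` haplotypes coincide.
#'
#' @param label character population label.
#' @param freq carrier frequency in `[0, 1]`.
#' @param size haploid effective population size (default 5000); constant
#'   over a simulation.
#' @return An object of class `"wf_population"`: a list with elements
#'   `label`, `freq`, `size` and the integral allele `count = freq * size`.
#' @examples
#' wf_population("Ural-Siberian", freq = 0.13)
#' @export
wf_population <- function(label, freq, size = 5000) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(freq) || length(freq) != 1L || is.na(freq) ||
      freq < 0 || freq > 1) {
    stop("`freq` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(size) || length(size) != 1L || is.na(size) || size < 1) {
    stop("`size` must be a single value >= 1", call. = FALSE)
  }
  size <- as.integer(round(size))
  structure(
    list(label = label, freq = freq, size = size,
         count = as.integer(round(freq * size))),
    class = "wf_population"
  )
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> %s: freq %.6g (%d/%d haplotypes)\n",
              x$label, x$freq, x$count, x$size))
  invisible(x)
}

# Vectorised Wright-Fisher kernel on allele counts: one generation is a
# binomial resampling of N haplotypes with replacement at the current
# frequency.  `counts` is an integer vector (one entry per replicate).
wf_generation_counts <- function(counts, N) {
  stats::rbinom(length(counts), N, counts / N)
}

# Drift `counts` forward `generations` generations.  Frequencies 0 and 1 are
# absorbing (rbinom with p = 0 or 1 is degenerate), so no special-casing is
# needed for correctness.
wf_drift_counts <- function(counts, N, generations) {
  for (g in seq_len(generations)) {
    counts <- stats::rbinom(length(counts), N, counts / N)
  }
  counts
}

# Literal with-replacement resampling of N haplotype labels; distributionally
# identical to the binomial kernel.  Kept as an independent oracle for tests
# (scalar, slow on purpose).
wf_generation_literal <- function(count, N) {
  pool <- c(rep(1L, count), rep(0L, N - count))
  sum(sample(pool, N, replace = TRUE))
}

#' One generation of Wright-Fisher drift
#'
#' Resamples the population: the next generation's carrier count is a
#' binomial draw of size `N` at the current frequency, which is
#' distributionally identical to drawing `N` haplotypes with replacement
#' from the current gene pool.
#'
#' @param state a [wf_population()] object.
#' @return A new `wf_population` with the post-drift frequency; the input is
#'   unmodified.  The returned frequency is always an integer multiple of
#'   `1/size`.
#' @seealso [drift_trajectory()] for multi-generation drift.
#' @export
drift_step <- function(state) {
  stopifnot(inherits(state, "wf_population"))
  if (state$freq < 0 || state$freq > 1) {
    stop("frequency outside [0, 1]", call. = FALSE)
  }
  count <- wf_generation_counts(state$count, state$size)
  state$count <- count
  state$freq <- count / state$size
  state
}

#' Drift a population forward in time
#'
#' Applies [drift_step()] `generations` times.  `generations = 0` returns
#' the input unchanged.  Drift is mean-preserving (a martingale); after `t`
#' generations the frequency variance is
#' `p0 * (1 - p0) * (1 - (1 - 1/N)^t)`.
#'
#' @inheritParams drift_step
#' @param generations non-negative integer number of generations.
#' @param keep if `TRUE`, attach the full frequency trajectory as a
#'   data frame (`generation`, `freq`) in attribute `"trajectory"`.
#' @return The final `wf_population`.
#' @export
drift_trajectory <- function(state, generations, keep = FALSE) {
  stopifnot(inherits(state, "wf_population"))
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 0) {
    stop("`generations` must be a single non-negative integer", call. = FALSE)
  }
  generations <- as.integer(generations)
  N <- state$size
  count <- state$count
  traj <- if (keep) integer(generations + 1L) else NULL
  if (keep) traj[1L] <- count
  for (g in seq_len(generations)) {
    # short-circuit at absorbing states: the remaining trajectory is constant
    if (count == 0L || count == N) {
      if (keep) traj[(g + 1L):(generations + 1L)] <- count
      break
    }
    count <- wf_generation_counts(count, N)
    if (keep) traj[g + 1L] <- count
  }
  state$count <- count
  state$freq <- count / N
  if (keep) {
    attr(state, "trajectory") <- data.frame(
      generation = 0:generations, freq = traj / N
    )
  }
  state
}

#' Apply a single admixture pulse
#'
#' Moves a proportion `alpha` of the recipient's gene pool: the recipient
#' frequency becomes `(1 - alpha) * p_recipient + alpha * p_source`, rounded
#' to the nearest multiple of `1/N` so the subsequent drift generation
#' operates on an integral allele count.  The source population is left
#' unchanged (a replacement pulse under constant population sizes).
#'
#' @param recipient,source [wf_population()] objects.
#' @param alpha admixture proportion in `[0, 1]`.
#' @return The post-pulse recipient as a `wf_population`.
#' @export
admix <- function(recipient, source, alpha) {
  stopifnot(inherits(recipient, "wf_population"),
            inherits(source, "wf_population"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  if (identical(recipient$label, source$label)) {
    stop("source and recipient must be distinct populations", call. = FALSE)
  }
  mixed <- (1 - alpha) * recipient$freq + alpha * source$freq
  recipient$count <- as.integer(round(mixed * recipient$size))
  recipient$freq <- recipient$count / recipient$size
  recipient
}

#' Draw an observed sample from a population
#'
#' Final-generation sampling: the number of carriers among `n` sampled men
#' is a binomial draw at the population frequency.
#'
#' @inheritParams drift_step
#' @param n sample size (number of men sampled), `>= 1`.
#' @return A list with `count` (sampled carrier count) and `freq`
#'   (`count / n`).
#' @export
sample_carriers <- function(state, n) {
  stopifnot(inherits(state, "wf_population"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single value >= 1", call. = FALSE)
  }
  n <- as.integer(round(n))
  count <- stats::rbinom(1L, n, state$freq)
  list(count = count, freq = count / n)
}

#' Write a drift trajectory as tab-separated text
#'
#' @param state a `wf_population` returned by
#'   `drift_trajectory(..., keep = TRUE)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(state, path) {
  traj <- attr(state, "trajectory")
  if (is.null(traj)) {
    stop("no trajectory attached; run drift_trajectory(..., keep = TRUE)",
         call. = FALSE)
  }
  out <- data.frame(generation = traj$generation,
                    population = state$label, freq = traj$freq)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
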