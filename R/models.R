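## Model framework: conditioned-simulation blocks for Models A/B, the
## 100 x 100 replication protocol, and Model C rejection sampling.
##
## All kernels are vectorised over simulation attempts; conditioning is
## applied as a sequential filter (source / Ural-Siberian sample first,
## recipients only for surviving attempts), which is distributionally
## identical to simulating every population for every attempt because the
## populations drift independently given the source frequency at the pulse.

runif_prior <- function(b, range) stats::runif(b, range[1], range[2])

# One vectorised batch of Model A attempts.  Three populations share one
# uniform starting frequency and drift independently for the full horizon.
# Returns logical vectors `cond` (Ural-Siberian sample matches) and
# `success` (Sekler and Indo-European samples also match; FALSE where not
# conditioned).
batch_model_a <- function(b, cfg) {
  obs <- cfg$observed
  p0 <- runif_prior(b, cfg$priors$p0)
  start <- as.integer(round(p0 * cfg$N))
  sib <- wf_drift_counts(start, cfg$N, cfg$total_generations)
  sib_samp <- stats::rbinom(b, obs$ural_siberian$n, sib / cfg$N)
  cond <- matches(sib_samp / obs$ural_siberian$n, obs$ural_siberian)
  success <- logical(b)
  idx <- which(cond)
  if (length(idx)) {
    hun <- wf_drift_counts(start[idx], cfg$N, cfg$total_generations)
    ie <- wf_drift_counts(start[idx], cfg$N, cfg$total_generations)
    hun_samp <- stats::rbinom(length(idx), obs$sekler$n, hun / cfg$N)
    ie_samp <- stats::rbinom(length(idx), obs$indo_european$n, ie / cfg$N)
    success[idx] <- matches(hun_samp / obs$sekler$n, obs$sekler) &
      matches(ie_samp / obs$indo_european$n, obs$indo_european)
  }
  list(cond = cond, success = success)
}

# One vectorised batch of Model B attempts.  The source drifts from a
# uniform start, both recipients begin carrier-free and receive one shared
# pulse, then everything drifts to the present.  Conditioning is the
# Ural-Siberian AND Sekler match; success is the Indo-European match.
batch_model_b <- function(b, cfg) {
  obs <- cfg$observed
  p0 <- runif_prior(b, cfg$priors$p0)
  alpha <- runif_prior(b, cfg$priors$alpha)
  src_pulse <- wf_drift_counts(as.integer(round(p0 * cfg$N)), cfg$N,
                               cfg$pre_admixture_generations)
  post <- cfg$admixture_generation
  src_fin <- wf_drift_counts(src_pulse, cfg$N, post)
  sib_samp <- stats::rbinom(b, obs$ural_siberian$n, src_fin / cfg$N)
  m_sib <- matches(sib_samp / obs$ural_siberian$n, obs$ural_siberian)
  cond <- logical(b)
  success <- logical(b)
  i1 <- which(m_sib)
  if (length(i1)) {
    # recipients start at 0, so the post-pulse count is round(alpha * src)
    hun0 <- as.integer(round(alpha[i1] * src_pulse[i1]))
    hun <- wf_drift_counts(hun0, cfg$N, post)
    hun_samp <- stats::rbinom(length(i1), obs$sekler$n, hun / cfg$N)
    m_hun <- matches(hun_samp / obs$sekler$n, obs$sekler)
    i2 <- i1[m_hun]
    cond[i2] <- TRUE
    if (length(i2)) {
      ie0 <- as.integer(round(alpha[i2] * src_pulse[i2]))
      ie <- wf_drift_counts(ie0, cfg$N, post)
      ie_samp <- stats::rbinom(length(i2), obs$indo_european$n, ie / cfg$N)
      success[i2] <- matches(ie_samp / obs$indo_european$n,
                             obs$indo_european)
    }
  }
  list(cond = cond, success = success)
}

#' Run one block of conditioned simulations
#'
#' Repeatedly simulates the configured model until `sims_per_block`
#' conditioned simulations have been collected, and counts how many of them
#' are successes.  See [model_config()] for the conditioning and success
#' criteria of Models A and B; Model C has no block protocol (use
#' [fit_admixture_abc()]).
#'
#' @param cfg a [model_config()] with `model` `"A"` or `"B"`.
#' @param batch_size attempts simulated per vectorised batch.
#' @return A list of class `"block_result"`: `successes`,
#'   `conditioned_sims`, `raw_attempts`, `success_rate` (proportion).
#' @export
run_model_block <- function(cfg, batch_size = 8192L) {
  stopifnot(inherits(cfg, "model_config"))
  batch_fn <- switch(cfg$model,
    A = batch_model_a,
    B = batch_model_b,
    stop("run_model_block() is defined for Models A and B only", call. = FALSE)
  )
  needed <- cfg$sims_per_block
  collected <- 0L
  successes <- 0L
  raw_attempts <- 0
  while (collected < needed) {
    res <- batch_fn(batch_size, cfg)
    hits <- which(res$cond)
    take <- needed - collected
    if (length(hits) >= take) {
      # count attempts only up to the one that fills the block
      cut <- hits[take]
      hits <- hits[seq_len(take)]
      raw_attempts <- raw_attempts + cut
    } else {
      raw_attempts <- raw_attempts + batch_size
    }
    collected <- collected + length(hits)
    successes <- successes + sum(res$success[hits])
    if (collected < needed &&
        raw_attempts / max(1L, collected) > cfg$max_attempts) {
      stop(sprintf(
        paste0("conditioning too rare for Model %s: %d conditioned ",
               "simulations in %.3g raw attempts (acceptance %.3g); ",
               "raise `max_attempts` or revisit the configuration"),
        cfg$model, collected, raw_attempts,
        collected / raw_attempts), call. = FALSE)
    }
  }
  structure(
    list(successes = successes, conditioned_sims = needed,
         raw_attempts = raw_attempts,
         success_rate = successes / needed),
    class = "block_result"
  )
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result> %d/%d successes (%.2f%%), %g raw attempts\n",
              x$successes, x$conditioned_sims, 100 * x$success_rate,
              x$raw_attempts))
  invisible(x)
}

#' Replicate the per-block success rate of a demographic model
#'
#' Runs `blocks` independent blocks of `sims_per_block` conditioned
#' simulations each (defaults 100 x 100, i.e. 10,000 conditioned
#' simulations) and summarises the per-block success rates by their mean
#' and sample standard deviation, expressed as percentages.  This is the
#' model-comparison statistic: a model whose conditioned simulations rarely
#' reproduce the remaining observed samples is rejected.
#'
#' @param cfg a [model_config()] with `model` `"A"` or `"B"`.
#' @param seed optional integer seed for reproducibility.
#' @param verbose print per-block progress (block index, successes,
#'   raw attempts) as messages.
#' @return An object of class `"drift_replication"`: a list with `model`,
#'   `blocks` (a data frame with one row per block: `block`, `successes`,
#'   `conditioned_sims`, `raw_attempts`, `success_rate_pct`),
#'   `mean_success_pct`, `sd_success_pct`, and the `config`.
#' @examples
#' cfg <- model_config("A", blocks = 2, sims_per_block = 5)
#' replicate_success_rate(cfg, seed = 1)
#' @export
replicate_success_rate <- function(cfg, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", cfg$blocks)
  for (b in seq_len(cfg$blocks)) {
    blk <- run_model_block(cfg)
    rows[[b]] <- data.frame(
      block = b, successes = blk$successes,
      conditioned_sims = blk$conditioned_sims,
      raw_attempts = blk$raw_attempts,
      success_rate_pct = 100 * blk$success_rate
    )
    if (verbose) {
      message(sprintf("block %d/%d: %d/%d successes, %g raw attempts",
                      b, cfg$blocks, blk$successes, blk$conditioned_sims,
                      blk$raw_attempts))
    }
  }
  blocks <- do.call(rbind, rows)
  sd_pct <- if (cfg$blocks > 1) stats::sd(blocks$success_rate_pct) else {
    warning("standard deviation undefined for a single block; reporting 0",
            call. = FALSE)
    0
  }
  structure(
    list(model = cfg$model, blocks = blocks,
         mean_success_pct = mean(blocks$success_rate_pct),
         sd_success_pct = sd_pct, config = cfg),
    class = "drift_replication"
  )
}

#' @export
print.drift_replication <- function(x, ...) {
  cat(sprintf(
    "<drift_replication> Model %s: mean success rate %.2f%% (sd %.2f%%) over %d blocks of %d conditioned simulations\n",
    x$model, x$mean_success_pct, x$sd_success_pct, nrow(x$blocks),
    x$config$sims_per_block))
  cat(sprintf("  total raw attempts: %g (conditioning acceptance %.3g)\n",
              sum(x$blocks$raw_attempts),
              sum(x$blocks$conditioned_sims) / sum(x$blocks$raw_attempts)))
  invisible(x)
}

#' @export
summary.drift_replication <- function(object, ...) {
  print(object)
  cat("\nPer-block success rate (%):\n")
  print(summary(object$blocks$success_rate_pct))
  invisible(object)
}

# One vectorised batch of Model C attempts; returns the accepted draws as a
# data frame (possibly with zero rows).
batch_model_c <- function(b, cfg) {
  obs <- cfg$observed
  p0 <- runif_prior(b, cfg$priors$p0)
  a_hun <- runif_prior(b, cfg$priors$alpha_hun)
  a_ie <- runif_prior(b, cfg$priors$alpha_ie)
  src_pulse <- wf_drift_counts(as.integer(round(p0 * cfg$N)), cfg$N,
                               cfg$pre_admixture_generations)
  post <- cfg$admixture_generation
  src_fin <- wf_drift_counts(src_pulse, cfg$N, post)
  sib_samp <- stats::rbinom(b, obs$ural_siberian$n, src_fin / cfg$N)
  i1 <- which(matches(sib_samp / obs$ural_siberian$n, obs$ural_siberian))
  if (!length(i1)) return(NULL)
  hun0 <- as.integer(round(a_hun[i1] * src_pulse[i1]))
  hun <- wf_drift_counts(hun0, cfg$N, post)
  hun_samp <- stats::rbinom(length(i1), obs$sekler$n, hun / cfg$N)
  i2 <- i1[matches(hun_samp / obs$sekler$n, obs$sekler)]
  if (!length(i2)) return(NULL)
  ie0 <- as.integer(round(a_ie[i2] * src_pulse[i2]))
  ie <- wf_drift_counts(ie0, cfg$N, post)
  ie_samp <- stats::rbinom(length(i2), obs$indo_european$n, ie / cfg$N)
  ok <- matches(ie_samp / obs$indo_european$n, obs$indo_european)
  i3 <- i2[ok]
  if (!length(i3)) return(NULL)
  keep2 <- match(i3, i2)   # positions within the Sekler-conditioned subset
  keep1 <- match(i3, i1)
  data.frame(
    p0 = p0[i3],
    alpha_hun = a_hun[i3],
    alpha_ie = a_ie[i3],
    source_final_freq = src_fin[i3] / cfg$N,
    source_sample_freq = sib_samp[i3] / obs$ural_siberian$n,
    sekler_sample_freq = hun_samp[keep1] / obs$sekler$n,
    ie_sample_freq = ie_samp[keep2] / obs$indo_european$n
  )
}

#' Fit the population-specific admixture model by rejection sampling
#'
#' The estimator at the core of the package (Model C).  Parameters -- the
#' starting source carrier frequency `p0` and two independent admixture
#' proportions `alpha_hun` (source into Hungarian Seklers) and `alpha_ie`
#' (source into neighbouring Indo-Europeans) -- are drawn from uniform
#' priors; each draw is simulated forward (source drifts, one pulse into
#' each recipient, drift to the present, binomial sampling at the observed
#' sample sizes) and accepted only when all three simulated samples fall
#' within the match tolerance of the observed ones.  The accepted draws
#' form an approximate posterior (rejection-sampling ABC with a hard
#' acceptance kernel).
#'
#' @param observed list of three [observed_population()] objects (named
#'   `indo_european`, `sekler`, `ural_siberian`); defaults to
#'   [default_observed()].
#' @param n_accepted number of accepted draws to collect (default 1000).
#' @param seed optional integer seed.
#' @param verbose report progress (accepted count, raw acceptance rate).
#' @param batch_size attempts per vectorised batch.
#' @param acceptance_floor abort (with the observed raw acceptance rate in
#'   the error message) if the acceptance rate falls below this after
#'   `2/acceptance_floor` attempts; guards against impossible observations.
#' @param config a full [model_config()] with `model = "C"`; overrides all
#'   other model arguments when supplied.
#' @param ... further arguments passed to [model_config()] (`N`,
#'   `total_generations`, `admixture_generation`,
#'   `pre_admixture_generations`, `priors`, `max_attempts`,
#'   `tolerance_variant`).
#' @return An object of class `"admixture_abc"`: a list with `draws` (one
#'   row per accepted draw: the parameters `p0`, `alpha_hun`, `alpha_ie`,
#'   the final source-population frequency `source_final_freq`, and the
#'   simulated sample frequencies `source_sample_freq`,
#'   `sekler_sample_freq`, `ie_sample_freq`), `raw_attempts`,
#'   `acceptance_rate`, `config`, and `seed`.  Supported methods:
#'   `print`, `summary`, `coef` (posterior means), `confint`, `plot`,
#'   `as.data.frame`.
#' @examples
#' fit <- fit_admixture_abc(n_accepted = 25, seed = 7)
#' coef(fit)
#' @export
fit_admixture_abc <- function(observed = NULL, n_accepted = 1000,
                              seed = NULL, verbose = FALSE,
                              batch_size = 65536L,
                              acceptance_floor = 1e-6,
                              config = NULL, ...) {
  if (is.null(config)) {
    config <- model_config("C", observed = observed,
                           n_accepted = n_accepted, ...)
  }
  stopifnot(inherits(config, "model_config"), config$model == "C")
  n_accepted <- config$n_accepted
  if (!is.null(seed)) set.seed(seed)
  draws <- NULL
  raw_attempts <- 0
  while (is.null(draws) || nrow(draws) < n_accepted) {
    got <- batch_model_c(batch_size, config)
    raw_attempts <- raw_attempts + batch_size
    if (!is.null(got)) draws <- rbind(draws, got)
    n_got <- if (is.null(draws)) 0L else nrow(draws)
    if (verbose) {
      message(sprintf("accepted %d/%d (raw acceptance %.3g)",
                      n_got, n_accepted, n_got / raw_attempts))
    }
    if (n_got < n_accepted) {
      if (raw_attempts >= 2 / acceptance_floor &&
          n_got / raw_attempts < acceptance_floor) {
        stop(sprintf(
          "acceptance rate %.3g below floor %.3g after %.3g attempts; observations may be unreachable under the priors",
          n_got / raw_attempts, acceptance_floor, raw_attempts),
          call. = FALSE)
      }
      if (raw_attempts / max(1L, n_got) > config$max_attempts) {
        stop(sprintf(
          "attempt cap exceeded: %d accepted draws in %.3g raw attempts",
          n_got, raw_attempts), call. = FALSE)
      }
    }
  }
  # trim to exactly n_accepted, preserving acceptance order, and adjust the
  # attempt count to the batch granularity (the trimmed surplus came from
  # the final batch)
  draws <- draws[seq_len(n_accepted), , drop = FALSE]
  rownames(draws) <- NULL
  structure(
    list(draws = draws, raw_attempts = raw_attempts,
         acceptance_rate = n_accepted / raw_attempts,
         config = config, seed = seed),
    class = "admixture_abc"
  )
}

#' Summarise posterior draws
#'
#' Per-parameter arithmetic mean and interval of the accepted draws, on a
#' 0--100 percentage scale.  The default interval is the empirical
#' 2.5th--97.5th percentile; `interval = "minmax"` reports the range of the
#' accepted draws instead.
#'
#' @param draws a data frame of accepted draws (as in the `draws` element
#'   of a [fit_admixture_abc()] fit), or an `"admixture_abc"` object.
#' @param interval `"percentile"` (default) or `"minmax"`.
#' @return A data frame with one row per parameter: `parameter`,
#'   `mean_pct`, `lower_pct`, `upper_pct`.
#' @export
summarize_posterior <- function(draws, interval = c("percentile", "minmax")) {
  interval <- match.arg(interval)
  if (inherits(draws, "admixture_abc")) draws <- draws$draws
  stopifnot(is.data.frame(draws), nrow(draws) >= 1)
  if (nrow(draws) < 2) {
    stop("at least 2 accepted draws are required to summarise an interval",
         call. = FALSE)
  }
  stats_one <- function(x) {
    if (interval == "percentile") {
      q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    } else {
      q <- range(x)
    }
    c(mean = mean(x), lower = q[1], upper = q[2])
  }
  m <- vapply(draws, stats_one, numeric(3))
  data.frame(
    parameter = colnames(m),
    mean_pct = 100 * m["mean", ],
    lower_pct = 100 * m["lower", ],
    upper_pct = 100 * m["upper", ],
    row.names = NULL
  )
}

#' @export
print.admixture_abc <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<admixture_abc> rejection-sampling fit: %d accepted draws, raw acceptance %.3g\n",
    nrow(x$draws), x$acceptance_rate))
  s <- summarize_posterior(x)
  cat("Posterior means (95% percentile interval), %:\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %6.*f  (%.*f - %.*f)\n", s$parameter[i],
                digits - 2, s$mean_pct[i], digits - 2, s$lower_pct[i],
                digits - 2, s$upper_pct[i]))
  }
  invisible(x)
}

#' @export
summary.admixture_abc <- function(object, ...) {
  out <- list(
    n_accepted = nrow(object$draws),
    raw_attempts = object$raw_attempts,
    acceptance_rate = object$acceptance_rate,
    percentile = summarize_posterior(object, "percentile"),
    minmax = summarize_posterior(object, "minmax")
  )
  class(out) <- "summary.admixture_abc"
  out
}

#' @export
print.summary.admixture_abc <- function(x, ...) {
  cat(sprintf("Rejection-sampling admixture fit: %d accepted draws in %g raw attempts (acceptance %.3g)\n\n",
              x$n_accepted, x$raw_attempts, x$acceptance_rate))
  cat("Posterior summaries (%), 2.5-97.5 percentile interval:\n")
  print(x$percentile, row.names = FALSE, digits = 4)
  cat("\nRange of accepted draws (%):\n")
  print(x$minmax, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.admixture_abc <- function(object, ...) {
  colMeans(object$draws)
}

#' @export
confint.admixture_abc <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  m <- t(vapply(object$draws, stats::quantile, numeric(2),
                probs = c(a, 1 - a), names = FALSE))
  colnames(m) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
as.data.frame.admixture_abc <- function(x, ...) {
  x$draws
}

#' @export
plot.admixture_abc <- function(x, which = c("alpha_hun", "alpha_ie",
                                            "source_final_freq"), ...) {
  which <- match.arg(which, choices = names(x$draws), several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  labels <- c(p0 = "starting source frequency",
              alpha_hun = "admixture into Seklers",
              alpha_ie = "admixture into Indo-Europeans",
              source_final_freq = "final source frequency",
              source_sample_freq = "sampled source frequency")
  for (w in which) {
    graphics::hist(x$draws[[w]], breaks = 30, main = labels[[w]],
                   xlab = "posterior draw", col = "grey80", border = "white",
                   ...)
  }
  invisible(x)
}

#' Write accepted draws as tab-separated text
#'
#' One row per accepted draw: parameters, final source-population
#' frequency, and the simulated sample frequencies of the three pools.
#'
#' @param fit an [fit_admixture_abc()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "admixture_abc"))
  utils::write.table(fit$draws, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
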