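#' Demographic model configuration
#'
#' Full specification of one of the three demographic models:
#'
#' * **Model A** (pure drift): three populations diverge from one shared
#'   ancestor whose starting carrier frequency is drawn uniform(0, 1), then
#'   drift independently for `total_generations`.  A simulation is retained
#'   (conditioned) when the Ural-Siberian sample matches; it is a success
#'   when the Indo-European and Sekler samples also match.
#' * **Model B** (shared pulse): the source population starts at a
#'   uniform(0, 1) frequency and drifts for `pre_admixture_generations`;
#'   both recipients start carrier-free; a single pulse with one shared
#'   `alpha ~ uniform(0, 1)` is applied from the source into both
#'   recipients `admixture_generation` generations before present; all
#'   three then drift to the present.  Conditioning: Ural-Siberian and
#'   Sekler samples match.  Success: the Indo-European sample matches.
#' * **Model C** (independent pulses): as Model B but with two independent
#'   admixture proportions into the Sekler and Indo-European populations;
#'   a draw is accepted only when all three samples match, so the success
#'   rate is 100% by construction and the accepted draws form the
#'   approximate posterior.
#'
#' @param model one of `"A"`, `"B"`, `"C"`.
#' @param N haploid effective population size (default 5000).
#' @param total_generations simulation horizon in generations (default 100,
#'   i.e. 3000 years at 30 years per generation).
#' @param admixture_generation generations before present of the admixture
#'   pulse (default 30; Models B/C only); must be `< total_generations`.
#' @param pre_admixture_generations generations the source drifts before
#'   the pulse; defaults to `total_generations - admixture_generation` so
#'   all models share one horizon.  Set to 0 for the sensitivity variant in
#'   which the source starts at its prior frequency at the pulse.
#' @param generation_time years per generation (default 30; documentation
#'   only, not used in the simulation).
#' @param priors named list of `c(min, max)` ranges on `[0, 1]` for
#'   `p0` (starting source frequency), `alpha` (shared pulse, Model B),
#'   `alpha_hun` and `alpha_ie` (Model C).
#' @param observed list of three [observed_population()] objects named
#'   `indo_european`, `sekler`, `ural_siberian`; defaults to
#'   [default_observed()].
#' @param blocks number of replication blocks (default 100).
#' @param sims_per_block conditioned simulations per block (default 100).
#' @param n_accepted accepted draws for Model C (default 1000).
#' @param max_attempts cap on raw attempts per conditioned simulation
#'   (or per accepted draw, Model C); default `1e7`.
#' @param tolerance_variant passed to [tolerance()] when `observed` is
#'   rebuilt from defaults.
#' @return An object of class `"model_config"`.
#' @examples
#' model_config("A")
#' model_config("C", n_accepted = 100)
#' @export
model_config <- function(model = c("A", "B", "C"),
                         N = 5000,
                         total_generations = 100,
                         admixture_generation = 30,
                         pre_admixture_generations = NULL,
                         generation_time = 30,
                         priors = NULL,
                         observed = NULL,
                         blocks = 100,
                         sims_per_block = 100,
                         n_accepted = 1000,
                         max_attempts = 1e7,
                         tolerance_variant = c("halved", "classic")) {
  model <- match.arg(model)
  tolerance_variant <- match.arg(tolerance_variant)
  if (is.null(observed)) observed <- default_observed(tolerance_variant)
  stopifnot(
    N >= 1, total_generations >= 0,
    blocks >= 1, sims_per_block >= 1, n_accepted >= 1, max_attempts >= 1
  )
  if (model %in% c("B", "C")) {
    if (admixture_generation < 0 ||
        admixture_generation >= total_generations) {
      stop("`admixture_generation` must lie in [0, total_generations)",
           call. = FALSE)
    }
  }
  if (is.null(pre_admixture_generations)) {
    pre_admixture_generations <- total_generations - admixture_generation
  }
  stopifnot(pre_admixture_generations >= 0)
  default_priors <- list(p0 = c(0, 1), alpha = c(0, 1),
                         alpha_hun = c(0, 1), alpha_ie = c(0, 1))
  if (is.null(priors)) priors <- list()
  priors <- utils::modifyList(default_priors, priors)
  for (nm in names(priors)) {
    pr <- priors[[nm]]
    if (length(pr) != 2L || any(pr < 0) || any(pr > 1) || pr[1] > pr[2]) {
      stop(sprintf("prior `%s` must be a c(min, max) range within [0, 1]", nm),
           call. = FALSE)
    }
  }
  needed <- c("indo_european", "sekler", "ural_siberian")
  if (!all(needed %in% names(observed)) ||
      !all(vapply(observed, inherits, logical(1), "observed_population"))) {
    stop("`observed` must be a named list of observed_population objects ",
         "with elements indo_european, sekler, ural_siberian", call. = FALSE)
  }
  structure(
    list(model = model, N = as.integer(N),
         total_generations = as.integer(total_generations),
         admixture_generation = as.integer(admixture_generation),
         pre_admixture_generations = as.integer(pre_admixture_generations),
         generation_time = generation_time,
         priors = priors, observed = observed,
         blocks = as.integer(blocks),
         sims_per_block = as.integer(sims_per_block),
         n_accepted = as.integer(n_accepted),
         max_attempts = max_attempts,
         tolerance_variant = tolerance_variant),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> Model %s: N = %d, %d generations", x$model,
              x$N, x$total_generations))
  if (x$model %in% c("B", "C")) {
    cat(sprintf(", pulse %d generations before present (source drifts %d first)",
                x$admixture_generation, x$pre_admixture_generations))
  }
  cat("\nObserved samples:\n")
  for (obs in x$observed) {
    cat("  "); print(obs)
  }
  if (x$model == "C") {
    cat(sprintf("Rejection sampling: %d accepted draws\n", x$n_accepted))
  } else {
    cat(sprintf("Replication: %d blocks x %d conditioned simulations\n",
                x$blocks, x$sims_per_block))
  }
  invisible(x)
}

#' Read a model configuration from a YAML file
#'
#' Keys mirror the arguments of [model_config()]; observed populations are
#' given as a list of `{label, n, carriers, role}` entries where `role` is
#' one of `indo_european`, `sekler`, `ural_siberian`.  Unknown keys are an
#' error.  A `seed` key, if present, is returned in attribute `"seed"`.
#'
#' @param path YAML file path.
#' @return A [model_config()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- c("model", "N", "total_generations", "admixture_generation",
             "pre_admixture_generations", "generation_time", "priors",
             "observed", "blocks", "sims_per_block", "n_accepted",
             "max_attempts", "tolerance_variant", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  seed <- raw$seed
  raw$seed <- NULL
  tv <- if (is.null(raw$tolerance_variant)) "halved" else raw$tolerance_variant
  if (!is.null(raw$observed)) {
    obs <- lapply(raw$observed, function(o) {
      observed_population(o$label, o$n, o$carriers, tolerance_variant = tv)
    })
    names(obs) <- vapply(raw$observed, `[[`, character(1), "role")
    raw$observed <- obs
  }
  if (!is.null(raw$priors)) raw$priors <- lapply(raw$priors, unlist)
  cfg <- do.call(model_config, raw)
  attr(cfg, "seed") <- seed
  cfg
}
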