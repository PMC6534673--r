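## Synthetic-data generator: count tables with known drift/admixture ground
## truth, produced by running the drift engine forward under one of three
## scenarios mirroring the demographic models.

#' Specify a synthetic scenario
#'
#' @param scenario one of `"pure_drift"` (all pools drift from one shared
#'   starting frequency), `"shared_pulse"` (source drifts, one shared-alpha
#'   pulse into both carrier-free recipients), `"independent_pulses"`
#'   (two independent pulse proportions).
#' @param p0 starting (source) carrier frequency.
#' @param alpha shared pulse proportion (`shared_pulse`).
#' @param alpha_hun,alpha_ie pulse proportions into the Sekler and
#'   Indo-European pools (`independent_pulses`).
#' @param N haploid effective size of every population.
#' @param total_generations,admixture_generation,pre_admixture_generations
#'   timeline in generations; defaults follow [model_config()].
#' @param sample_sizes named integer vector with elements `indo_european`,
#'   `sekler`, `ural_siberian`; defaults to the pooled sizes 2677/95/957.
#' @param n_subpops number of sampled sub-populations each pool's sample is
#'   split across (all sub-populations draw from the same pool frequency).
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("pure_drift", "shared_pulse",
                                       "independent_pulses"),
                          p0 = 0.13, alpha = 0.3,
                          alpha_hun = 0.3, alpha_ie = 0,
                          N = 5000, total_generations = 100,
                          admixture_generation = 30,
                          pre_admixture_generations = NULL,
                          sample_sizes = c(indo_european = 2677,
                                           sekler = 95,
                                           ural_siberian = 957),
                          n_subpops = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(
    p0 >= 0, p0 <= 1, alpha >= 0, alpha <= 1,
    alpha_hun >= 0, alpha_hun <= 1, alpha_ie >= 0, alpha_ie <= 1,
    N >= 1, total_generations >= 0, n_subpops >= 1,
    all(c("indo_european", "sekler", "ural_siberian") %in%
          names(sample_sizes)),
    all(sample_sizes >= 1)
  )
  if (is.null(pre_admixture_generations)) {
    pre_admixture_generations <- total_generations - admixture_generation
  }
  structure(
    list(scenario = scenario, p0 = p0, alpha = alpha,
         alpha_hun = alpha_hun, alpha_ie = alpha_ie, N = as.integer(N),
         total_generations = as.integer(total_generations),
         admixture_generation = as.integer(admixture_generation),
         pre_admixture_generations = as.integer(pre_admixture_generations),
         sample_sizes = sample_sizes, n_subpops = as.integer(n_subpops)),
    class = "scenario_spec"
  )
}

# split a pool's sample size into k near-equal sub-population sizes
split_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a synthetic count table with known ground truth
#'
#' Simulates the scenario with the drift engine, then splits each pool's
#' sample across `n_subpops` sub-populations, each drawing binomially from
#' the same final pool frequency.  The true parameters and final pool
#' frequencies are attached as attribute `"ground_truth"`.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed.
#' @return A `count_table` with `n_subpops` rows per pool and a
#'   `ground_truth` attribute.
#' @examples
#' tab <- generate_counts(scenario_spec("pure_drift", p0 = 0.2), seed = 1)
#' pool_counts(tab)
#' @export
generate_counts <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  N <- spec$N
  pre <- spec$pre_admixture_generations
  post <- spec$admixture_generation
  if (spec$scenario == "pure_drift") {
    start <- as.integer(round(spec$p0 * N))
    finals <- c(
      indo_european = wf_drift_counts(start, N, spec$total_generations),
      sekler = wf_drift_counts(start, N, spec$total_generations),
      ural_siberian = wf_drift_counts(start, N, spec$total_generations)
    )
  } else {
    a_hun <- if (spec$scenario == "shared_pulse") spec$alpha else spec$alpha_hun
    a_ie <- if (spec$scenario == "shared_pulse") spec$alpha else spec$alpha_ie
    src_pulse <- wf_drift_counts(as.integer(round(spec$p0 * N)), N, pre)
    finals <- c(
      indo_european = wf_drift_counts(as.integer(round(a_ie * src_pulse)),
                                      N, post),
      sekler = wf_drift_counts(as.integer(round(a_hun * src_pulse)),
                               N, post),
      ural_siberian = wf_drift_counts(src_pulse, N, post)
    )
  }
  pools <- names(finals)
  rows <- lapply(pools, function(pool) {
    sizes <- split_sizes(spec$sample_sizes[[pool]], spec$n_subpops)
    counts <- stats::rbinom(length(sizes), sizes, finals[[pool]] / N)
    data.frame(
      population = if (length(sizes) == 1) pool else
        paste(pool, seq_along(sizes), sep = "_"),
      group = pool, n = sizes, carriers = counts
    )
  })
  tab <- validate_count_table(do.call(rbind, rows), "generate_counts()")
  attr(tab, "ground_truth") <- list(
    scenario = spec$scenario, p0 = spec$p0,
    alpha = if (spec$scenario == "shared_pulse") spec$alpha else NULL,
    alpha_hun = if (spec$scenario == "independent_pulses") spec$alpha_hun else NULL,
    alpha_ie = if (spec$scenario == "independent_pulses") spec$alpha_ie else NULL,
    final_pool_freq = as.list(finals / N)
  )
  tab
}

#' Write the deterministic fixture suite
#'
#' Writes a small set of count tables and a model configuration used by the
#' test suite and documentation: a replica of the three observed pools
#' (pooled 0/2677, 4/95, 124/957, split across sub-populations), two
#' simulated tables with JSON ground-truth sidecars (`pure_drift` and
#' `independent_pulses`), a degenerate table (carriers = n) exercising the
#' zero-tolerance warning path, and a Model C configuration in YAML.
#' Output is byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 1).
#' @return Character vector of the file paths written.
#' @export
make_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  # replica of the observed pools: pooled counts 0/2677, 4/95, 124/957
  replica <- count_table(
    population = c("IndoEuropean_west", "IndoEuropean_central",
                   "IndoEuropean_east", "Sekler",
                   "UralSiberian_bashkir", "UralSiberian_khanty",
                   "UralSiberian_mansi"),
    group = c("indo_european", "indo_european", "indo_european",
              "sekler", "ural_siberian", "ural_siberian", "ural_siberian"),
    n = c(900L, 900L, 877L, 95L, 400L, 300L, 257L),
    carriers = c(0L, 0L, 0L, 4L, 52L, 39L, 33L)
  )
  p <- file.path(dir, "counts_observed_replica.tsv")
  write_counts(replica, p); add(p)

  # simulated scenarios with ground truth sidecars
  specs <- list(
    pure_drift = scenario_spec("pure_drift", p0 = 0.13, n_subpops = 3L),
    independent_pulses = scenario_spec("independent_pulses", p0 = 0.4,
                                       alpha_hun = 0.3, alpha_ie = 0,
                                       n_subpops = 2L)
  )
  for (nm in names(specs)) {
    tab <- generate_counts(specs[[nm]], seed = seed)
    p <- file.path(dir, sprintf("counts_%s.tsv", nm))
    write_counts(tab, p); add(p)
    p <- file.path(dir, sprintf("counts_%s.truth.json", nm))
    jsonlite::write_json(attr(tab, "ground_truth"), p, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    add(p)
  }

  # degenerate: a fixed population (carriers = n) has zero tolerance
  degen <- count_table(
    population = c("FixedPool", "Sekler"),
    group = c("fixed", "sekler"), n = c(10L, 95L), carriers = c(10L, 4L)
  )
  p <- file.path(dir, "counts_degenerate.tsv")
  write_counts(degen, p); add(p)

  cfg <- list(
    model = "C", N = 5000L, total_generations = 100L,
    admixture_generation = 30L, n_accepted = 1000L, seed = as.integer(seed),
    observed = list(
      list(label = "Indo-European", n = 2677L, carriers = 0L,
           role = "indo_european"),
      list(label = "Hungarian Sekler", n = 95L, carriers = 4L,
           role = "sekler"),
      list(label = "Ural-Siberian", n = 957L, carriers = 124L,
           role = "ural_siberian")
    )
  )
  p <- file.path(dir, "model_c_config.yaml")
  yaml::write_yaml(cfg, p); add(p)

  paths
}
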