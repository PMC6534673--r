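test_that("model configuration validates its timeline and priors", {
  cfg <- model_config("B")
  expect_equal(cfg$pre_admixture_generations, 70L)
  expect_error(model_config("B", admixture_generation = 100),
               "admixture_generation")
  expect_error(model_config("A", priors = list(p0 = c(0.5, 1.5))),
               "prior")
  expect_error(model_config("A", observed = list(a = 1)),
               "observed_population")
  cfg0 <- model_config("C", pre_admixture_generations = 0)
  expect_equal(cfg0$pre_admixture_generations, 0L)
})

test_that("configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    model = "B", N = 500, total_generations = 50,
    admixture_generation = 10, blocks = 3, sims_per_block = 4, seed = 99,
    observed = list(
      list(label = "IE", n = 2677, carriers = 0, role = "indo_european"),
      list(label = "Sekler", n = 95, carriers = 4, role = "sekler"),
      list(label = "Sib", n = 957, carriers = 124, role = "ural_siberian")
    )
  ), path)
  cfg <- read_model_config(path)
  expect_equal(cfg$model, "B")
  expect_equal(cfg$N, 500L)
  expect_equal(attr(cfg, "seed"), 99L)
  expect_equal(cfg$observed$sekler$carriers, 4L)
  expect_error(read_model_config("no/such/file.yaml"), "no/such/file")
  yaml::write_yaml(list(model = "A", bogus_key = 1), path)
  expect_error(read_model_config(path), "bogus_key")
})

test_that("a block fills with exactly the requested conditioned simulations", {
  set.seed(21)
  cfg <- model_config("A", blocks = 1, sims_per_block = 30)
  blk <- run_model_block(cfg)
  expect_s3_class(blk, "block_result")
  expect_equal(blk$conditioned_sims, 30L)
  expect_gte(blk$raw_attempts, blk$conditioned_sims)
  expect_lte(blk$successes, blk$conditioned_sims)
  expect_equal(blk$success_rate, blk$successes / 30)
})

test_that("success is certain when every tolerance spans the whole unit interval", {
  set.seed(22)
  cfg_a <- model_config("A", sims_per_block = 25,
                        observed = obs_with_tol(1))
  expect_equal(run_model_block(cfg_a)$success_rate, 1)
  # Model B with a vacuous Indo-European criterion only
  cfg_b <- model_config("B", sims_per_block = 10,
                        observed = obs_with_tol(1, "indo_european"))
  expect_equal(run_model_block(cfg_b)$success_rate, 1)
})

test_that("unreachable conditioning trips the attempt cap with a diagnostic", {
  set.seed(23)
  cfg <- model_config("A", sims_per_block = 5,
                      observed = obs_unmatchable("ural_siberian"),
                      max_attempts = 2000)
  expect_error(run_model_block(cfg), "conditioning too rare")
})

test_that("the replication protocol reports per-block rates and their spread", {
  cfg <- model_config("A", blocks = 4, sims_per_block = 10,
                      observed = obs_with_tol(1))
  rep <- replicate_success_rate(cfg, seed = 30)
  expect_s3_class(rep, "drift_replication")
  expect_equal(nrow(rep$blocks), 4)
  expect_equal(rep$mean_success_pct, 100)
  expect_equal(rep$sd_success_pct, 0)
  expect_warning(
    replicate_success_rate(
      model_config("A", blocks = 1, sims_per_block = 2,
                   observed = obs_with_tol(1)), seed = 30),
    "single block")
})

test_that("identical seeds reproduce the replication summary exactly", {
  cfg <- model_config("B", blocks = 2, sims_per_block = 10)
  r1 <- replicate_success_rate(cfg, seed = 77)
  r2 <- replicate_success_rate(cfg, seed = 77)
  expect_identical(r1$blocks, r2$blocks)
  expect_identical(r1$mean_success_pct, r2$mean_success_pct)
})

test_that("every accepted rejection-sampling draw satisfies all three criteria", {
  fit <- fit_admixture_abc(n_accepted = 60, seed = 41)
  obs <- fit$config$observed
  expect_equal(nrow(fit$draws), 60)
  expect_true(all(matches(fit$draws$source_sample_freq, obs$ural_siberian)))
  expect_true(all(matches(fit$draws$sekler_sample_freq, obs$sekler)))
  expect_true(all(matches(fit$draws$ie_sample_freq, obs$indo_european)))
  # parameters come from their priors' support
  expect_true(all(fit$draws$p0 >= 0 & fit$draws$p0 <= 1))
  expect_true(all(fit$draws$alpha_hun >= 0 & fit$draws$alpha_hun <= 1))
})

test_that("the fit is reproducible and its methods are coherent", {
  f1 <- fit_admixture_abc(n_accepted = 30, seed = 55)
  f2 <- fit_admixture_abc(n_accepted = 30, seed = 55)
  expect_identical(f1$draws, f2$draws)
  cf <- coef(f1)
  expect_equal(unname(cf["alpha_hun"]), mean(f1$draws$alpha_hun))
  ci <- confint(f1, "alpha_hun", level = 0.9)
  expect_lt(ci[1, 1], cf["alpha_hun"])
  expect_gt(ci[1, 2], cf["alpha_hun"])
  expect_identical(as.data.frame(f1), f1$draws)
  s <- summary(f1)
  expect_s3_class(s, "summary.admixture_abc")
  expect_true(all(s$minmax$lower_pct <= s$percentile$lower_pct))
  expect_output(print(f1), "accepted draws")
})

test_that("unmatchable observations abort at the acceptance floor", {
  cfg <- model_config("C", observed = obs_unmatchable("sekler"),
                      n_accepted = 10)
  expect_error(
    fit_admixture_abc(config = cfg, seed = 1, batch_size = 4096L,
                      acceptance_floor = 1e-3),
    "acceptance rate")
})

test_that("posterior summaries follow order statistics of the draws", {
  const <- data.frame(a = rep(0.3, 10))
  s <- summarize_posterior(const)
  expect_equal(s$mean_pct, 30)
  expect_equal(s$lower_pct, 30)
  expect_equal(s$upper_pct, 30)
  tri <- data.frame(a = rep(c(0, 0.5, 1), 50))
  expect_equal(summarize_posterior(tri)$mean_pct, 50)
  set.seed(71)
  unif <- data.frame(a = runif(1000))
  s <- summarize_posterior(unif)
  expect_equal(s$mean_pct, 50, tolerance = 0.08)
  expect_equal(s$lower_pct, 2.5, tolerance = 0.8)
  expect_equal(s$upper_pct, 97.5, tolerance = 0.02)
  expect_equal(summarize_posterior(unif, "minmax")$lower_pct, 100 * min(unif$a))
  expect_error(summarize_posterior(data.frame(a = 0.5)), "at least 2")
})

test_that("symmetric observations give indistinguishable admixture posteriors", {
  # both recipients observed at 0 carriers of 2677: by symmetry the two
  # pulse proportions have the same posterior
  obs <- default_observed()
  obs$sekler <- observed_population("Sekler", 2677, 0)
  fit <- fit_admixture_abc(observed = obs, n_accepted = 150, seed = 88)
  m <- coef(fit)
  pooled_sd <- sd(c(fit$draws$alpha_hun, fit$draws$alpha_ie))
  expect_lt(abs(m["alpha_hun"] - m["alpha_ie"]),
            4 * pooled_sd / sqrt(150 / 2))
})
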