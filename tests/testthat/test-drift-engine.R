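test_that("population state construction validates its invariants", {
  pop <- wf_population("src", freq = 0.13, size = 5000)
  expect_s3_class(pop, "wf_population")
  expect_equal(pop$count, 650L)
  expect_error(wf_population("x", freq = -0.1), "\\[0, 1\\]")
  expect_error(wf_population("x", freq = 1.2), "\\[0, 1\\]")
  expect_error(wf_population("x", freq = 0.5, size = 0), ">= 1")
})

test_that("frequencies 0 and 1 are absorbing under drift", {
  set.seed(1)
  lost <- wf_population("lost", 0)
  fixed <- wf_population("fixed", 1)
  for (i in 1:20) {
    expect_identical(drift_step(lost)$freq, 0)
    expect_identical(drift_step(fixed)$freq, 1)
  }
  expect_identical(drift_trajectory(lost, 100)$freq, 0)
  expect_identical(drift_trajectory(fixed, 100)$freq, 1)
})

test_that("a drift step is binomial resampling: mean and variance match", {
  set.seed(42)
  N <- 5000
  reps <- 1e5
  after <- driftpulse:::wf_drift_counts(rep(2500L, reps), N, 1) / N
  expect_lt(abs(mean(after) - 0.5), 4 * sqrt(0.25 / N / reps))
  expect_equal(var(after), 0.5 * 0.5 / N, tolerance = 0.03)
})

test_that("drift is a martingale with the closed-form variance over 100 generations", {
  set.seed(7)
  N <- 5000; t <- 100; p0 <- 0.13; reps <- 2e4
  finals <- driftpulse:::wf_drift_counts(rep(650L, reps), N, t) / N
  v_expect <- p0 * (1 - p0) * (1 - (1 - 1 / N)^t)
  expect_lt(abs(mean(finals) - p0), 4 * sqrt(v_expect / reps))
  expect_equal(var(finals), v_expect, tolerance = 0.06)
})

test_that("tiny populations fix or lose the allele as the exact Markov chain predicts", {
  set.seed(11)
  # N = 2, start at freq 0.5: the exact 3-state chain says the middle state
  # survives 50 generations with probability 0.5^50
  M <- wf_transition_matrix(2)
  p_middle <- M[2, 2]^50  # only route to staying unabsorbed from count 1
  reps <- 2000
  finals <- vapply(seq_len(reps), function(i) {
    drift_trajectory(wf_population("p", 0.5, size = 2), 50)$freq
  }, numeric(1))
  expect_true(all(finals %in% c(0, 1)))
  expect_gt(1 - p_middle, 0.99)
  # martingale: fixation probability equals the starting frequency
  expect_lt(abs(mean(finals) - 0.5), 4 * sqrt(0.25 / reps))
})

test_that("literal haplotype resampling has binomial one-step moments", {
  set.seed(3)
  N <- 50; count <- 20L
  draws <- vapply(seq_len(4000), function(i) {
    driftpulse:::wf_generation_literal(count, N)
  }, integer(1))
  expect_lt(abs(mean(draws) - count), 4 * sqrt(N * 0.4 * 0.6 / 4000))
  expect_equal(var(draws), N * 0.4 * 0.6, tolerance = 0.15)
})

test_that("admixture is the linear mixture, rounded to the allele-count grid", {
  src <- wf_population("src", 0.5)
  rec <- wf_population("rec", 0.0)
  expect_equal(admix(rec, src, 0)$freq, 0)
  expect_equal(admix(rec, src, 1)$freq, 0.5)
  expect_equal(admix(rec, src, 0.4)$freq, 0.2)
  expect_error(admix(rec, src, 1.5), "\\[0, 1\\]")
  expect_error(admix(src, src, 0.5), "distinct")
})

test_that("composing two pulses matches the closed-form mixture up to one grid unit", {
  set.seed(5)
  N <- 5000
  for (i in 1:25) {
    p_r <- runif(1); p_s <- runif(1); a <- runif(1); b <- runif(1)
    rec <- wf_population("rec", p_r, N)
    src <- wf_population("src", p_s, N)
    out <- admix(admix(rec, src, a), src, b)
    keep <- (1 - a) * (1 - b)
    expect_lt(abs(out$freq - (keep * p_r + (1 - keep) * p_s)), 1 / N + 1e-12)
  }
})

test_that("final-generation sampling is binomial at the population frequency", {
  set.seed(9)
  pop <- wf_population("sib", 0.13)
  reps <- 2e4
  freqs <- vapply(seq_len(reps), function(i) {
    sample_carriers(pop, 957)$freq
  }, numeric(1))
  sd_expect <- sqrt(0.13 * 0.87 / 957)
  expect_lt(abs(mean(freqs) - 0.13), 4 * sd_expect / sqrt(reps))
  expect_equal(sd(freqs), sd_expect, tolerance = 0.05)
  expect_equal(sample_carriers(wf_population("none", 0), 957),
               list(count = 0L, freq = 0))
  expect_equal(sample_carriers(wf_population("all", 1), 95),
               list(count = 95L, freq = 1))
  expect_error(sample_carriers(pop, 0), ">= 1")
})

test_that("trajectories are returned on the count grid and can be dumped as text", {
  set.seed(13)
  pop <- wf_population("p", 0.3, size = 200)
  expect_identical(drift_trajectory(pop, 0)$freq, pop$freq)
  expect_error(drift_trajectory(pop, -1), "non-negative")
  out <- drift_trajectory(pop, 40, keep = TRUE)
  traj <- attr(out, "trajectory")
  expect_equal(nrow(traj), 41)
  expect_equal(traj$freq[1], 0.3)
  expect_true(all(abs(traj$freq * 200 - round(traj$freq * 200)) < 1e-9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(out, path)
  dumped <- read.delim(path)
  expect_equal(dumped$freq, traj$freq)
  expect_error(write_trajectory(drift_trajectory(pop, 3), path),
               "keep = TRUE")
})
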