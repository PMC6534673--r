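# shared builders for the test suite

# the three default observed pools (IE 0/2677, Sekler 4/95, Ural-Siberian
# 124/957), built fresh each call so tests can mutate copies freely
obs_default <- function() default_observed()

# an observed set whose tolerances are forced to a given width, for
# degenerate-criterion tests (everything matches at tol = 1)
obs_with_tol <- function(tol, which = c("indo_european", "sekler",
                                        "ural_siberian")) {
  obs <- default_observed()
  for (nm in which) obs[[nm]]$tol <- tol
  obs
}

# an observed set that no simulated sample frequency can ever match:
# irrational target with zero tolerance on the named pool
obs_unmatchable <- function(which) {
  obs <- default_observed()
  obs[[which]]$tol <- 0
  obs[[which]]$p_adjusted <- pi / 100
  obs
}

# write a small count table file and return its path
write_tmp_counts <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# exact haploid Wright-Fisher transition matrix on allele counts 0..N,
# used as a brute-force Markov-chain oracle at tiny N
wf_transition_matrix <- function(N) {
  outer(0:N, 0:N, function(i, j) dbinom(j, N, i / N))
}
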