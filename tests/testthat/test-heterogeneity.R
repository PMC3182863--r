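test_that("zero heterogeneity gives exactly unit multipliers", {
  m <- sample_multipliers(het_spec(0, 0, 42, 20))
  expect_equal(m$zeta, rep(1, 20))
  expect_equal(m$xi, rep(1, 20))
})

test_that("draws have the requested mean and SD and respect the floor", {
  m <- sample_multipliers(het_spec(0.2, 0.1, 123, 1e5))
  expect_equal(mean(m$zeta), 1, tolerance = 0.01)
  expect_equal(sd(m$zeta), 0.2, tolerance = 0.01)
  expect_equal(mean(m$xi), 1, tolerance = 0.01)
  expect_equal(sd(m$xi), 0.1, tolerance = 0.01)
  expect_true(all(m$zeta > 0.05))
  expect_true(all(m$xi > 0.05))
  # heavy truncation pressure still never yields values at or below the floor
  m2 <- sample_multipliers(het_spec(0.4, 0, 5, 1e4))
  expect_true(all(m2$zeta > 0.05))
})

test_that("sampling is reproducible and does not disturb the global RNG", {
  a <- sample_multipliers(het_spec(0.2, 0.2, 7, 50))
  b <- sample_multipliers(het_spec(0.2, 0.2, 7, 50))
  expect_identical(a, b)
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(sample_multipliers(het_spec(0.2, 0, 7, 50)))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("child seeds are deterministic, distinct, and in integer range", {
  s1 <- child_seeds(1, 60)
  s2 <- child_seeds(1, 60)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 60)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_false(identical(child_seeds(1, 10), child_seeds(2, 10)))
})

test_that("ensembles replicate the base config across child seeds", {
  cfg <- std_config(n = 5)
  ens <- make_ensemble(cfg, 4)
  expect_length(ens, 4)
  expect_equal(attr(ens, "master_seed"), cfg$seed)
  seeds <- vapply(ens, function(c) c$seed, integer(1))
  expect_equal(seeds, child_seeds(cfg$seed, 4))
  # a single-member ensemble mean equals the single trace
  c1 <- sim_config(topology(4), protocol(post_stretch_hold = 6),
                   alpha = 0.1, beta = 0, seed = 2)
  e1 <- ensemble_rfe(c1, 1)
  pair <- run_protocol_pair(make_ensemble(c1, 1)[[1]])
  expect_equal(e1$force_stretch_mean, pair$stretch$force)
  expect_equal(e1$rfe_percent, pair$rfe$rfe_percent)
})
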