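test_that("sweep specifications validate their inputs", {
  expect_error(sweep_spec("velocity", numeric(0)), "non-empty")
  expect_error(sweep_spec("nonsense", 1), "arg")
  expect_error(magnitude_sweep(sweep_spec("magnitude", c(0.08, 0.08), 2,
                                          std_config(n = 2))),
               "two distinct")
})

test_that("convergence time handles identical and homogeneous pairs", {
  prot <- protocol(post_stretch_hold = 8)
  n <- length(sarcomech:::protocol_times(prot))
  f <- rep(100, n)
  expect_equal(convergence_time(f, f, prot), 0)
  # alpha = 0 pair: the transient decays within a few basal cycle times of
  # the stretch end -- orders of magnitude faster than the tens of seconds
  # a heterogeneous chain needs
  cfg <- sim_config(topology(1), prot, alpha = 0, beta = 0, seed = 1)
  pair <- run_protocol_pair(cfg)
  ct <- convergence_time(pair$stretch$force, pair$isometric$force, prot)
  expect_lt(ct, 5)
  # never-converging traces are reported as beyond the horizon
  expect_equal(convergence_time(f * 1.5, f, prot), Inf)
})

test_that("two dissimilar half-sarcomeres show the enhancement mechanism", {
  ex <- two_hs_demo(zeta_weak = 0.9, zeta_strong = 1.1,
                    post_stretch_hold = 35,
                    lt_grid = seq(1100, 1680, by = 20))
  prot <- protocol(post_stretch_hold = 35)
  traj <- ex$trajectory
  # after the stretch ends the weak unit keeps lengthening while the strong
  # one shortens (antagonistic internal motion at fixed total length)
  k1 <- which.min(abs(traj$time - (prot$stretch_end + 0.5)))
  k2 <- which.min(abs(traj$time - (prot$stretch_end + 4)))
  expect_gt(traj$length_weak[k2], traj$length_weak[k1])
  expect_lt(traj$length_strong[k2], traj$length_strong[k1])
  # 1 s post-stretch: chain tension above the weak unit's steady-state curve
  # at its current length, below the strong unit's
  snap <- ex$snapshots[ex$snapshots$when == "post_stretch_1s", ]
  curve_at <- function(unit, l) {
    cu <- ex$curves[ex$curves$unit == unit, ]
    approx(cu$length, cu$tension, xout = l)$y
  }
  expect_gt(snap$tension, curve_at("weak", snap$length_weak))
  expect_lt(snap$tension, curve_at("strong", snap$length_strong))
})

test_that("equal-strength two-unit chains show no post-stretch drift", {
  prot <- protocol(post_stretch_hold = 6)
  cfg <- sim_config(topology(2), prot, alpha = 0, beta = 0, seed = 1)
  pair <- run_protocol_pair(cfg)
  expect_lt(abs(pair$rfe$rfe_percent), 1)
  lens <- pair$stretch$lengths
  post <- pair$stretch$rec_time > prot$stretch_end + 0.5
  drift <- apply(lens[post, ], 2, function(v) max(v) - min(v))
  expect_lt(max(drift), 0.5)
})

test_that("enhancement requires heterogeneity and grows with alpha", {
  base <- std_config(n = 50, post_stretch_hold = 6)
  sw <- alpha_sweep(sweep_spec("alpha", c(0, 0.1), 3, base))
  expect_lt(abs(sw$rfe_percent[sw$alpha == 0]), 1)
  expect_gt(sw$rfe_percent[sw$alpha == 0.1], sw$rfe_percent[sw$alpha == 0])
})
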