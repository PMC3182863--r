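test_that("activation ramps linearly and saturates", {
  prot <- protocol()
  expect_equal(activation_trace(0, prot), 0)
  expect_equal(activation_trace(0.5, prot), 0.5)
  expect_equal(activation_trace(10, prot), 1)
  expect_error(activation_trace(-1, prot), ">= 0")
})

test_that("length traces implement the ramp-and-hold and isometric designs", {
  prot <- protocol()  # 8% at 0.1 L0/s from 1200 nm
  expect_equal(prot$stretch_duration, 0.8)
  expect_equal(prot$initial_mean_hs_length, 1200)
  expect_equal(prot$final_mean_hs_length, 1296)
  expect_equal(length_trace(c(0, 5, 50), prot, "isometric"), rep(1296, 3))
  expect_equal(length_trace(1.5, prot, "stretch"), 1200)   # before onset
  expect_equal(length_trace(2.4, prot, "stretch"), 1248)   # mid-ramp
  expect_equal(length_trace(9, prot, "stretch"), 1296)     # after ramp
  # specifying the final length back-computes the start
  prot2 <- protocol(final_mean_hs_length = 1296)
  expect_equal(prot2$initial_mean_hs_length, 1200)
  expect_error(protocol(post_stretch_hold = 2, t_ss = 6), "t_ss")
})

test_that("the enhancement statistic is plain arithmetic at t_ss", {
  prot <- protocol()
  n <- length(sarcomech:::protocol_times(prot))
  fs <- rep(113, n); fi <- rep(100, n)
  r <- rfe_from_traces(fs, fi, prot)
  expect_equal(r$rfe_percent, 13)
  expect_equal(r$t_eval, prot$stretch_end + 6)
  # invariant to shifting both traces by a common time offset: the statistic
  # depends only on the values at the evaluation index
  k <- round(r$t_eval / prot$dt) + 1
  fs2 <- fi2 <- rep(1, n); fs2[k] <- 226; fi2[k] <- 200
  expect_equal(rfe_from_traces(fs2, fi2, prot)$rfe_percent, 13)
  expect_error(rfe_from_traces(fs[1:10], fi[1:10], prot), "t_ss")
})

test_that("a homogeneous pair shows no residual enhancement", {
  cfg <- sim_config(topology(1), protocol(), alpha = 0, beta = 0, seed = 1)
  pair <- run_protocol_pair(cfg)
  expect_lt(abs(pair$rfe$rfe_percent), 1)
  # force peaks during the stretch, then decays back to isometric
  prot <- cfg$protocol
  i_ramp <- round(seq(prot$ramp_start, prot$stretch_end, by = prot$dt) /
                    prot$dt) + 1
  expect_gt(max(pair$stretch$force[i_ramp]), 1.1 * pair$rfe$force_iso)
  expect_lt(abs(pair$rfe$force_stretch - pair$rfe$force_iso) /
              pair$rfe$force_iso, 0.01)
})

test_that("steady-state length-tension curve has the expected shape", {
  p <- test_params()
  lt <- steady_state_length_tension(
    p, c(1050, 1134, 1210, 1296, 1404, 1512, 1650))
  expect_true(all(lt$converged))
  expect_equal(lt$limb,
               c("ascending", "ascending", "plateau", "plateau",
                 "descending", "descending", "descending"))
  # plateau lengths sit near the curve maximum; ascending below it
  mx <- max(lt$tension)
  expect_gt(lt$tension[lt$length == 1210], 0.92 * mx)
  expect_gt(lt$tension[lt$length == 1296], 0.92 * mx)
  expect_lt(lt$tension[lt$length == 1134], lt$tension[lt$length == 1210])
  # beyond overlap the active component vanishes and tension is passive
  p17 <- steady_state_length_tension(p, 1700)
  expect_equal(p17$active, 0, tolerance = 1e-6)
  expect_equal(p17$tension, passive_force(1700, p))
  expect_error(steady_state_length_tension(p, 900), "1000")
})

test_that("the stretched trial stays above its isometric companion", {
  cfg <- std_config(n = 50, alpha = 0.2, seed = 1, post_stretch_hold = 6)
  ens <- ensemble_rfe(cfg, 3)
  prot <- cfg$protocol
  after <- which(ens$time > prot$ramp_start + 0.1 &
                 ens$time <= prot$stretch_end + 6)
  frac_above <- mean(ens$force_stretch_mean[after] > ens$force_iso_mean[after])
  expect_gt(frac_above, 0.95)
  expect_gt(ens$rfe_percent, 0)
})
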