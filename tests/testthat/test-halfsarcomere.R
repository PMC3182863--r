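p <- test_params()

test_that("overlap fraction is piecewise linear with the expected limbs", {
  expect_equal(overlap_fraction(1210, p), 1)            # plateau
  expect_equal(overlap_fraction(1296, p), 1)            # plateau
  expect_lt(overlap_fraction(1134, p), 1)               # ascending limb
  expect_gt(overlap_fraction(1134, p), 0)
  expect_equal(overlap_fraction(1700, p), 0)            # no overlap
  expect_equal(overlap_fraction(1900, p), 0)
  # continuity at every breakpoint
  br <- c(p$overlap_zero_short, p$overlap_plateau_lo,
          p$overlap_plateau_hi, p$overlap_zero_long)
  eps <- 1e-9
  for (b in br)
    expect_equal(overlap_fraction(b - eps, p), overlap_fraction(b + eps, p),
                 tolerance = 1e-6)
  expect_error(overlap_fraction(NaN, p), "finite")
  expect_error(overlap_fraction(-5, p), "finite")
})

test_that("available heads scale with density, strength, activation, overlap", {
  expect_equal(n_available(1210, 0, p), 0)
  expect_equal(n_available(1210, 1, p), 1.15e17)
  p2 <- p; p2$zeta <- 0.5
  expect_equal(n_available(1210, 1, p2), 5.75e16)
  expect_equal(n_available(1210, 0.25, p), 1.15e17 * 0.25)
  expect_error(n_available(1210, 1.2, p), "activation")
  expect_error(n_available(1210, -0.1, p), "activation")
})

test_that("passive force is an xi-scaled exponential, zero at the offset", {
  expect_equal(passive_force(p$passive_offset, p), 0)
  p2 <- p; p2$xi <- 2
  expect_equal(passive_force(1400, p2), 2 * passive_force(1400, p))
  expect_gt(passive_force(1404, p), passive_force(1296, p))
  # strictly increasing on a grid, continuous at the offset
  l <- seq(400, 1700, by = 25)
  expect_true(all(diff(passive_force(l, p)) > 0))
  eps <- 1e-7
  expect_equal(passive_force(p$passive_offset + eps, p),
               passive_force(p$passive_offset - eps, p), tolerance = 1e-4)
  # direct check against the analytic form above the offset
  expect_equal(passive_force(1300, p),
               p$passive_sigma * (exp((1300 - p$passive_offset) /
                                        p$passive_lambda) - 1))
})

test_that("active force matches the Huxley population sum", {
  nb <- p$axis$n_bins
  x <- p$axis$x
  expect_equal(active_force(xb_distribution(p, d = 1e16), p), 0)
  # a single occupied pre-powerstroke bin at zero strain contributes nothing
  a1 <- numeric(nb); a1[which(x == 0)] <- 1e15
  expect_equal(active_force(xb_distribution(p, a1 = a1), p), 0)
  # uniform A2 occupancy symmetric about zero: strain terms cancel,
  # leaving k_cb * x_ps * total
  a2 <- rep(1e13, nb)
  expect_equal(active_force(xb_distribution(p, a2 = a2), p),
               p$k_cb * p$x_ps * sum(a2), tolerance = 1e-12)
  # random distribution against direct summation in R
  set.seed(42)
  a1 <- runif(nb) * 1e13; a2 <- runif(nb) * 1e13
  expect_equal(active_force(xb_distribution(p, a1, a2), p),
               p$k_cb * (sum(a1 * x) + sum(a2 * (x + p$x_ps))))
  bad <- hs_params(axis = strain_axis(-10, 10, 81))
  expect_error(active_force(xb_distribution(p, a1, a2), bad), "axis")
})

test_that("kinetics conserves mass and leaves an all-zero-rate system unchanged", {
  set.seed(7)
  for (k in 1:5) {
    nb <- p$axis$n_bins
    dist <- xb_distribution(p, runif(nb) * 1e14, runif(nb) * 1e14, 3e16)
    st <- hs_state(1210, dist, p)
    nav <- n_available(1210, 1, p)
    out <- kinetics_step(st, 1, 1e-3, p)
    expect_equal(total_heads(out), nav, tolerance = 1e-9)
  }
  # all rates zero: distribution unchanged by the transition step
  p0 <- hs_params(f0 = 0, h0 = 0, h_r = 0, g_a1 = 0, g0 = 0, g1 = 0)
  dist <- xb_distribution(p0, a2 = rep(1e13, p0$axis$n_bins), d = 1e15)
  dist <- rescale_pools(dist, total_heads(dist))  # identity rescale
  out <- cpp_kinetics_step(dist$a1, dist$a2, dist$d, 1e-3,
                           sarcomech:::pars_to_c(p0))
  expect_equal(out$a1, dist$a1)
  expect_equal(out$a2, dist$a2)
  expect_equal(out$d, dist$d)
})

test_that("pure detachment decays as the closed-form exponential", {
  # only A2 -> D at constant rate g: occupancy must follow exp(-g t)
  g <- 8
  pg <- hs_params(f0 = 0, h0 = 0, h_r = 0, g_a1 = 0, g0 = g, g1 = 0)
  pc <- sarcomech:::pars_to_c(pg)
  nb <- pg$axis$n_bins
  a1 <- numeric(nb); a2 <- rep(1e13, nb); d <- 0
  dt <- 1e-3; n <- 500
  for (i in seq_len(n)) {
    out <- cpp_kinetics_step(a1, a2, d, dt, pc)
    a1 <- out$a1; a2 <- out$a2; d <- out$d
  }
  expect_equal(sum(a2) / (1e13 * nb), exp(-g * dt * n), tolerance = 1e-2)
})

test_that("kinetic steady state matches the analytic fixed point and is unique", {
  s <- settle_halfsarcomere(1210, p, activation = 1, tol = 1e-9)
  expect_true(s$converged)
  an <- analytic_steady_state(p, 1210, 1)
  expect_equal(s$force_active, an$force_active, tolerance = 1e-4)
  expect_equal(s$dist$d, an$d, tolerance = 1e-4)
  # independence of the initial occupancy: start from a very different
  # distribution and iterate the kinetics to convergence
  pc <- sarcomech:::pars_to_c(p)
  nav <- n_available(1210, 1, p)
  nb <- p$axis$n_bins
  a1 <- numeric(nb); a2 <- rep(nav / nb, nb); d <- 0
  for (i in 1:8000) {
    out <- cpp_kinetics_step(a1, a2, d, 1e-3, pc)
    a1 <- out$a1; a2 <- out$a2; d <- out$d
  }
  f2 <- active_force(xb_distribution(p, a1, a2, d), p)
  expect_equal(f2, s$force_active, tolerance = 1e-3)
})

test_that("strain advection translates profiles conservatively", {
  nb <- p$axis$n_bins
  x <- p$axis$x
  gauss <- 1e14 * exp(-(x - 1)^2 / 2)
  dist <- xb_distribution(p, a1 = gauss, a2 = gauss / 2, d = 1e15)
  # zero shift is the identity
  s0 <- shift_distribution(dist, 0, p)
  expect_equal(s0$a1, dist$a1)
  # one-bin shift is an exact index translation
  h <- p$axis$bin_width
  s1 <- shift_distribution(dist, h, p)
  expect_equal(s1$a1[-1], dist$a1[-nb])
  expect_equal(sum(s1$a1) + sum(s1$a2), sum(dist$a1) + sum(dist$a2),
               tolerance = 1e-12)
  # +0.3h then -0.3h conserves totals exactly; profile differs only by
  # bounded interpolation diffusion relative to the analytic translation
  s2 <- shift_distribution(shift_distribution(dist, 0.3 * h, p), -0.3 * h, p)
  expect_equal(sum(s2$a1), sum(dist$a1), tolerance = 1e-12)
  l2 <- sqrt(sum((s2$a1 - dist$a1)^2)) / sqrt(sum(dist$a1^2))
  expect_lt(l2, 0.05)
  # fractional shift moves the first moment by exactly the shift
  s3 <- shift_distribution(dist, 0.3 * h, p)
  m0 <- sum(dist$a1 * x) / sum(dist$a1)
  m3 <- sum(s3$a1 * x) / sum(s3$a1)
  expect_equal(m3 - m0, 0.3 * h, tolerance = 1e-9)
  expect_error(shift_distribution(dist, 25, p), "axis")
})

test_that("instantaneous stiffness matches a finite-difference of total force", {
  set.seed(11)
  nb <- p$axis$n_bins
  x <- p$axis$x
  prof <- 1e14 * exp(-(x + 0.5)^2)
  dist <- xb_distribution(p, a1 = prof, a2 = 2 * prof, d = 1e15)
  st <- hs_state(1350, dist, p)
  k <- instantaneous_stiffness(st, p)
  dl <- 0.01
  # bound population held fixed: shift the profiles with the length change
  f_at <- function(l) {
    d2 <- shift_distribution(dist, l - 1350, p)
    active_force(d2, p) + passive_force(l, p)
  }
  k_fd <- (f_at(1350 + dl) - f_at(1350 - dl)) / (2 * dl)
  expect_equal(k, k_fd, tolerance = 1e-3)
  # doubling the bound population doubles the cross-bridge term
  dist2 <- xb_distribution(p, 2 * prof, 4 * prof, 1e15)
  st2 <- hs_state(1350, dist2, p)
  pass_slope <- instantaneous_stiffness(hs_state(1350, xb_distribution(p), p), p)
  expect_equal(instantaneous_stiffness(st2, p) - pass_slope,
               2 * (k - pass_slope), tolerance = 1e-12)
})
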