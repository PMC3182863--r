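p <- test_params()

test_that("identical units share the total length equally", {
  n <- 8
  net <- make_network(topology(n), p, rep(1, n), rep(1, n), 1200)
  # give every unit the same settled distribution so forces are non-trivial
  s <- settle_halfsarcomere(1200, p)
  for (u in seq_len(n)) {
    net$a1[, u] <- s$dist$a1; net$a2[, u] <- s$dist$a2; net$d[u] <- s$dist$d
  }
  out <- solve_force_balance(net, n * 1250)
  expect_equal(out$lengths, rep(1250, n), tolerance = 1e-9)
  f <- attr(out, "forces")
  expect_lt(max(abs(f - mean(f))) / mean(f), 1e-5)
})

test_that("two passive units share extension like series springs", {
  # no bound bridges: the units are passive exponential springs. After
  # equilibrating, a small added extension splits by the closed-form
  # series-spring rule with the local stiffnesses at equilibrium.
  xi <- c(1, 2.5)
  net <- make_network(topology(2), p, c(1, 1), xi, 1300)
  net <- solve_force_balance(net, 2 * 1300)   # passive equilibrium
  l0 <- net$lengths
  # oracle for the equilibrium itself: equal passive force by root finding
  eq <- uniroot(function(l1)
    xi[1] * passive_force(l1, p) - xi[2] * passive_force(2 * 1300 - l1, p),
    c(1000, 1600), tol = 1e-10)$root
  expect_equal(l0, c(eq, 2 * 1300 - eq), tolerance = 1e-6)
  dL <- 2
  out <- solve_force_balance(net, 2 * 1300 + dL)
  k <- xi * p$passive_sigma / p$passive_lambda *
    exp((l0 - p$passive_offset) / p$passive_lambda)
  expect_equal(out$lengths[1] - l0[1], dL * k[2] / (k[1] + k[2]),
               tolerance = 0.02)
  expect_equal(out$lengths[2] - l0[2], dL * k[1] / (k[1] + k[2]),
               tolerance = 0.02)
})

test_that("three heterogeneous units agree with a brute-force grid scan", {
  zeta <- c(0.8, 1.0, 1.25)
  xi <- c(1.2, 0.9, 1.0)
  n <- 3
  net <- make_network(topology(n), p, zeta, xi, 1250)
  for (u in seq_len(n)) {
    pu <- p; pu$zeta <- zeta[u]
    s <- settle_halfsarcomere(1250, pu)
    net$a1[, u] <- s$dist$a1; net$a2[, u] <- s$dist$a2; net$d[u] <- s$dist$d
  }
  Ltot <- 3 * 1250 + 30
  out <- solve_force_balance(net, Ltot)
  # oracle: frozen-population force functions, grid-scanned to 1e-3 nm
  pc <- sarcomech:::pars_to_c(p)
  B <- colSums(net$a1) + colSums(net$a2)
  A <- sapply(seq_len(n), function(u)
    sarcomech:::cpp_active_force(net$a1[, u], net$a2[, u], pc))
  fns <- lapply(seq_len(n), function(u) {
    force(u)
    function(l) A[u] + p$k_cb * B[u] * (l - 1250) +
      xi[u] * passive_force(l, p)
  })
  oracle <- brute_force_balance_3(fns, Ltot, resolution = 1e-3)
  expect_equal(out$lengths, oracle, tolerance = 1e-3)
})

test_that("a homogeneous chain reproduces the single half-sarcomere trace", {
  prot <- protocol(post_stretch_hold = 6)
  c1 <- sim_config(topology(1), prot, alpha = 0, beta = 0, seed = 1)
  c8 <- sim_config(topology(8), prot, alpha = 0, beta = 0, seed = 1)
  s1 <- run_trial(c1, "stretch")
  s8 <- run_trial(c8, "stretch")
  i <- seq(101, length(s1$force), by = 50)  # skip the initial zeros
  expect_lt(max(abs(s8$force[i] - s1$force[i]) / s1$force[i]), 1e-3)
})

test_that("total length is conserved and series forces stay uniform", {
  cfg <- std_config(n = 20, alpha = 0.15, seed = 3,
                    post_stretch_hold = 6)
  s <- run_trial(cfg, "stretch")
  L <- length_trace(s$rec_time, cfg$protocol, "stretch") * 20
  expect_equal(rowSums(s$lengths), L, tolerance = 1e-6)
  expect_true(all(s$lengths > 0))
  # uniform tension at the end of the run
  pc <- sarcomech:::pars_to_c(p)
  mult <- sample_multipliers(het_spec(0.15, 0, 3, 20))
  fa <- sapply(1:20, function(u)
    sarcomech:::cpp_active_force(s$final_a1[, u], s$final_a2[, u], pc))
  fp <- sarcomech:::cpp_passive_force(s$lengths[nrow(s$lengths), ],
                                      1, pc) * mult$xi
  f <- fa + fp
  expect_lt(max(abs(f - mean(f))) / mean(f), 1e-5)
})

test_that("passive-only integration leaves lengths constant in time", {
  cfg <- sim_config(topology(6), protocol(post_stretch_hold = 6), alpha = 0.3,
                    beta = 0.3, seed = 5)
  t <- seq(0, 1, by = 1e-3)
  mult <- sample_multipliers(het_spec(0.3, 0.3, 5, 6))
  sim <- run_simulation(topology(6), p, mult$zeta, mult$xi,
                        rep(0, length(t)), rep(6 * 1300, length(t)), 1e-3)
  # after the first balance, lengths are at the passive equilibrium and stay
  rng <- apply(sim$lengths[-1, ], 2, function(v) max(v) - min(v))
  expect_lt(max(rng), 1e-6)
})

test_that("a zero-duration protocol yields an empty trace with metadata", {
  sim <- run_simulation(topology(3), p, rep(1, 3), rep(1, 3),
                        numeric(0), numeric(0), 1e-3, seed = 9)
  expect_equal(length(sim$time), 0)
  expect_equal(length(sim$force), 0)
  expect_equal(sim$meta$seed, 9)
})

test_that("tighter z-line coupling reduces z-line misregistration", {
  # 2 myofibrils x 4 units, mildly heterogeneous, short activation
  set.seed(1)
  M <- 2; n <- 4
  mult <- sample_multipliers(het_spec(0.2, 0, 11, M * n))
  t <- seq(0, 1.2, by = 1e-3)
  psi <- pmin(t, 1)
  L <- rep(n * 1250, length(t))
  mis <- sapply(c(0, 0.01, 0.1, 1), function(kim) {
    sim <- run_simulation(topology(n, M, kim), p, mult$zeta, mult$xi,
                          psi, L, 1e-3)
    len <- sim$lengths[nrow(sim$lengths), ]
    # z-line node: position after unit pair (1,2) within each myofibril
    z <- c(len[1] + len[2], len[n + 1] + len[n + 2])
    abs(z[1] - z[2])
  })
  expect_true(all(diff(mis) <= 1e-9))
})
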