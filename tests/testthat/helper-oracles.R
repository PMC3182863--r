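# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ paths: closed forms, brute-force search, and direct R
# arithmetic on the rate tables.

# analytic fixed point of the three-state cycle at fixed length/activation:
# per strain bin, the stationary balance
#   f_j D + hr a2_j = (h_j + ga1_j) a1_j
#   h_j a1_j        = (g_j + hr) a2_j
# plus conservation D + sum(a1) + sum(a2) = N has the closed-form solution
# below (bins couple only through the shared detached pool).
analytic_steady_state <- function(params, length, activation = 1) {
  rt <- rate_tables(params)
  hr <- attr(rt, "h_r")
  p <- params
  nav <- p$n0_density * p$zeta * activation * overlap_fraction(length, p)
  # per unit of D:
  a1_per_d <- rt$f / (rt$h + rt$g_a1x - hr * rt$h / (rt$g + hr))
  a2_per_d <- rt$h * a1_per_d / (rt$g + hr)
  D <- nav / (1 + sum(a1_per_d) + sum(a2_per_d))
  list(a1 = a1_per_d * D, a2 = a2_per_d * D, d = D,
       force_active = p$k_cb *
         (sum(a1_per_d * D * rt$x) + sum(a2_per_d * D * (rt$x + p$x_ps))))
}

# brute-force series force balance for three units by nested grid scan on
# the two interior node positions, refined to the requested resolution
brute_force_balance_3 <- function(force_fns, total_length, resolution = 1e-3) {
  obj <- function(l1, l2) {
    l3 <- total_length - l1 - l2
    if (l3 <= 0) return(Inf)
    f <- c(force_fns[[1]](l1), force_fns[[2]](l2), force_fns[[3]](l3))
    max(abs(f - mean(f)))
  }
  c1 <- c2 <- total_length / 3
  width <- total_length / 4
  while (width > resolution / 4) {
    g1 <- seq(c1 - width, c1 + width, length.out = 21)
    g2 <- seq(c2 - width, c2 + width, length.out = 21)
    vals <- outer(g1, g2, Vectorize(obj))
    k <- arrayInd(which.min(vals), dim(vals))
    c1 <- g1[k[1]]; c2 <- g2[k[2]]
    width <- width / 5
  }
  c(c1, c2, total_length - c1 - c2)
}

# small standard configs for tests
test_params <- function(...) hs_params(...)
std_config <- function(n = 50, alpha = 0.2, beta = 0, seed = 1, ...)
  sim_config(topology(n), protocol(...), alpha = alpha, beta = beta,
             seed = seed)
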