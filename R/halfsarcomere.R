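#' Cross-bridge distribution container
#'
#' Holds the bound cross-bridge populations of one half-sarcomere, resolved
#' per strain bin for the pre-powerstroke (A1) and post-powerstroke (A2)
#' attached states, plus a scalar detached pool D. Densities are heads m^-2.
#'
#' @param params an [hs_params()] supplying the strain axis
#' @param a1,a2 numeric vectors of per-bin densities (default all zero)
#' @param d detached pool density (default 0)
#' @return an object of class `xb_distribution`
#' @export
xb_distribution <- function(params, a1 = NULL, a2 = NULL, d = 0) {
  nb <- params$axis$n_bins
  if (is.null(a1)) a1 <- numeric(nb)
  if (is.null(a2)) a2 <- numeric(nb)
  if (length(a1) != nb || length(a2) != nb)
    stop("a1/a2 must have one entry per strain bin")
  if (any(a1 < 0) || any(a2 < 0) || d < 0)
    stop("occupancies must be non-negative")
  structure(list(a1 = as.numeric(a1), a2 = as.numeric(a2), d = as.numeric(d),
                 axis = params$axis),
            class = "xb_distribution")
}

#' Total head count of a distribution
#' @param dist an [xb_distribution()]
#' @return detached + bound head density (heads m^-2)
#' @export
total_heads <- function(dist) dist$d + sum(dist$a1) + sum(dist$a2)

#' Half-sarcomere state
#'
#' Couples a length to a cross-bridge distribution and caches the force
#' decomposition. Total force is always the sum of the active (cross-bridge)
#' and passive (titin-like) components.
#'
#' @param length half-sarcomere length, nm
#' @param dist an [xb_distribution()]
#' @param params an [hs_params()]
#' @return an object of class `hs_state` with cached `force_active`,
#'   `force_passive` and `force_total`
#' @export
hs_state <- function(length, dist, params) {
  if (!is.finite(length) || length <= 0) stop("length must be finite and positive")
  fa <- active_force(dist, params)
  fp <- passive_force(length, params)
  structure(list(length = length, dist = dist,
                 force_active = fa, force_passive = fp,
                 force_total = fa + fp),
            class = "hs_state")
}

#' Filament overlap fraction
#'
#' Piecewise-linear proportion of myosin heads able to interact with actin at
#' a given half-sarcomere length: zero at very short lengths, rising linearly
#' to a plateau of 1, and falling linearly to zero where thick and thin
#' filaments no longer overlap. Continuous everywhere.
#'
#' @param length half-sarcomere length(s), nm (positive, finite)
#' @param params an [hs_params()]
#' @return overlap fraction(s) in \[0, 1\]
#' @export
overlap_fraction <- function(length, params) {
  stopifnot(inherits(params, "hs_params"))
  if (!all(is.finite(length)) || any(length <= 0))
    stop("length must be finite and positive")
  cpp_overlap_fraction(as.numeric(length), pars_to_c(params))
}

#' Available myosin heads
#'
#' The head density available to cycle:
#' `n0_density * zeta * activation * overlap_fraction(length)`.
#' When this quantity changes between time steps (activation ramp, overlap
#' change), the integrator rescales the detached and bound pools
#' proportionally so that their total matches the new availability.
#'
#' @param length half-sarcomere length, nm
#' @param activation activated fraction of binding sites, in \[0, 1\]
#' @param params an [hs_params()]
#' @return available head density, heads m^-2
#' @export
n_available <- function(length, activation, params) {
  if (!all(is.finite(activation)) || any(activation < 0) || any(activation > 1))
    stop("activation must lie in [0, 1]")
  params$n0_density * params$zeta * activation * overlap_fraction(length, params)
}

#' Passive force of a half-sarcomere
#'
#' Exponential passive elasticity
#' `xi * sigma_p * (exp((l - l0)/lambda) - 1)` for `l >= l0`, continued
#' linearly below `l0` with matched slope. Strictly increasing in length and
#' zero at `l0`.
#'
#' @inheritParams overlap_fraction
#' @return passive stress, N m^-2
#' @export
passive_force <- function(length, params) {
  stopifnot(inherits(params, "hs_params"))
  if (!all(is.finite(length)) || any(length <= 0))
    stop("length must be finite and positive")
  cpp_passive_force(as.numeric(length), params$xi, pars_to_c(params))
}

#' Active (cross-bridge) force
#'
#' Huxley-style population force: each A1 bridge contributes its elastic
#' strain `x`, each A2 bridge `x + x_ps` (the powerstroke displacement), all
#' scaled by the cross-bridge stiffness. Positive values are tensile.
#'
#' @param dist an [xb_distribution()]
#' @param params an [hs_params()] (its strain axis must match the
#'   distribution's)
#' @return active stress, N m^-2
#' @export
active_force <- function(dist, params) {
  stopifnot(inherits(dist, "xb_distribution"), inherits(params, "hs_params"))
  if (dist$axis$n_bins != params$axis$n_bins ||
      dist$axis$x_min != params$axis$x_min ||
      dist$axis$x_max != params$axis$x_max)
    stop("strain axis of distribution does not match params")
  cpp_active_force(dist$a1, dist$a2, pars_to_c(params))
}

#' One kinetics step
#'
#' Rescales the pools to the current available-head count and then applies
#' one step of the three-state cycle: strain-localized attachment D -> A1,
#' strain-dependent powerstroke A1 <-> A2, and strain-promoted detachment
#' from both attached states. Inflows are frozen at the step start while
#' exits are integrated exactly (integrating-factor update), so the step is
#' stable and positivity-preserving for arbitrarily steep detachment and its
#' fixed point is the exact steady state of the underlying rate equations.
#' Mass is conserved by charging the net bound-pool change to the detached
#' pool; the `clipped` attribute reports the (normally zero) mass clipped at
#' negativity.
#'
#' @param state an [hs_state()]
#' @param activation activated site fraction in \[0, 1\]
#' @param dt time step, s; the explicit attachment flux requires
#'   `dt * total attachment rate < 1`
#' @param params an [hs_params()]
#' @return the updated [xb_distribution()], with attribute `clipped`
#' @export
kinetics_step <- function(state, activation, dt, params) {
  stopifnot(inherits(state, "hs_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  nav <- n_available(state$length, activation, params)
  dist <- rescale_pools(state$dist, nav)
  out <- cpp_kinetics_step(dist$a1, dist$a2, dist$d, dt, pars_to_c(params))
  res <- xb_distribution(params, out$a1, out$a2, out$d)
  attr(res, "clipped") <- out$clipped
  res
}

#' Proportional pool rescaling
#'
#' Conservative closure used when the available-head count changes: detached
#' and bound pools are scaled by a common factor so their total matches the
#' new availability. If the distribution is empty, all new heads enter the
#' detached pool.
#'
#' @param dist an [xb_distribution()]
#' @param n_new new available head density, heads m^-2
#' @return rescaled [xb_distribution()]
#' @export
rescale_pools <- function(dist, n_new) {
  tot <- total_heads(dist)
  if (n_new <= 0) {
    dist$a1[] <- 0; dist$a2[] <- 0; dist$d <- 0
  } else if (tot <= 0) {
    dist$d <- n_new
  } else {
    f <- n_new / tot
    dist$a1 <- dist$a1 * f; dist$a2 <- dist$a2 * f; dist$d <- dist$d * f
  }
  dist
}

#' Strain advection of bound cross-bridges
#'
#' When a half-sarcomere changes length by `delta_length`, every bound head
#' keeps its attachment point, so its elastic strain changes by the same
#' amount: the A1 and A2 profiles are translated along the strain axis by
#' conservative linear interpolation. Totals are conserved; mass that would
#' leave the axis range is an error here (the axis is sized so this stays
#' negligible; inside the integrator, a unit that jumps far during a "pop"
#' instead has such bridges forcibly detached into the D pool).
#'
#' @param dist an [xb_distribution()]
#' @param delta_length length change, nm; must be smaller in magnitude than
#'   half the axis range
#' @param params an [hs_params()]
#' @return the shifted [xb_distribution()]
#' @export
shift_distribution <- function(dist, delta_length, params) {
  stopifnot(inherits(dist, "xb_distribution"))
  if (!is.finite(delta_length)) stop("delta_length must be finite")
  out <- cpp_shift_distribution(dist$a1, dist$a2, delta_length,
                                pars_to_c(params))
  res <- xb_distribution(params, out$a1, out$a2, dist$d)
  attr(res, "lost") <- out$lost
  res
}

#' Instantaneous stiffness of a half-sarcomere
#'
#' Derivative of total force with respect to length holding the bound
#' population fixed: the cross-bridge term `k_cb * (bound heads)` plus the
#' slope of the passive law. This is the quantity the force-balance Newton
#' solver uses as its Jacobian diagonal.
#'
#' @param state an [hs_state()]
#' @param params an [hs_params()]
#' @return stiffness, N m^-2 per nm
#' @export
instantaneous_stiffness <- function(state, params) {
  stopifnot(inherits(state, "hs_state"))
  cpp_instantaneous_stiffness(state$dist$a1, state$dist$a2,
                              state$length, params$xi, pars_to_c(params))
}

#' Relax a half-sarcomere to its kinetic steady state
#'
#' Holds length and activation fixed and iterates the kinetics until the
#' largest per-step change relative to the available head count falls below
#' `tol`. The fixed point is unique and independent of the initial
#' occupancy.
#'
#' @param length half-sarcomere length, nm
#' @param params an [hs_params()]
#' @param activation activated site fraction (default 1)
#' @param dt iteration step, s
#' @param tol relative per-step change threshold
#' @param max_steps iteration cap
#' @return a list with the settled `dist` ([xb_distribution()]),
#'   `force_active`, `force_passive`, `force_total`, `steps`, `converged`
#' @export
settle_halfsarcomere <- function(length, params, activation = 1,
                                 dt = 1e-3, tol = 1e-8, max_steps = 2e5) {
  stopifnot(inherits(params, "hs_params"))
  out <- cpp_settle(length, params$zeta, params$xi, activation,
                    dt, tol, as.integer(max_steps), pars_to_c(params))
  list(dist = xb_distribution(params, out$a1, out$a2, out$d),
       force_active = out$force_active,
       force_passive = out$force_passive,
       force_total = out$force_total,
       steps = out$steps, converged = out$converged)
}
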