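#' Network topology
#'
#' Series/parallel arrangement of half-sarcomeres: `n_series` units in series
#' per myofibril, `n_myofibrils` myofibrils in parallel, optionally coupled
#' at z-lines by linear springs of stiffness `k_im` (stress per nm of z-line
#' misregistration, applied between corresponding z-lines of every myofibril
#' pair). Adjacent half-sarcomere pairs form sarcomeres, so z-lines sit at
#' even series node indices.
#'
#' @param n_series half-sarcomeres in series (>= 1)
#' @param n_myofibrils parallel myofibrils (>= 1)
#' @param k_im inter-myofibril z-line coupling stiffness (>= 0), N m^-2 nm^-1
#' @return an object of class `topology`
#' @export
topology <- function(n_series = 50, n_myofibrils = 1, k_im = 0) {
  n_series <- as.integer(n_series); n_myofibrils <- as.integer(n_myofibrils)
  if (n_series < 1 || n_myofibrils < 1) stop("topology counts must be >= 1")
  if (!is.numeric(k_im) || k_im < 0) stop("k_im must be >= 0")
  structure(list(n_series = n_series, n_myofibrils = n_myofibrils,
                 k_im = k_im),
            class = "topology")
}

#' Assemble a half-sarcomere network
#'
#' Creates the state of a series chain (or lattice) of half-sarcomeres. All
#' units start at the same length with empty (all-detached, zero-head)
#' cross-bridge distributions; heterogeneity enters only through the
#' per-unit `zeta` and `xi` multipliers.
#'
#' @param topo a [topology()]
#' @param params an [hs_params()] shared by all units
#' @param zeta,xi per-unit multiplier vectors (length
#'   `n_series * n_myofibrils`, myofibril-major order)
#' @param initial_hs_length starting half-sarcomere length, nm
#' @return an object of class `sarco_network`
#' @export
make_network <- function(topo, params, zeta, xi, initial_hs_length = 1200) {
  stopifnot(inherits(topo, "topology"), inherits(params, "hs_params"))
  U <- topo$n_series * topo$n_myofibrils
  if (length(zeta) != U || length(xi) != U)
    stop("zeta and xi must have one entry per unit")
  if (any(zeta <= 0) || any(xi <= 0)) stop("multipliers must be positive")
  nb <- params$axis$n_bins
  structure(list(
    topology = topo, params = params,
    zeta = as.numeric(zeta), xi = as.numeric(xi),
    a1 = matrix(0, nb, U), a2 = matrix(0, nb, U), d = numeric(U),
    lengths = rep(initial_hs_length, U),
    total_length = initial_hs_length * topo$n_series),
    class = "sarco_network")
}

#' Solve the series/lattice force balance
#'
#' Repartitions the imposed total length among the half-sarcomeres so that
#' tension is equal at every series connection (and, in a lattice, so that
#' the net force including z-line coupling springs vanishes at every interior
#' node). A damped Newton iteration on interior node positions is used, with
#' the analytic tridiagonal (plus coupling) Jacobian built from each unit's
#' instantaneous stiffness; bound distributions are advected by each unit's
#' length change.
#'
#' @param network a network from [make_network()]
#' @param new_total_length imposed total length per myofibril, nm (within
#'   0.5x to 2x the current total)
#' @return the updated network, with attributes `iterations` and `forces`
#' @export
solve_force_balance <- function(network, new_total_length) {
  stopifnot(inherits(network, "sarco_network"))
  if (!is.finite(new_total_length) ||
      new_total_length < 0.5 * network$total_length ||
      new_total_length > 2 * network$total_length)
    stop("new_total_length outside the sane [0.5, 2]x range of the current length")
  out <- cpp_solve_force_balance(
    network$a1, network$a2, network$d, network$lengths,
    network$zeta, network$xi,
    network$topology$n_myofibrils, network$topology$k_im,
    new_total_length, pars_to_c(network$params),
    tol_abs = 1e-4, tol_rel = 1e-6)
  network$a1 <- out$a1; network$a2 <- out$a2; network$d <- out$d
  network$lengths <- as.numeric(out$lengths)
  network$total_length <- new_total_length
  attr(network, "iterations") <- out$iterations
  attr(network, "forces") <- as.numeric(out$forces)
  network
}

#' One operator-split integration step
#'
#' Per unit: update the available-head pool for the current activation and
#' length (proportional rescale), apply one explicit kinetics step; then
#' re-balance forces at the target total length, advecting bound
#' distributions by the resulting length changes.
#'
#' @param network a network from [make_network()]
#' @param L_target imposed total length per myofibril, nm
#' @param activation activated site fraction in \[0, 1\]
#' @param dt time step, s
#' @return the updated network (attributes as in [solve_force_balance()])
#' @export
integrate_step <- function(network, L_target, activation, dt) {
  stopifnot(inherits(network, "sarco_network"))
  if (activation < 0 || activation > 1) stop("activation must lie in [0, 1]")
  p <- network$params
  pc <- pars_to_c(p)
  U <- length(network$d)
  ov <- cpp_overlap_fraction(network$lengths, pc)
  for (u in seq_len(U)) {
    nav <- p$n0_density * network$zeta[u] * activation * ov[u]
    tot <- network$d[u] + sum(network$a1[, u]) + sum(network$a2[, u])
    if (nav <= 0) {
      network$a1[, u] <- 0; network$a2[, u] <- 0; network$d[u] <- 0
    } else if (tot <= 0) {
      network$d[u] <- nav
    } else {
      f <- nav / tot
      network$a1[, u] <- network$a1[, u] * f
      network$a2[, u] <- network$a2[, u] * f
      network$d[u] <- network$d[u] * f
    }
    st <- cpp_kinetics_step(network$a1[, u], network$a2[, u], network$d[u],
                            dt, pc)
    network$a1[, u] <- st$a1; network$a2[, u] <- st$a2; network$d[u] <- st$d
  }
  solve_force_balance(network, L_target)
}

#' Run a full simulation
#'
#' Integrates a half-sarcomere network under imposed activation and total
#' length trajectories using operator splitting (kinetics, then force
#' balance) at fixed `dt`. The fast C++ core is used throughout; the force
#' trace is recorded at every step and per-unit lengths at `record_every`
#' seconds.
#'
#' @param topo a [topology()]
#' @param params an [hs_params()]
#' @param zeta,xi per-unit multiplier vectors
#' @param psi activation trace, one value per time step (including t = 0)
#' @param L_total total-length trace per myofibril, nm, same length as `psi`
#' @param dt time step, s
#' @param initial_hs_length starting half-sarcomere length, nm (defaults to
#'   `L_total[1] / n_series`)
#' @param record_every interval for recording per-unit lengths, s
#' @param seed seed recorded in the metadata (the integrator itself is
#'   deterministic)
#' @return an object of class `sarco_sim`: time/force traces, a per-unit
#'   length matrix at `rec_time`, and metadata (seed, clipped mass, mass
#'   ripped off the strain axis and returned to the detached pool, solver
#'   iterations)
#' @export
run_simulation <- function(topo, params, zeta, xi, psi, L_total, dt,
                           initial_hs_length = NULL, record_every = 0.01,
                           seed = NA_integer_) {
  stopifnot(inherits(topo, "topology"), inherits(params, "hs_params"))
  if (length(psi) != length(L_total))
    stop("psi and L_total must have the same length")
  meta <- list(seed = seed, topology = topo, dt = dt,
               config_hash = config_hash(list(topo, zeta, xi, dt,
                                              utils::head(L_total, 5))))
  if (length(psi) == 0) {
    return(structure(list(time = numeric(0), force = numeric(0),
                          rec_time = numeric(0),
                          lengths = matrix(0, 0, length(zeta)),
                          psi = numeric(0), L_total = numeric(0),
                          clipped = 0, ripped = 0, solver_iterations = 0,
                          meta = meta),
                     class = "sarco_sim"))
  }
  stride <- max(1L, as.integer(round(record_every / dt)))
  out <- cpp_run_simulation(psi, L_total, dt,
                            topo$n_series, topo$n_myofibrils, topo$k_im,
                            zeta, xi, pars_to_c(params),
                            stride, tol_abs = 1e-4, tol_rel = 1e-6)
  structure(list(time = out$time, force = out$force,
                 rec_time = out$rec_time, lengths = out$lengths,
                 psi = psi, L_total = L_total,
                 clipped = out$clipped, ripped = out$ripped,
                 max_move = out$max_move, nsub = out$nsub,
                 solver_iterations = out$solver_iterations,
                 final_d = out$final_d, final_a1 = out$final_a1,
                 final_a2 = out$final_a2,
                 meta = meta),
            class = "sarco_sim")
}

# cheap polynomial hash of a deparsed object, for provenance stamps
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.sarco_sim <- function(x, ...) {
  cat("<sarco_sim>", length(x$time), "steps,",
      x$meta$topology$n_series, "units x",
      x$meta$topology$n_myofibrils, "myofibril(s)\n")
  if (length(x$force))
    cat("  final force:", format(x$force[length(x$force)], digits = 6),
        "N m^-2\n")
  invisible(x)
}

#' Tidy per-unit length records
#'
#' @param x a `sarco_sim`
#' @param row.names,optional,... ignored (S3 signature)
#' @return data.frame with columns `time`, `myofibril`, `unit`, `length`
#' @export
as.data.frame.sarco_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  topo <- x$meta$topology
  U <- topo$n_series * topo$n_myofibrils
  data.frame(
    time = rep(x$rec_time, U),
    myofibril = rep(rep(seq_len(topo$n_myofibrils), each = topo$n_series),
                    each = length(x$rec_time)),
    unit = rep(rep(seq_len(topo$n_series), topo$n_myofibrils),
               each = length(x$rec_time)),
    length = as.vector(x$lengths))
}
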