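#' Ramp-and-hold protocol definition
#'
#' Defines the paired trial design: the fiber is activated linearly over
#' `activation_ramp_duration`, held for `pre_stretch_hold`, stretched at
#' constant velocity to the final length, and then held. The isometric
#' companion trial is activated identically but sits at the final length
#' throughout. Stretch magnitude and velocity are expressed relative to the
#' *initial* (pre-stretch reference) fiber length L0; the implied
#' final-length-relative magnitude is also reported in the protocol object.
#'
#' @param activation_ramp_duration s, linear 0 -> 1 activation ramp
#' @param pre_stretch_hold s, isometric hold between ramp end and stretch
#' @param stretch_magnitude fraction of the initial length L0 (e.g. 0.08)
#' @param stretch_velocity initial lengths (L0) per second (e.g. 0.1)
#' @param post_stretch_hold s, hold after the stretch ends (must exceed
#'   `t_ss`)
#' @param dt integration step, s
#' @param initial_mean_hs_length nm; ignored if `final_mean_hs_length` given
#' @param final_mean_hs_length nm, or `NULL` to derive it from the initial
#'   length and the magnitude
#' @param t_ss s after stretch end at which enhancement is evaluated
#' @return an object of class `protocol` with derived fields
#'   `stretch_duration`, `ramp_start` (stretch onset time), `stretch_end`,
#'   `total_duration`, and both length conventions
#' @export
protocol <- function(activation_ramp_duration = 1,
                     pre_stretch_hold = 1,
                     stretch_magnitude = 0.08,
                     stretch_velocity = 0.1,
                     post_stretch_hold = 7,
                     dt = 1e-3,
                     initial_mean_hs_length = 1200,
                     final_mean_hs_length = NULL,
                     t_ss = 6) {
  if (any(c(activation_ramp_duration, pre_stretch_hold, post_stretch_hold) < 0))
    stop("durations must be >= 0")
  if (stretch_magnitude < 0 || stretch_magnitude >= 1)
    stop("stretch_magnitude must lie in [0, 1)")
  if (stretch_magnitude > 0 && stretch_velocity <= 0)
    stop("stretch_velocity must be positive for a non-zero stretch")
  if (dt <= 0) stop("dt must be positive")
  if (is.null(final_mean_hs_length)) {
    final_mean_hs_length <- initial_mean_hs_length * (1 + stretch_magnitude)
  } else {
    initial_mean_hs_length <- final_mean_hs_length / (1 + stretch_magnitude)
  }
  stretch_duration <- if (stretch_magnitude > 0)
    stretch_magnitude / stretch_velocity else 0
  ramp_start <- activation_ramp_duration + pre_stretch_hold
  stretch_end <- ramp_start + stretch_duration
  p <- list(activation_ramp_duration = activation_ramp_duration,
            pre_stretch_hold = pre_stretch_hold,
            stretch_magnitude = stretch_magnitude,
            stretch_velocity = stretch_velocity,
            post_stretch_hold = post_stretch_hold,
            dt = dt,
            initial_mean_hs_length = initial_mean_hs_length,
            final_mean_hs_length = final_mean_hs_length,
            t_ss = t_ss,
            stretch_duration = stretch_duration,
            ramp_start = ramp_start,
            stretch_end = stretch_end,
            total_duration = stretch_end + post_stretch_hold,
            magnitude_vs_final =
              (final_mean_hs_length - initial_mean_hs_length) /
              final_mean_hs_length)
  if (p$post_stretch_hold < t_ss)
    stop("post_stretch_hold must be at least t_ss")
  structure(p, class = "protocol")
}

#' Activation time course
#'
#' Linear activation ramp: 0 at t = 0, rising to 1 over the ramp duration,
#' saturated at 1 thereafter (identical for every half-sarcomere).
#'
#' @param t time(s), s (>= 0)
#' @param prot a [protocol()]
#' @return activated fraction(s) in \[0, 1\]
#' @export
activation_trace <- function(t, prot) {
  if (any(t < 0)) stop("t must be >= 0")
  if (prot$activation_ramp_duration == 0) return(rep(1, length(t)))
  pmin(t / prot$activation_ramp_duration, 1)
}

#' Mean half-sarcomere length time course
#'
#' Stretch mode: the initial length until the stretch onset, a
#' constant-velocity ramp to the final length, then constant. Isometric
#' mode: the final length throughout.
#'
#' @param t time(s), s (>= 0)
#' @param prot a [protocol()]
#' @param mode `"stretch"` or `"isometric"`
#' @return mean half-sarcomere length(s), nm (multiply by `n_series` for the
#'   fiber length)
#' @export
length_trace <- function(t, prot, mode = c("stretch", "isometric")) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be >= 0")
  if (mode == "isometric") return(rep(prot$final_mean_hs_length, length(t)))
  v <- prot$stretch_velocity * prot$initial_mean_hs_length  # nm/s, mean-hs scale
  l <- prot$initial_mean_hs_length +
    v * pmin(pmax(t - prot$ramp_start, 0), prot$stretch_duration)
  pmin(l, prot$final_mean_hs_length)
}

#' Simulation configuration
#'
#' Bundles topology, heterogeneity levels, protocol and model parameters
#' into a single reproducible unit of work.
#'
#' @param topo a [topology()]
#' @param prot a [protocol()]
#' @param alpha,beta heterogeneity SDs (see [het_spec()])
#' @param seed master seed
#' @param params an [hs_params()]
#' @param record_every s, per-unit length recording interval
#' @return an object of class `sim_config`
#' @export
sim_config <- function(topo = topology(), prot = protocol(),
                       alpha = 0.2, beta = 0, seed = 1,
                       params = hs_params(), record_every = 0.01) {
  stopifnot(inherits(topo, "topology"), inherits(prot, "protocol"),
            inherits(params, "hs_params"))
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  structure(list(topology = topo, protocol = prot, alpha = alpha,
                 beta = beta, seed = as.integer(seed), params = params,
                 record_every = record_every),
            class = "sim_config")
}

# time grid shared by both trials of a pair
protocol_times <- function(prot) {
  n <- round(prot$total_duration / prot$dt)
  (0:n) * prot$dt
}

#' Run one trial of a configuration
#'
#' @param config a [sim_config()]
#' @param mode `"stretch"` or `"isometric"`
#' @param multipliers optional list with `zeta`, `xi` (defaults to the draw
#'   implied by the config's seed, so paired trials share multipliers)
#' @return a `sarco_sim`
#' @export
run_trial <- function(config, mode = c("stretch", "isometric"),
                      multipliers = NULL) {
  mode <- match.arg(mode)
  topo <- config$topology; prot <- config$protocol
  U <- topo$n_series * topo$n_myofibrils
  if (is.null(multipliers))
    multipliers <- sample_multipliers(
      het_spec(config$alpha, config$beta, config$seed, U))
  t <- protocol_times(prot)
  psi <- activation_trace(t, prot)
  Lhs <- length_trace(t, prot, mode)
  run_simulation(topo, config$params, multipliers$zeta, multipliers$xi,
                 psi, Lhs * topo$n_series, prot$dt,
                 record_every = config$record_every, seed = config$seed)
}

#' Residual force enhancement of a trial pair
#'
#' Evaluates RFE = 100 * (F_stretch - F_iso) / F_iso at `t_ss` seconds after
#' the end of the length change, from two force traces on the protocol's
#' common time grid.
#'
#' @param force_stretch,force_iso force traces (N m^-2), one value per step
#' @param prot the shared [protocol()]
#' @return an object of class `rfe_result` with fields `rfe_percent`,
#'   `t_ss`, `force_stretch`, `force_iso`
#' @export
rfe_from_traces <- function(force_stretch, force_iso, prot) {
  t_eval <- prot$stretch_end + prot$t_ss
  idx <- round(t_eval / prot$dt) + 1
  if (idx > length(force_stretch) || idx > length(force_iso))
    stop("traces end before t_ss after stretch end")
  fs <- force_stretch[idx]; fi <- force_iso[idx]
  structure(list(rfe_percent = 100 * (fs - fi) / fi,
                 t_ss = prot$t_ss, t_eval = t_eval,
                 force_stretch = fs, force_iso = fi),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("RFE = %.2f%% at t_ss = %g s (stretch %.4g vs isometric %.4g N m^-2)\n",
              x$rfe_percent, x$t_ss, x$force_stretch, x$force_iso))
  invisible(x)
}

#' Run a paired ramp-and-hold / isometric trial
#'
#' Runs the stretch trial and its isometric companion with identical
#' multipliers (same seed) and evaluates the enhancement statistic at `t_ss`
#' after the end of the length change.
#'
#' @param config a [sim_config()]
#' @return an object of class `sarco_pair`: `stretch` and `isometric`
#'   `sarco_sim`s plus the `rfe_result` and the config
#' @export
run_protocol_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  topo <- config$topology
  U <- topo$n_series * topo$n_myofibrils
  mult <- sample_multipliers(het_spec(config$alpha, config$beta,
                                      config$seed, U))
  s <- run_trial(config, "stretch", mult)
  i <- run_trial(config, "isometric", mult)
  r <- rfe_from_traces(s$force, i$force, config$protocol)
  r$seed <- config$seed
  structure(list(stretch = s, isometric = i, rfe = r, config = config,
                 multipliers = mult),
            class = "sarco_pair")
}

#' Ensemble-averaged residual force enhancement
#'
#' Runs the paired protocol for `n_seeds` deterministic child seeds of the
#' config's master seed, averages the stretch and isometric force traces
#' across the ensemble on the common time grid, and applies the enhancement
#' statistic to the averaged traces (the per-seed values are also kept).
#'
#' @param config a [sim_config()] (its `seed` acts as the master seed)
#' @param n_seeds ensemble size
#' @return an object of class `rfe_ensemble`: `rfe_percent` (from averaged
#'   traces), `per_seed` RFE vector, mean traces, and the time grid
#' @export
ensemble_rfe <- function(config, n_seeds = 10) {
  members <- make_ensemble(config, n_seeds)
  prot <- config$protocol
  fs <- NULL; fi <- NULL
  per_seed <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    pair <- run_protocol_pair(members[[k]])
    if (is.null(fs)) { fs <- pair$stretch$force; fi <- pair$isometric$force }
    else { fs <- fs + pair$stretch$force; fi <- fi + pair$isometric$force }
    per_seed[k] <- pair$rfe$rfe_percent
  }
  fs <- fs / n_seeds; fi <- fi / n_seeds
  r <- rfe_from_traces(fs, fi, prot)
  structure(list(rfe_percent = r$rfe_percent, rfe = r, per_seed = per_seed,
                 force_stretch_mean = fs, force_iso_mean = fi,
                 time = protocol_times(prot), config = config,
                 n_seeds = n_seeds, master_seed = config$seed),
            class = "rfe_ensemble")
}

#' @export
print.rfe_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble RFE = %.2f%% (n = %d seeds; per-seed mean %.2f%%, SD %.2f%%)\n",
              x$rfe_percent, x$n_seeds, mean(x$per_seed), sd(x$per_seed)))
  invisible(x)
}

#' Steady-state length-tension curve
#'
#' Holds a fully activated half-sarcomere at each grid length until its
#' cross-bridge distribution reaches steady state (force drift below 0.01%
#' per second, settle capped at 60 s of model time) and records total
#' (active + passive) tension. Limb labels follow the overlap geometry:
#' ascending below the plateau interval, descending above it.
#'
#' @param params an [hs_params()]
#' @param length_grid half-sarcomere lengths, nm (within \[1000, 1700\])
#' @param activation activated fraction (default 1)
#' @param dt settle step, s
#' @return data.frame with columns `length`, `tension`, `active`, `passive`,
#'   `limb`, `converged`
#' @export
steady_state_length_tension <- function(params, length_grid,
                                        activation = 1, dt = 1e-3) {
  stopifnot(inherits(params, "hs_params"))
  if (any(length_grid < 1000 | length_grid > 1700))
    stop("length_grid must lie within [1000, 1700] nm")
  # drift < 0.01%/s of the head count <=> per-step relative change < 1e-4*dt
  tol <- 1e-4 * dt
  rows <- lapply(length_grid, function(l) {
    s <- settle_halfsarcomere(l, params, activation, dt = dt, tol = tol,
                              max_steps = round(60 / dt))
    data.frame(length = l, tension = s$force_total, active = s$force_active,
               passive = s$force_passive, converged = s$converged)
  })
  out <- do.call(rbind, rows)
  out$limb <- ifelse(out$length < params$overlap_plateau_lo, "ascending",
                     ifelse(out$length <= params$overlap_plateau_hi,
                            "plateau", "descending"))
  out
}
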