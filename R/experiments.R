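#' Sweep specification
#'
#' @param variable one of `"velocity"`, `"magnitude"`, `"final_length"`,
#'   `"alpha"`, `"beta"`, `"k_im"`
#' @param grid non-empty numeric vector of values
#' @param seeds_per_point ensemble size per grid value (>= 1)
#' @param base_config a [sim_config()] supplying everything else
#' @return an object of class `sweep_spec`
#' @export
sweep_spec <- function(variable, grid, seeds_per_point = 10,
                       base_config = sim_config()) {
  variable <- match.arg(variable, c("velocity", "magnitude", "final_length",
                                    "alpha", "beta", "k_im"))
  if (length(grid) == 0) stop("grid must be non-empty")
  if (seeds_per_point < 1) stop("seeds_per_point must be >= 1")
  structure(list(variable = variable, grid = grid,
                 seeds_per_point = as.integer(seeds_per_point),
                 base_config = base_config),
            class = "sweep_spec")
}

apply_sweep_value <- function(config, variable, value) {
  prot <- config$protocol
  switch(variable,
    velocity = {
      config$protocol <- protocol(
        activation_ramp_duration = prot$activation_ramp_duration,
        pre_stretch_hold = prot$pre_stretch_hold,
        stretch_magnitude = prot$stretch_magnitude,
        stretch_velocity = value,
        post_stretch_hold = prot$post_stretch_hold, dt = prot$dt,
        initial_mean_hs_length = prot$initial_mean_hs_length,
        t_ss = prot$t_ss)
    },
    magnitude = {
      config$protocol <- protocol(
        activation_ramp_duration = prot$activation_ramp_duration,
        pre_stretch_hold = prot$pre_stretch_hold,
        stretch_magnitude = value,
        stretch_velocity = prot$stretch_velocity,
        post_stretch_hold = prot$post_stretch_hold, dt = prot$dt,
        final_mean_hs_length = prot$final_mean_hs_length,
        t_ss = prot$t_ss)
    },
    final_length = {
      config$protocol <- protocol(
        activation_ramp_duration = prot$activation_ramp_duration,
        pre_stretch_hold = prot$pre_stretch_hold,
        stretch_magnitude = prot$stretch_magnitude,
        stretch_velocity = prot$stretch_velocity,
        post_stretch_hold = prot$post_stretch_hold, dt = prot$dt,
        final_mean_hs_length = value,
        t_ss = prot$t_ss)
    },
    alpha = { config$alpha <- value },
    beta = { config$beta <- value },
    k_im = {
      config$topology <- topology(config$topology$n_series,
                                  config$topology$n_myofibrils, value)
    })
  config
}

run_sweep <- function(spec) {
  rows <- lapply(spec$grid, function(v) {
    cfg <- apply_sweep_value(spec$base_config, spec$variable, v)
    ens <- ensemble_rfe(cfg, spec$seeds_per_point)
    data.frame(value = v, rfe_percent = ens$rfe_percent,
               rfe_per_seed_mean = mean(ens$per_seed),
               rfe_per_seed_sd = sd(ens$per_seed),
               force_stretch = ens$rfe$force_stretch,
               force_iso = ens$rfe$force_iso)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- spec$variable
  out
}

#' Stretch-velocity dependence of enhancement
#'
#' Runs the paired protocol at a fixed 8% magnitude across a grid of stretch
#' velocities and reports the ensemble RFE per velocity together with the
#' max/min RFE ratio (a flat profile signals velocity independence).
#'
#' @param spec a [sweep_spec()] with `variable = "velocity"`
#' @return data.frame of RFE per velocity, with attribute `max_min_ratio`
#' @export
velocity_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$variable == "velocity")
  out <- run_sweep(spec)
  attr(out, "max_min_ratio") <- max(out$rfe_percent) / min(out$rfe_percent)
  out
}

#' Stretch-magnitude dependence of enhancement
#'
#' Sweeps the stretch magnitude at fixed velocity (final length held fixed
#' so all trials are compared at the same length) and fits least-squares
#' lines RFE ~ magnitude, through the origin and with an intercept.
#'
#' @param spec a [sweep_spec()] with `variable = "magnitude"` (grid given as
#'   fractions, e.g. 0.02 for a 2% stretch)
#' @return data.frame of RFE per magnitude, with attributes
#'   `slope_through_origin`, `slope_with_intercept`, `intercept`,
#'   `r_squared` (slopes in % RFE per % stretch)
#' @export
magnitude_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$variable == "magnitude")
  if (length(unique(spec$grid)) < 2)
    stop("magnitude sweep needs at least two distinct magnitudes")
  out <- run_sweep(spec)
  mag_pct <- 100 * out$magnitude
  f0 <- lm(rfe_percent ~ 0 + mag_pct, data = cbind(out, mag_pct = mag_pct))
  f1 <- lm(rfe_percent ~ mag_pct, data = cbind(out, mag_pct = mag_pct))
  attr(out, "slope_through_origin") <- unname(coef(f0)[1])
  attr(out, "slope_with_intercept") <- unname(coef(f1)[2])
  attr(out, "intercept") <- unname(coef(f1)[1])
  attr(out, "r_squared") <- summary(f1)$r.squared
  out
}

#' Enhancement across the length-tension curve
#'
#' Runs the standard stretch at a set of final mean half-sarcomere lengths
#' spanning the ascending limb, plateau, and descending limb, and reports
#' RFE and the enhanced tension at each, plus whether enhanced tension
#' exceeds the isometric curve maximum.
#'
#' @param spec a [sweep_spec()] with `variable = "final_length"` (grid in nm)
#' @return data.frame with RFE, isometric and enhanced tension, and limb
#'   label per final length; attribute `curve_max` holds the isometric
#'   optimum of the homogeneous unit
#' @export
length_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$variable == "final_length")
  out <- run_sweep(spec)
  p <- spec$base_config$params
  out$limb <- ifelse(out$final_length < p$overlap_plateau_lo, "ascending",
                     ifelse(out$final_length <= p$overlap_plateau_hi,
                            "plateau", "descending"))
  lt <- steady_state_length_tension(
    p, seq(p$overlap_plateau_lo, p$overlap_plateau_hi, length.out = 7))
  attr(out, "curve_max") <- max(lt$tension)
  out$enhanced_exceeds_optimum <- out$force_stretch > attr(out, "curve_max")
  out
}

#' Sensitivity of enhancement to strength heterogeneity
#'
#' @param spec a [sweep_spec()] with `variable = "alpha"` (a log-spaced grid
#'   is the intended use)
#' @return data.frame of RFE per alpha
#' @export
alpha_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$variable == "alpha")
  run_sweep(spec)
}

#' Joint passive/active heterogeneity grid
#'
#' Crosses beta (passive variability) with alpha (strength variability) and
#' reports the ensemble RFE for every combination.
#'
#' @param beta_grid,alpha_grid heterogeneity SD grids
#' @param seeds_per_point ensemble size per cell
#' @param base_config a [sim_config()]
#' @return data.frame with columns `beta`, `alpha`, `rfe_percent`, ...
#' @export
beta_alpha_grid <- function(beta_grid = c(0, 0.1, 0.2),
                            alpha_grid = c(0, 0.1, 0.2),
                            seeds_per_point = 10,
                            base_config = sim_config()) {
  rows <- list()
  for (b in beta_grid) for (a in alpha_grid) {
    cfg <- base_config; cfg$alpha <- a; cfg$beta <- b
    ens <- ensemble_rfe(cfg, seeds_per_point)
    rows[[length(rows) + 1]] <-
      data.frame(beta = b, alpha = a, rfe_percent = ens$rfe_percent,
                 rfe_per_seed_sd = sd(ens$per_seed))
  }
  do.call(rbind, rows)
}

#' Multi-myofibril lattice experiment
#'
#' Builds a lattice of parallel myofibrils whose z-lines are coupled by
#' springs of stiffness `k_im`, applies a slow ramp stretch (default 8% over
#' 4 s), and reports the ensemble RFE together with the relative (CV)
#' variation of whole-sarcomere versus half-sarcomere lengths at the end of
#' the record. Sarcomeres are adjacent half-sarcomere pairs.
#'
#' @param n_myofibrils parallel myofibrils
#' @param n_series half-sarcomeres in series per myofibril
#' @param k_im z-line coupling stiffness
#' @param alpha strength heterogeneity SD
#' @param stretch_magnitude,stretch_duration stretch: fraction of final
#'   length and ramp time in s (velocity = magnitude / duration)
#' @param n_seeds ensemble size
#' @param seed master seed
#' @param base_params an [hs_params()]
#' @return a list: `rfe` (ensemble), `variation` data.frame with the
#'   half-sarcomere and sarcomere length CVs over time (last member), and
#'   the per-cell config
#' @export
myofibril_lattice_experiment <- function(n_myofibrils = 6, n_series = 50,
                                         k_im = 0.1, alpha = 0.2,
                                         stretch_magnitude = 0.08,
                                         stretch_duration = 4,
                                         n_seeds = 4, seed = 1,
                                         base_params = hs_params()) {
  prot <- protocol(stretch_magnitude = stretch_magnitude,
                   stretch_velocity = stretch_magnitude / stretch_duration)
  cfg <- sim_config(topology(n_series, n_myofibrils, k_im), prot,
                    alpha = alpha, beta = 0, seed = seed,
                    params = base_params)
  ens <- ensemble_rfe(cfg, n_seeds)
  # length-variation statistics from one member's stretch trial
  pair <- run_protocol_pair(make_ensemble(cfg, 1)[[1]])
  lens <- pair$stretch$lengths  # nrec x (M*n)
  M <- n_myofibrils; n <- n_series
  sarc <- matrix(0, nrow(lens), M * (n %/% 2))
  k <- 0
  for (m in seq_len(M)) for (s in seq_len(n %/% 2)) {
    k <- k + 1
    sarc[, k] <- lens[, (m - 1) * n + 2 * s - 1] + lens[, (m - 1) * n + 2 * s]
  }
  cv <- function(x) sd(x) / mean(x)
  variation <- data.frame(
    time = pair$stretch$rec_time,
    hs_cv = apply(lens, 1, cv),
    sarcomere_cv = apply(sarc, 1, cv))
  list(rfe = ens, variation = variation, config = cfg, pair = pair)
}

#' Two dissimilar half-sarcomeres: mechanism demonstration
#'
#' Runs the paired stretch protocol on a two-unit chain with unequal
#' strength multipliers and returns the trajectories of each unit on its
#' length-tension plane, together with both units' steady-state
#' length-tension curves and snapshots at 1 s post-stretch and late in the
#' hold. The weak unit is expected to sit above its steady-state curve
#' shortly after stretch while the strong unit sits below, and the weak unit
#' keeps lengthening while the strong one shortens.
#'
#' @param zeta_weak,zeta_strong strength multipliers of the two units
#' @param post_stretch_hold s (use >= 35 to capture the late snapshot)
#' @param params an [hs_params()]
#' @param lt_grid length grid (nm) for the steady-state curves
#' @return a list: `trajectory` (time, per-unit length, chain tension),
#'   `curves` (per-unit steady-state length-tension), `snapshots`, and the
#'   underlying `pair`
#' @export
two_hs_demo <- function(zeta_weak = 0.9, zeta_strong = 1.1,
                        post_stretch_hold = 40, params = hs_params(),
                        lt_grid = seq(1000, 1690, by = 10)) {
  stopifnot(zeta_weak < zeta_strong)
  prot <- protocol(post_stretch_hold = post_stretch_hold)
  cfg <- sim_config(topology(n_series = 2), prot, alpha = 0, beta = 0,
                    seed = 1, params = params)
  mult <- list(zeta = c(zeta_strong, zeta_weak), xi = c(1, 1))
  s <- run_trial(cfg, "stretch", mult)
  i <- run_trial(cfg, "isometric", mult)
  r <- rfe_from_traces(s$force, i$force, prot)
  traj <- data.frame(time = s$rec_time,
                     length_strong = s$lengths[, 1],
                     length_weak = s$lengths[, 2],
                     tension = s$force[match(round(s$rec_time, 9),
                                             round(s$time, 9))])
  curves <- do.call(rbind, lapply(
    c(strong = zeta_strong, weak = zeta_weak),
    function(z) {
      p <- params; p$zeta <- z
      lt <- steady_state_length_tension(p, lt_grid)
      lt$unit <- if (z == zeta_strong) "strong" else "weak"
      lt
    }))
  snap <- function(t) {
    k <- which.min(abs(traj$time - t))
    data.frame(time = traj$time[k],
               length_strong = traj$length_strong[k],
               length_weak = traj$length_weak[k],
               tension = traj$tension[k])
  }
  snapshots <- rbind(cbind(when = "post_stretch_1s",
                           snap(prot$stretch_end + 1)),
                     cbind(when = "late",
                           snap(prot$total_duration - 0.5)))
  list(trajectory = traj, curves = curves, snapshots = snapshots,
       rfe = r, pair = list(stretch = s, isometric = i))
}

#' Time for stretched and isometric tensions to converge
#'
#' First time after stretch end at which the relative difference between
#' the stretched and isometric force traces falls below `threshold` and
#' stays below it for the rest of the record.
#'
#' @param force_stretch,force_iso force traces on the protocol's time grid
#' @param prot the shared [protocol()]
#' @param threshold relative difference threshold (default 0.01)
#' @return time in s after stretch end; `Inf` if the traces never converge
#'   within the record (reported as "> horizon")
#' @export
convergence_time <- function(force_stretch, force_iso, prot,
                             threshold = 0.01) {
  t <- protocol_times(prot)
  rel <- abs(force_stretch - force_iso) / pmax(force_iso, .Machine$double.eps)
  after <- t >= prot$stretch_end
  rel <- rel[after]; ta <- t[after]
  below <- rev(cumprod(rev(rel < threshold))) == 1  # below from here onward
  if (!any(below)) return(Inf)
  ta[which(below)[1]] - prot$stretch_end
}
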