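#' Discrete strain axis for cross-bridge distributions
#'
#' Bound cross-bridge populations are resolved over a uniform grid of elastic
#' strain values (nm). The axis must bracket zero and be wide enough that the
#' occupancy of the boundary bins stays negligible (< 1e-6 of the bound
#' population) in every protocol that is run on it; the integrator enforces
#' this by refusing advection steps that push mass off the grid.
#'
#' @param x_min,x_max strain range in nm (`x_min < 0 < x_max`)
#' @param n_bins number of grid points (uniform spacing)
#' @return an object of class `strain_axis` with fields `x_min`, `x_max`,
#'   `n_bins`, `bin_width` and the grid `x`
#' @export
strain_axis <- function(x_min = -20, x_max = 20, n_bins = 161) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), is.numeric(n_bins))
  if (!is.finite(x_min) || !is.finite(x_max) || x_min >= 0 || x_max <= 0)
    stop("strain axis must satisfy x_min < 0 < x_max")
  n_bins <- as.integer(n_bins)
  if (n_bins < 3) stop("strain axis needs at least 3 bins")
  bw <- (x_max - x_min) / (n_bins - 1)
  structure(
    list(x_min = x_min, x_max = x_max, n_bins = n_bins, bin_width = bw,
         x = seq(x_min, x_max, length.out = n_bins)),
    class = "strain_axis")
}

#' Half-sarcomere model parameters
#'
#' Bundles the mechanical and kinetic constants of a single half-sarcomere:
#' the myosin head density and its strength multiplier, the exponential
#' passive elasticity, the piecewise-linear filament overlap geometry, the
#' cross-bridge stiffness and powerstroke size, and the coefficients of the
#' strain-dependent rate laws of the three-state (D, A1, A2) cycle.
#'
#' Defaults describe a fast skeletal half-sarcomere: 1.15e17 heads m^-2 at
#' full overlap, passive parameters (112 N m^-2, 625 nm offset, 136 nm length
#' constant) from fits to rabbit psoas passive length-tension data, a 5 nm
#' powerstroke, and rate-law coefficients calibrated once against the
#' single-unit ramp-and-hold response and the standard-protocol enhancement
#' magnitude, then frozen (see the package vignette).
#'
#' Rate laws (per strain bin at strain `x` nm):
#' \itemize{
#'   \item attachment D -> A1: `f(x) = f0 * exp(-x^2 / (2 sigma_f^2))`,
#'     localized near zero strain;
#'   \item powerstroke A1 -> A2: `h(x) = h0 / (1 + exp(-(x - x_h0)/x_hw))`,
#'     increasing where the stroke releases energy; reversal at constant `h_r`;
#'   \item detachment A2 -> D: `g(x) = min(g0 + g1 (exp(|x|/x_d) - 1),
#'     g_cap)`: gentle near zero strain, exponentially steep at large
#'     strain. This shape makes the eccentric force capacity a monotone,
#'     slowly (logarithmically) increasing function of drag velocity, so a
#'     unit carrying excess force lengthens at a finite velocity instead of
#'     falling off a capacity cliff, while bridge strains stay well inside
#'     the strain axis. Detachment A1 -> D is `g_a1 + g1 (exp(|x|/x_d) - 1)`,
#'     sharing the forcible-ripping term.
#' }
#'
#' @param n0_density myosin heads per m^2 at full availability
#' @param zeta dimensionless strength multiplier (an alpha-draw; mean 1)
#' @param xi dimensionless passive-stiffness multiplier (a beta-draw; mean 1)
#' @param passive_sigma,passive_offset,passive_lambda exponential passive
#'   law: `xi * passive_sigma * (exp((l - passive_offset)/passive_lambda) - 1)`
#'   for `l >= passive_offset`, linearly continued below with matched slope
#' @param overlap_zero_short,overlap_plateau_lo,overlap_plateau_hi,overlap_zero_long
#'   breakpoints (nm) of the piecewise-linear thick/thin filament overlap
#'   fraction: 0 at or below `overlap_zero_short`, 1 on the plateau, 0 at or
#'   beyond `overlap_zero_long`
#' @param k_cb cross-bridge stiffness, N per head per nm of strain
#' @param x_ps powerstroke displacement, nm
#' @param f0,sigma_f,h0,x_h0,x_hw,h_r,g_a1,g0,g1,x_d,g_cap rate-law
#'   coefficients (s^-1 and nm), see Details
#' @param g_r,x_r optional forcible-rupture detachment `g_r * (|x|/x_r)^16`
#'   added to both attached states (off by default, `g_r = 0`)
#' @param eta_visc small parallel dashpot, N m^-2 per nm/s of unit
#'   lengthening: negligible at physiological creep velocities, it keeps the
#'   lengthening velocity of rapidly yielding ("popping") units finite so
#'   the force-balance network stays well-posed
#' @param axis a [strain_axis()]
#' @return an object of class `hs_params`
#' @export
hs_params <- function(n0_density = 1.15e17,
                      zeta = 1, xi = 1,
                      passive_sigma = 112,
                      passive_offset = 625,
                      passive_lambda = 136,
                      overlap_zero_short = 800,
                      overlap_plateau_lo = 1170,
                      overlap_plateau_hi = 1300,
                      overlap_zero_long = 1700,
                      k_cb = 4.4e-13,
                      x_ps = 5,
                      f0 = 8, sigma_f = 0.5,
                      h0 = 40, x_h0 = -2.5, x_hw = 0.5, h_r = 2,
                      g_a1 = 2, g0 = 0.6, g1 = 0.02, x_d = 1.2, g_cap = 40,
                      g_r = 0, x_r = 11, eta_visc = 0,
                      axis = strain_axis()) {
  p <- list(n0_density = n0_density, zeta = zeta, xi = xi,
            passive_sigma = passive_sigma, passive_offset = passive_offset,
            passive_lambda = passive_lambda,
            overlap_zero_short = overlap_zero_short,
            overlap_plateau_lo = overlap_plateau_lo,
            overlap_plateau_hi = overlap_plateau_hi,
            overlap_zero_long = overlap_zero_long,
            k_cb = k_cb, x_ps = x_ps,
            f0 = f0, sigma_f = sigma_f, h0 = h0, x_h0 = x_h0, x_hw = x_hw,
            h_r = h_r, g_a1 = g_a1, g0 = g0, g1 = g1, x_d = x_d,
            g_cap = g_cap, g_r = g_r, x_r = x_r, eta_visc = eta_visc,
            axis = axis)
  validate_hs_params(p)
  structure(p, class = "hs_params")
}

validate_hs_params <- function(p) {
  num <- vapply(p[setdiff(names(p), "axis")], function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))
  if (!all(num)) stop("non-finite or non-scalar parameter: ",
                      paste(names(num)[!num], collapse = ", "))
  if (p$n0_density <= 0) stop("n0_density must be positive")
  if (p$zeta <= 0) stop("zeta must be positive")
  if (p$xi <= 0) stop("xi must be positive")
  if (p$passive_lambda <= 0) stop("passive_lambda must be positive")
  if (p$x_d <= 0) stop("x_d must be positive")
  br <- c(p$overlap_zero_short, p$overlap_plateau_lo,
          p$overlap_plateau_hi, p$overlap_zero_long)
  if (any(diff(br) <= 0)) stop("overlap breakpoints must be strictly increasing")
  if (!inherits(p$axis, "strain_axis")) stop("axis must be a strain_axis")
  invisible(p)
}

# flatten for the C++ core
pars_to_c <- function(p) {
  c(p[setdiff(names(p), "axis")],
    list(n_bins = p$axis$n_bins, x_min = p$axis$x_min, x_max = p$axis$x_max))
}

#' Strain-dependent rate tables
#'
#' Evaluates the attachment, powerstroke, and detachment rate laws on the
#' strain grid, mainly for inspection and plotting.
#'
#' @param params an [hs_params()] object
#' @return a data.frame with columns `x`, `f`, `h`, `g` (A2 detachment) and
#'   `g_a1x` (A1 detachment) plus attributes `h_r`, `g_a1`, `sum_f`
#' @export
rate_tables <- function(params) {
  stopifnot(inherits(params, "hs_params"))
  rt <- cpp_rate_tables(pars_to_c(params))
  out <- data.frame(x = rt$x, f = rt$f, h = rt$h, g = rt$g,
                    g_a1x = rt$g_a1x)
  attr(out, "h_r") <- rt$h_r
  attr(out, "g_a1") <- rt$g_a1
  attr(out, "sum_f") <- rt$sum_f
  out
}
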