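#' Heterogeneity specification
#'
#' Describes the stochastic variation across half-sarcomeres: `alpha` is the
#' standard deviation (coefficient of variation) of the Gaussian strength
#' multipliers zeta, `beta` that of the passive-stiffness multipliers xi.
#' Both distributions have mean 1. Draws at or below 0.05 are rejected and
#' redrawn so that no unit has a nonphysical (near-zero or negative)
#' strength; at the levels used here (alpha <= 0.4) rejections are rare.
#'
#' @param alpha SD of the strength multiplier (dimensionless, >= 0)
#' @param beta SD of the passive multiplier (dimensionless, >= 0)
#' @param seed integer RNG seed
#' @param n_units number of half-sarcomeres to draw for
#' @return an object of class `het_spec`
#' @export
het_spec <- function(alpha = 0.2, beta = 0, seed = 1, n_units = 50) {
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  n_units <- as.integer(n_units)
  if (n_units < 1) stop("n_units must be >= 1")
  structure(list(alpha = alpha, beta = beta, seed = as.integer(seed),
                 n_units = n_units),
            class = "het_spec")
}

truncated_gaussian <- function(n, sd, floor = 0.05) {
  if (sd == 0) return(rep(1, n))
  v <- rnorm(n, mean = 1, sd = sd)
  while (any(bad <- v <= floor))
    v[bad] <- rnorm(sum(bad), mean = 1, sd = sd)
  v
}

#' Sample strength and passive multipliers
#'
#' Draws the per-unit zeta (strength) and xi (passive stiffness) multipliers
#' from truncated Gaussians with mean 1 and SDs `alpha` and `beta`.
#' Reproducible: the same spec always yields the same vectors.
#'
#' @param spec a [het_spec()]
#' @return a list with numeric vectors `zeta` and `xi` of length `n_units`
#' @export
sample_multipliers <- function(spec) {
  stopifnot(inherits(spec, "het_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  zeta <- truncated_gaussian(spec$n_units, spec$alpha)
  xi <- truncated_gaussian(spec$n_units, spec$beta)
  list(zeta = zeta, xi = xi)
}

#' Deterministic child seeds
#'
#' Derives reproducible per-member seeds from a master seed via a
#' counter-based affine map modulo a large prime, so ensembles are fully
#' determined by the master seed and member index.
#'
#' @param master integer master seed
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @export
child_seeds <- function(master, n) {
  master <- as.integer(master)
  # 2147483629 is the largest prime below 2^31 - 1
  as.integer((as.numeric(master) * 48271 + 1000003 * seq_len(n)) %% 2147483629)
}

#' Build an ensemble of configurations
#'
#' Replicates a base configuration across `n_seeds` deterministic child
#' seeds (the study design averages many random patterns of half-sarcomere
#' variation to suppress stochastic noise).
#'
#' @param base_config a [sim_config()]
#' @param n_seeds ensemble size (>= 1)
#' @return list of configs, one per child seed, with attribute `master_seed`
#' @export
make_ensemble <- function(base_config, n_seeds) {
  stopifnot(inherits(base_config, "sim_config"), n_seeds >= 1)
  seeds <- child_seeds(base_config$seed, n_seeds)
  out <- lapply(seeds, function(s) { cfg <- base_config; cfg$seed <- s; cfg })
  attr(out, "master_seed") <- base_config$seed
  out
}
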