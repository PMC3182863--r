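#' Plot a paired stretch/isometric tension response
#'
#' @param x a `sarco_pair` or `rfe_ensemble`
#' @param ... passed to [graphics::plot()]
#' @return `x` invisibly
#' @export
plot.sarco_pair <- function(x, ...) {
  graphics::plot(x$stretch$time, x$stretch$force, type = "l", col = "red",
                 xlab = "time (s)", ylab = expression(tension~(N~m^-2)), ...)
  graphics::lines(x$isometric$time, x$isometric$force, col = "black")
  graphics::abline(v = x$config$protocol$stretch_end + x$rfe$t_ss,
                   lty = 3, col = "grey50")
  graphics::legend("bottomright", c("stretch", "isometric"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' @rdname plot.sarco_pair
#' @export
plot.rfe_ensemble <- function(x, ...) {
  graphics::plot(x$time, x$force_stretch_mean, type = "l", col = "red",
                 xlab = "time (s)", ylab = expression(tension~(N~m^-2)), ...)
  graphics::lines(x$time, x$force_iso_mean, col = "black")
  graphics::abline(v = x$rfe$t_eval, lty = 3, col = "grey50")
  graphics::legend("bottomright",
                   c(sprintf("stretch (ensemble of %d)", x$n_seeds),
                     "isometric"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}
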