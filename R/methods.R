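# print / summary / plot methods for the result classes

#' @export
print.idg_run <- function(x, ...) {
  cat(sprintf("Interdependent-game run: L = %d, b = %g, s = %g, seed = %d\n",
              x$L, x$params$b, x$params$s, x$seed))
  cat(sprintf("  %d relaxation + %d averaging MC steps, init = %s\n",
              x$relax, x$avg, x$init))
  last <- x$ts[nrow(x$ts), ]
  cat(sprintf("  final f_c: SD %.4f, PD %.4f, system %.4f; sync %.4f\n",
              last$fc_sd, last$fc_pd, last$fc_sys, last$sync))
  invisible(x)
}

#' @export
summary.idg_run <- function(object, window = NULL, ...) {
  out <- steady_state_average(object, window = window)
  cat(sprintf("Steady-state averages over the final %d MC steps:\n",
              out$window[1]))
  print(out, digits = 4)
  invisible(out)
}

#' Plot a run's time series
#'
#' Cooperation frequencies of both layers (and optionally the interlayer
#' pair frequencies) against MC time on a logarithmic time axis.
#'
#' @param x an `"idg_run"`.
#' @param what `"fc"` or `"pairs"`.
#' @param ... further arguments to [graphics::matplot()].
#' @export
plot.idg_run <- function(x, what = c("fc", "pairs"), ...) {
  what <- match.arg(what)
  ts <- x$ts[x$ts$step > 0, ]
  if (what == "fc") {
    graphics::matplot(ts$step, ts[, c("fc_sd", "fc_pd")], type = "l",
                      lty = 1, col = c("darkgreen", "darkorange"),
                      log = "x", xlab = "MC step",
                      ylab = "cooperation frequency", ylim = c(0, 1), ...)
    graphics::legend("topright", c("SD", "PD"), lty = 1,
                     col = c("darkgreen", "darkorange"), bty = "n")
  } else {
    graphics::matplot(ts$step, ts[, c("f_cc", "f_dd", "f_cd", "f_dc")],
                      type = "l", lty = 1,
                      col = c("blue", "red", "darkgreen", "purple"),
                      log = "x", xlab = "MC step", ylab = "pair frequency",
                      ylim = c(0, 1), ...)
    graphics::legend("topright", c("C-C", "D-D", "C-D", "D-C"), lty = 1,
                     col = c("blue", "red", "darkgreen", "purple"),
                     bty = "n")
  }
  invisible(x)
}

#' @export
print.idg_sweep <- function(x, ...) {
  axis <- attr(x, "axis")
  cfg <- attr(x, "config")
  cat(sprintf("Steady-state sweep over %s (%d points; fixed %s = %g)\n",
              axis, nrow(x), if (axis == "s") "b" else "s",
              attr(x, "fixed")))
  cat(sprintf("  L = %d, relax = %d, avg = %d, runs = %d\n",
              cfg$L, cfg$relax, cfg$avg, cfg$runs))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot a steady-state sweep
#'
#' Per-layer cooperation frequency against the swept parameter.
#'
#' @param x an `"idg_sweep"`.
#' @param ... further arguments to [graphics::matplot()].
#' @export
plot.idg_sweep <- function(x, ...) {
  axis <- attr(x, "axis")
  graphics::matplot(x[[axis]], cbind(x$fc_sd, x$fc_pd, x$fc_sys),
                    type = "b", pch = c(1, 2, 4), lty = 1,
                    col = c("darkgreen", "darkorange", "black"),
                    xlab = axis, ylab = "cooperation frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", c("SD", "PD", "system"), pch = c(1, 2, 4),
                   col = c("darkgreen", "darkorange", "black"), bty = "n")
  invisible(x)
}

#' @export
print.idg_phase <- function(x, ...) {
  cat(sprintf("b-s phase diagram: %d x %d cells\n",
              length(x$b), length(x$s)))
  cat("system-average cooperation frequency:\n")
  print(round(x$fc_sys, 3))
  invisible(x)
}

#' Plot a b-s phase diagram
#'
#' Image of the system-average cooperation frequency over the scanned grid.
#'
#' @param x an `"idg_phase"`.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.idg_phase <- function(x, ...) {
  graphics::image(x$b, x$s, x$fc_sys,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "b", ylab = "s", ...)
  invisible(x)
}
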