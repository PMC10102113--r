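# Base-graphics diagnostics for the main result objects.

#' Plot an activation map summary
#'
#' Scatter of the mesh nodes in a superior-view projection colored by
#' activation time; never-activated nodes in gray.
#'
#' @param x an `ep_solution`
#' @param mesh the mesh the solution lives on
#' @param ... passed to [graphics::plot()]
#' @export
plot.ep_solution <- function(x, mesh, ...) {
  tA <- x$t_A
  v <- mesh$vertices
  col <- rep("gray60", length(tA))
  act <- !is.na(tA)
  if (any(act)) {
    pal <- grDevices::hcl.colors(64, "viridis")
    col[act] <- pal[cut(tA[act], 64, labels = FALSE)]
  }
  graphics::plot(v[, 1], v[, 2], col = col, pch = 16, cex = 0.5, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("activation map (max %.0f ms, %.0f%% inactive)",
                                x$total_activation_time,
                                100 * mean(x$inactive_mask)), ...)
  invisible(x)
}

#' Plot pressure and volume traces of the closed loop
#'
#' @param x a `circ_result`
#' @param what "traces" (pressures and volumes over the last cycle) or
#'   "pv" (LV and LA pressure-volume loops)
#' @param ... passed through to plotting calls
#' @export
plot.circ_result <- function(x, what = c("traces", "pv"), ...) {
  tr <- x$traces
  what <- match.arg(what)
  if (what == "pv") {
    graphics::plot(tr$V_LV, tr$p_LV, type = "l", xlab = "volume (mL)",
                   ylab = "pressure (mmHg)", main = "PV loops", ...)
    graphics::lines(tr$V_LA, tr$p_LA, col = 2)
    graphics::legend("topleft", c("LV", "LA"), col = 1:2, lty = 1, bty = "n")
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(tr$time, tr$p_LV, type = "l", xlab = "time (s)",
                   ylab = "pressure (mmHg)", ...)
    graphics::lines(tr$time, tr$p_LA, col = 2)
    graphics::lines(tr$time, tr$p_SysArt, col = 4)
    graphics::legend("topright", c("LV", "LA", "SysArt"), col = c(1, 2, 4),
                     lty = 1, bty = "n")
    graphics::plot(tr$time, tr$V_LV, type = "l", xlab = "time (s)",
                   ylab = "volume (mL)", ...)
    graphics::lines(tr$time, tr$V_LA, col = 2)
    graphics::legend("topright", c("LV", "LA"), col = 1:2, lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
summary.biomarker_table <- function(object, ...) {
  cat("Lesion-case biomarkers (", nrow(object), "cases )\n")
  print(object[, c("case", "SV", "EF", "dEF", "AT", "IT")], row.names = FALSE,
        digits = 4)
  abl <- object[object$case != "Control", ]
  if (nrow(abl) >= 3) {
    r_it <- lesion_regression(abl$IT, abl$dEF)
    r_at <- lesion_regression(abl$AT, abl$dEF)
    cat(sprintf("dEF ~ IT: R2 = %.3f (slope %.3f pp/%%)\n", r_it$r2, r_it$slope))
    cat(sprintf("dEF ~ AT: R2 = %.3f (slope %.3f pp/%%)\n", r_at$r2, r_at$slope))
  }
  invisible(object)
}
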