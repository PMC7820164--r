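#' Rectangular plot window
#'
#' Defines the rectangular observation window of a stem map. Coordinates are
#' continuous meters; distances throughout the package are Euclidean. The
#' window area is reported in hectares.
#'
#' @param x_min,x_max,y_min,y_max Window bounds in meters. `x_max > x_min`
#'   and `y_max > y_min` are required.
#' @return An object of class `plot_window`: a named list with the four
#'   bounds plus `width`, `height` (m) and `area_ha` (hectares).
#' @examples
#' w <- plot_window(0, 200, 0, 215)
#' w$area_ha # 4.3
#' @export
plot_window <- function(x_min = 0, x_max, y_min = 0, y_max) {
  assert_number(x_min, "x_min"); assert_number(x_max, "x_max")
  assert_number(y_min, "y_min"); assert_number(y_max, "y_max")
  if (x_max <= x_min || y_max <= y_min) {
    abort("`plot_window()` needs x_max > x_min and y_max > y_min.")
  }
  w <- list(
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    width = x_max - x_min, height = y_max - y_min,
    area_ha = (x_max - x_min) * (y_max - y_min) / 1e4
  )
  structure(w, class = "plot_window")
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("<plot_window> [%g, %g] x [%g, %g] m (%.3f ha)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area_ha))
  invisible(x)
}

#' @export
format.plot_window <- function(x, ...) {
  sprintf("[%g, %g] x [%g, %g] m", x$x_min, x$x_max, x$y_min, x$y_max)
}

window_area_m2 <- function(window) window$width * window$height

in_window <- function(x, y, window) {
  x >= window$x_min & x <= window$x_max & y >= window$y_min & y <= window$y_max
}

as_plot_window <- function(x) {
  if (inherits(x, "plot_window")) return(x)
  if (is.list(x) && all(c("x_min", "x_max", "y_min", "y_max") %in% names(x))) {
    return(plot_window(x$x_min, x$x_max, x$y_min, x$y_max))
  }
  if (is.numeric(x) && length(x) == 4L) {
    return(plot_window(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  abort("Cannot interpret `window`; supply plot_window() or c(x_min, x_max, y_min, y_max).")
}
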