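# ggplot2 views of the package's result types.

#' @export
autoplot.stem_map <- function(object, ...) {
  w <- map_window(object)
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        size = .data$dbh))
  if ("status" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$status),
                                 alpha = 0.7) +
      ggplot2::scale_color_manual(values = c(alive = "#2a6f3e",
                                             killed = "#b5442c"))
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, color = "#2a6f3e")
  }
  p +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_fixed(xlim = c(w$x_min, w$x_max),
                         ylim = c(w$y_min, w$y_max), expand = FALSE) +
    ggplot2::labs(x = "x (m)", y = "y (m)", size = "dbh (cm)",
                  title = map_label(object)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fs_envelope <- function(object, ...) {
  kind <- attr(object, "kind") %||% "statistic"
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean),
                       linetype = "dashed", color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                       color = "#2c5f8a", linewidth = 0.8) +
    ggplot2::labs(
      x = "r (m)", y = kind,
      subtitle = sprintf("%s | r-averaged z = %.2f",
                         if (attr(object, "significant")) "significant"
                         else "not significant",
                         attr(object, "r_averaged_z"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fcf <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::labs(x = "r (m)", y = fcf_kind(object) %||% "value") +
    ggplot2::theme_minimal()
}

#' Tile plot of a group flow matrix
#'
#' Trees flowing from prefire group size classes (rows) into postfire
#' classes or death (columns); a text-annotated alternative to a Sankey
#' rendering.
#'
#' @param flow A `group_flow` object.
#' @return A ggplot.
#' @export
plot_group_flow <- function(flow) {
  df <- flow$flows
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to_class, y = .data$from_class,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "#b5442c") +
    ggplot2::labs(x = "postfire class", y = "prefire class", fill = "trees") +
    ggplot2::theme_minimal()
}

#' @export
tidy.fs_envelope <- function(x, ...) as_tibble(x)

#' @export
glance.fs_envelope <- function(x, ...) {
  tibble(
    kind = attr(x, "kind") %||% NA_character_,
    significant = attr(x, "significant"),
    crit = attr(x, "crit"),
    r_averaged_z = attr(x, "r_averaged_z"),
    mean_abs_z = attr(x, "mean_abs_z"),
    n_sim = attr(x, "n_sim"),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.fcf <- function(x, ...) as_tibble(x)
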