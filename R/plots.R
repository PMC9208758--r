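#' Plot a cursor trajectory in the target space
#'
#' Draws the trial's cursor path over the three target discs and the
#' trial's angle wedge (inner crop shown dashed).
#'
#' @param object A `mu_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_trial <- function(object, ...) {
  st <- tidy(object)
  circle <- function(cx, cy, r, n = 100) {
    a <- seq(0, 2 * pi, length.out = n)
    tibble(x = cx + r * cos(a), y = cy + r * sin(a))
  }
  targets <- purrr::map_dfr(c("TI", "TII", "TIII"), function(tg) {
    g <- target_geometry(tg)
    mutate(circle(g$center[1], g$center[2], g$radius), target = tg)
  })
  crop <- circle(0, 0, object$geometry$inner_crop)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = targets,
                       ggplot2::aes(group = .data$target),
                       colour = "grey40") +
    ggplot2::geom_path(data = crop, linetype = "dashed", colour = "grey70") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$buffer)) +
    ggplot2::geom_point(data = st[nrow(st), ], shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "normalised rate MU1", y = "normalised rate MU2",
                  colour = "buffer",
                  title = sprintf("%s trial: %s", object$target,
                                  object$outcome))
}

#' Plot a drive or force trace
#' @param object A `mu_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "%MVC")
}

#' Plot thresholds over the force trace
#'
#' Force trace with recruitment (up) and de-recruitment (down) markers per
#' ranked unit.
#'
#' @param thresholds A `mu_thresholds` tibble.
#' @param force The `mu_trace` the thresholds were estimated from.
#' @return A ggplot object.
#' @export
plot_thresholds <- function(thresholds, force) {
  ggplot2::ggplot(as_tibble(force),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(data = thresholds,
                        ggplot2::aes(x = .data$t_on, y = .data$f_on),
                        shape = 24, fill = "forestgreen") +
    ggplot2::geom_point(data = filter(thresholds, !is.na(.data$t_off)),
                        ggplot2::aes(x = .data$t_off, y = .data$f_off),
                        shape = 25, fill = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "force (%MVC)")
}
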