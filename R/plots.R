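# ggplot2 autoplot methods for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.trap_trace <- function(object, filter_hz = 500, truth = FALSE, ...) {
  trap <- attr(object, "trap")
  d <- tibble(time = object$time,
              force = .boxcar(object$force, round(trap$sample_rate / filter_hz)))
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey25") +
    ggplot2::labs(x = "time (s)", y = "force (pN)",
                  title = attr(object, "params")$construct_label) +
    ggplot2::theme_minimal()
  if (truth && !is.null(attr(object, "truth"))) {
    att <- ground_truth(object)$attachments
    att <- att[!is.na(att$t_off), , drop = FALSE]
    gg <- gg + ggplot2::geom_point(
      data = tibble(time = att$t_off, force = att$detach_force),
      colour = "red", size = 0.8)
  }
  gg
}

#' @exportS3Method ggplot2::autoplot
autoplot.step_fit <- function(object, dt = 1, ...) {
  d <- tibble(x = seq_len(object$n) * dt, y = object$data,
              fit = step_signal(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "grey55",
                       linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::labs(x = "sample", y = "signal") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eddm_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$i, y = .data$j,
                               fill = .data$mean_diff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object[object$significant, , drop = FALSE],
                        shape = 4, size = 0.8) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "residue i", y = "residue j",
                  fill = "masked\ndiff (A)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  s <- object$series
  grid <- tibble(C = seq(min(s$rel_concentration) / 2,
                         max(s$rel_concentration) * 1.1, length.out = 200))
  curves <- bind_rows(
    tibble(C = grid$C, fraction = binding_fraction(
      object$lam[["processive"]], grid$C, "processive"),
      model = "processive"),
    tibble(C = grid$C, fraction = binding_fraction(
      object$lam[["nonprocessive"]], grid$C, "nonprocessive"),
      model = "nonprocessive"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rel_concentration,
                                  y = .data$fraction)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$C, linetype = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fraction - .data$se, ymax = .data$fraction + .data$se)) +
    ggplot2::labs(x = "relative motor concentration",
                  y = "fraction of moving beads") +
    ggplot2::theme_minimal()
}

#' Stall-force histogram with its Gaussian fit
#'
#' @param stalls output of [detect_stalls()].
#' @param fit optional [fit_gaussian()] result (computed otherwise).
#' @return a ggplot.
#' @export
plot_stall_histogram <- function(stalls, fit = NULL) {
  fit <- fit %||% fit_gaussian(stalls$mean_force)
  bw <- 2 * stats::IQR(stalls$mean_force) / length(stalls$mean_force)^(1 / 3)
  xs <- seq(min(stalls$mean_force), max(stalls$mean_force), length.out = 200)
  nn <- nrow(stalls)
  dens <- tibble(x = xs,
                 y = nn * bw * stats::dnorm(xs, fit$mean, fit$sd))
  ggplot2::ggplot(stalls, ggplot2::aes(x = .data$mean_force)) +
    ggplot2::geom_histogram(binwidth = bw, fill = "grey70", colour = "white") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red") +
    ggplot2::labs(x = "stall force (pN)", y = "count") +
    ggplot2::theme_minimal()
}
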