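#' Plot a sweep trajectory
#'
#' Shows the per-plane centre-of-rotation x-excursion against declination
#' angle (proximal shift negative) and the shared-centre path.
#'
#' @param object an `mpsjc_sweep`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mpsjc_sweep <- function(object, ...) {
  tr <- object$trajectory |>
    dplyr::group_by(.data$plane) |>
    dplyr::mutate(cr_dx = .data$cr_x - dplyr::first(.data$cr_x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(tr, ggplot2::aes(.data$theta_deg, .data$cr_dx,
                                   colour = .data$plane)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$excursion_tol,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "declination angle (deg)",
                  y = "CR x-shift from initial (mm; negative = proximal)",
                  colour = "plane",
                  title = "Centre-of-rotation shift over the declination sweep") +
    ggplot2::theme_minimal()
}

#' Plot a composite profile with its groove
#'
#' @param profile a `composite_profile`.
#' @param n number of sampled points.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, n = 400) {
  psis <- seq(profile$span[1] + 1e-6, profile$span[2] - 1e-6, length.out = n)
  pts <- profile_point(profile, psis)
  lab <- vapply(psis, function(p) active_arc(profile, p)$label, character(1))
  df <- tibble::tibble(x = pts[, 1], y = pts[, 2], arc = lab)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$arc)) +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, distal +)", y = "y (mm, dorsal +)",
                  title = "Sagittal articular profile") +
    ggplot2::theme_minimal()
}

#' Plot a section stack's landmark diagnostics
#'
#' Circle-fit residual and plantar groove deficit per section, with the
#' located landmarks marked.
#'
#' @param object an `mpsjc_stack`.
#' @param landmarks optionally a [locate_landmarks()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mpsjc_stack <- function(object, landmarks = NULL, ...) {
  lm <- landmarks %||% tryCatch(locate_landmarks(object), error = function(e) NULL)
  if (is.null(lm)) {
    det <- dplyr::bind_rows(lapply(sort(unique(object$sections$section)), function(k) {
      pts <- as.matrix(object$sections[object$sections$section == k, c("x", "y")])
      tibble::tibble(section = k, rms = fit_circle(pts)$rms_residual,
                     depth = NA_real_)
    }))
  } else det <- lm$details
  df <- tidyr::pivot_longer(det[, c("section", "rms", "depth")],
                            cols = c("rms", "depth"),
                            names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$section, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "section index", y = "mm",
                  title = "Section-stack landmark diagnostics") +
    ggplot2::theme_minimal()
  if (!is.null(lm)) {
    marks <- tibble::tibble(section = c(lm$crista_index, lm$tibial_trough_index,
                                        lm$fibular_trough_index),
                            landmark = c("crista", "tibial trough", "fibular trough"))
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$section,
                                              colour = .data$landmark),
                                 linetype = "dashed")
  }
  p
}
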