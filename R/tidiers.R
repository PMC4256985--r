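#' Plot a training trace
#'
#' Shows the winning cell of the feedforward and the feedback sweep per
#' training step (top panel, points colored by cell) and the residual mass
#' per step (bottom panel). Recruitment events (first-time winners) are
#' marked with triangles.
#'
#' @param object A `corticat_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corticat_fit
#' @export
autoplot.corticat_fit <- function(object, ...) {
  tr <- tidy(object)
  if (nrow(tr) == 0) stop("empty trace")
  long <- tidyr::pivot_longer(tr, c("winner_ff", "winner_fb"),
                              names_to = "sweep", values_to = "winner")
  long$sweep <- ifelse(long$sweep == "winner_ff", "feedforward", "feedback")
  recruits <- dplyr::bind_rows(
    dplyr::filter(tr, .data$first_use_ff) |>
      dplyr::transmute(step = .data$step, winner = .data$winner_ff,
                       sweep = "feedforward"),
    dplyr::filter(tr, .data$first_use_fb) |>
      dplyr::transmute(step = .data$step, winner = .data$winner_fb,
                       sweep = "feedback")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$winner,
                                     color = factor(.data$winner))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_point(data = recruits, shape = 17, size = 3,
                        color = "black") +
    ggplot2::facet_wrap(~sweep, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = seq_len(max(long$winner))) +
    ggplot2::labs(x = "training step", y = "winning cell",
                  color = "cell",
                  title = "Sweep winners over training",
                  subtitle = "triangles: first-time recruitment") +
    ggplot2::theme_minimal()
}

#' Plot a stimulus or weight field as an image
#'
#' Reshapes a length-N vector (or passes a matrix through) to the model
#' grid and renders it with `geom_raster`. Useful for inspecting receptive
#' (`w_in` columns) and projective (`w_out` rows) fields.
#'
#' @param x Numeric matrix, or vector of length `height * width`.
#' @param height,width Grid dimensions used when `x` is a vector.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_field <- function(x, height = 100, width = 100, title = NULL) {
  m <- if (is.matrix(x)) x else matrix(x, height, width)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot all receptive or projective fields of a trained model
#'
#' @param fit A `corticat_fit`.
#' @param which `"w_in"` (receptive / fan-in fields, one per cell) or
#'   `"w_out"` (projective / fan-out fields).
#' @return A ggplot object, cells as facets.
#' @export
plot_weights <- function(fit, which = c("w_in", "w_out")) {
  which <- match.arg(which)
  p <- fit$config$params
  m <- length(fit$state$used)
  df <- purrr::map_dfr(seq_len(m), function(k) {
    w <- if (which == "w_in") fit$state$w_in[, k] else fit$state$w_out[k, ]
    g <- expand.grid(row = seq_len(p$height), col = seq_len(p$width))
    g$value <- as.vector(matrix(w, p$height, p$width))
    g$cell <- k
    g
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(title = if (which == "w_in") "Receptive fields (fan-in)"
                  else "Projective fields (fan-out)",
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
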