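#' Plot a substrate map
#'
#' Tile map of a per-node substrate field (voltage, fibrosis probability,
#' fibrosis mask, or region labels) with lesions and vein holes blanked.
#'
#' @param substrate A `substrate_map`.
#' @param field Column to display.
#' @return A ggplot object.
#' @export
plot_substrate <- function(substrate, field = c("voltage_mv", "p_fibrosis",
                                                "fibrotic", "region")) {
  field <- match.arg(field)
  d <- as_tibble(substrate)
  d$val <- d[[field]]
  d$val[d$removed] <- NA
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm,
                                       fill = .data$val)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = field)
  if (field %in% c("voltage_mv", "p_fibrosis"))
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "grey30")
  p
}

#' @export
autoplot.substrate_map <- function(object, ...) plot_substrate(object, ...)

#' Plot recorded membrane-potential traces
#'
#' @param object A `simulation_trace` with recorded nodes, or a
#'   `cell_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_trace <- function(object, ...) {
  if (length(object$time_ms) == 0) abort("trace has no recorded nodes")
  d <- as_tibble(t(object$vm))
  names(d) <- paste0("node_", object$rec_nodes)
  d$time_ms <- object$time_ms
  d <- tidyr::pivot_longer(d, -"time_ms", names_to = "node",
                           values_to = "vm_mV")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$vm_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~node) +
    ggplot2::labs(x = "time (ms)", y = "Vm (mV)")
}

#' @export
autoplot.cell_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$time_ms, .data$vm_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "Vm (mV)")
}

#' Plot a restitution fit with its data
#'
#' @param fit A `restitution_fit`.
#' @param pairs The (DI, APD90) pairs used for the fit.
#' @return A ggplot object.
#' @export
plot_restitution <- function(fit, pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(.data$di_ms, .data$apd90_ms)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "diastolic interval (ms)", y = "APD90 (ms)")
  if (isTRUE(fit$ok) && is.finite(fit$tau1)) {
    grid <- tibble(di_ms = seq(min(pairs$di_ms), max(pairs$di_ms),
                               length.out = 200))
    grid$apd90_ms <- fit$y0 + fit$a1 * (1 - exp(-grid$di_ms / fit$tau1))
    p <- p + ggplot2::geom_line(data = grid, color = "red")
  }
  p
}

#' Plot a per-node biomarker map
#'
#' @param object A `biomarker_map` from [smax_map()] or [df_map()].
#' @param substrate The matching `substrate_map` (for coordinates).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biomarker_map <- function(object, substrate, ...) {
  val_col <- if (object$biomarker == "smax") "smax" else "df_hz"
  d <- dplyr::left_join(object$values,
                        as_tibble(substrate)[, c("node", "x_mm", "y_mm")],
                        by = "node")
  ggplot2::ggplot(d[d$ok, ],
                  ggplot2::aes(.data$x_mm, .data$y_mm,
                               fill = .data[[val_col]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = object$biomarker)
}

#' @export
ggplot2::autoplot
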