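# Optional figure helpers (ggplot2 is suggested, not imported).

#' Heatmap of a lesion-transfer profile
#'
#' Absolute mean deviation per (position, parameter), translational and
#' rotational parameters faceted separately.
#'
#' @param profile a \code{transfer_profile}.
#' @return a ggplot object.
#' @export
plot_transfer_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = position, y = parameter,
                               fill = abs_deviation)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~units, scales = "free_y", ncol = 1L) +
    ggplot2::scale_fill_viridis_c(name = "|mean deviation|") +
    ggplot2::labs(x = "position relative to lesion", y = NULL)
}

#' Heatmap of a cation density map
#'
#' Radial-angular molarity map; the display is clipped at \code{clip} molar
#' (presentation only, stored data are untouched).
#'
#' @param map an \code{ion_density_map}.
#' @param clip display ceiling in molar (default 5).
#' @return a ggplot object.
#' @export
plot_ion_map <- function(map, clip = 5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  r_mid <- (map$r_edges[-1L] + map$r_edges[-length(map$r_edges)]) / 2
  t_mid <- (map$theta_edges[-1L] + map$theta_edges[-length(map$theta_edges)]) / 2
  df <- expand.grid(r = r_mid, theta = t_mid)
  df$molarity <- pmin(as.vector(map$molarity), clip)
  ggplot2::ggplot(df, ggplot2::aes(x = theta, y = r,
                                   fill = molarity)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_fill_viridis_c(name = "M", limits = c(0, clip)) +
    ggplot2::labs(x = "angle from major-groove centre (deg)", y = "r (A)")
}

utils::globalVariables(c("position", "parameter", "abs_deviation", "theta", "r", "molarity", "units"))
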