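#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_path
#'   geom_col geom_errorbar geom_hline scale_fill_viridis_c coord_equal labs
#'   facet_wrap theme_minimal
NULL

#' Plot plan-view feature maps
#'
#' @param object A `"plan_view_maps"`.
#' @param which `"height"` or `"occupancy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plan_view_maps <- function(object, which = c("height", "occupancy"),
                                    ...) {
  which <- match.arg(which)
  M <- object[[which]]
  df <- tidyr::expand_grid(
    ix = seq_len(object$nx), iy = seq_len(object$ny)
  )
  df$x <- object$x0 + (df$ix - 0.5) * object$cell
  df$y <- object$y0 + (df$iy - 0.5) * object$cell
  df$value <- M[cbind(df$ix, df$iy)]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)", fill = which,
         title = paste("Plan-view", which, "map")) +
    theme_minimal()
}

#' Plot a height template
#'
#' @param template A `"height_template"`.
#' @return A ggplot object.
#' @export
plot_height_template <- function(template) {
  n <- nrow(template$values)
  df <- tidyr::expand_grid(ix = seq_len(n), iy = seq_len(n))
  df$value <- template$values[cbind(df$ix, df$iy)]
  ggplot(df, aes(x = .data$ix, y = .data$iy, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "height",
         title = sprintf("Height template (norm %.2f m, %d cells)",
                         template$norm_constant, template$nonzero_count)) +
    theme_minimal()
}

#' Plot replication error statistics
#'
#' @param object A `"fog_replication"`.
#' @param table As in [tidy.fog_replication()].
#' @param ... Unused.
#' @return A ggplot object with RMSE per point/participant.
#' @export
autoplot.fog_replication <- function(object, table = "position", ...) {
  df <- tidy(object, table = table)
  key <- if ("point_id" %in% names(df)) "point_id" else "participant"
  df$key <- factor(df[[key]])
  p <- ggplot(df, aes(x = .data$key, y = .data$rmse)) +
    labs(x = key, y = "RMSE", title = paste("Replication accuracy:", table)) +
    theme_minimal()
  if ("coordinate" %in% names(df)) {
    p <- p + geom_col(aes(fill = .data$coordinate), position = "dodge")
  } else if ("condition" %in% names(df)) {
    p <- p + geom_col(aes(fill = .data$condition), position = "dodge")
  } else {
    p <- p + geom_col(fill = "steelblue")
  }
  p
}

#' Plot an estimated trajectory over the walk area
#'
#' @param pose Pose tibble from [run_pose_pipeline()].
#' @param truth Optional truth stop table for reference markers.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(pose, truth = NULL) {
  p <- ggplot(pose[!is.na(pose$x), ], aes(x = .data$x, y = .data$y)) +
    geom_path(colour = "grey50") +
    geom_point(aes(colour = .data$t), size = 0.8) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)", colour = "t (s)",
         title = "Tracked trajectory") +
    theme_minimal()
  if (!is.null(truth)) {
    p <- p + geom_point(data = truth, aes(x = .data$ref_x, y = .data$ref_y),
                        inherit.aes = FALSE, shape = 4, size = 3, colour = "red")
  }
  p
}
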