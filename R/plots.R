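#' Histogram of glenoid version by method
#'
#' Side-by-side histograms of the measured version values for the
#' conventional and vault methods, the standard way to show how the two
#' measures distribute over a cohort.
#'
#' @param results Version table from [measure_version()].
#' @param binwidth Histogram bin width in degrees (default 2.5).
#' @return A ggplot object.
#' @export
plot_version_distribution <- function(results, binwidth = 2.5) {
  ggplot2::ggplot(
    tibble::as_tibble(results),
    ggplot2::aes(x = .data$version_deg, fill = .data$method)
  ) +
    ggplot2::geom_histogram(
      binwidth = binwidth, boundary = 0,
      position = "identity", alpha = 0.6, colour = "grey30"
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "glenoid version (deg, retroversion positive)",
      y = "shoulders", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gv_method_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$method, y = .data$mean_deg, fill = .data$method)
  ) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_deg - .data$sd_deg,
        ymax = .data$mean_deg + .data$sd_deg
      ),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL, y = "glenoid version (deg, mean +/- SD)",
      subtitle = sprintf(
        "vault - conventional = %+.1f deg, Wilcoxon p = %.3f",
        object$mean_difference_deg, object$wilcoxon$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gv_side_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$dominance, y = .data$mean_deg, fill = .data$dominance)
  ) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_deg - .data$sd_deg,
        ymax = .data$mean_deg + .data$sd_deg
      ),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "glenoid version (deg, mean +/- SD)") +
    ggplot2::theme_minimal()
}

#' Plot one shoulder's corrected slice
#'
#' Projects the landmarks of one shoulder into its three-dimensionally
#' corrected slice and draws the glenoid line and both measurement axes —
#' the same construction a reader would check on a reformatted CT slice.
#'
#' @param landmarks Long landmark table.
#' @param shoulder_id Which shoulder to draw (default: the first).
#' @param variant Glenoid line variant.
#' @return A ggplot object.
#' @export
plot_slice <- function(landmarks, shoulder_id = NULL, variant = "standard") {
  landmarks <- validate_landmarks(landmarks)
  shoulder_id <- shoulder_id %||% landmarks$shoulder_id[1]
  rows <- landmarks[landmarks$shoulder_id == shoulder_id, ]
  if (!nrow(rows)) {
    abort(paste0("no shoulder '", shoulder_id, "'"), class = "gv_validation_error")
  }
  pts <- landmarks_matrix(rows)
  slice <- corrected_slice(pts, scapular_plane(pts))
  xy <- project_to_slice(pts, slice)
  gl <- glenoid_line(pts, slice, variant)
  df <- tibble::tibble(
    landmark = rownames(xy), x = xy[, 1], y = xy[, 2]
  )
  seg <- tibble::tibble(
    what = c("glenoid line", "conventional axis", "vault axis"),
    x = c(gl$posterior[1], xy["medial_border_tip", 1], xy["vault_tip", 1]),
    y = c(gl$posterior[2], xy["medial_border_tip", 2], xy["vault_tip", 2]),
    xend = c(gl$anterior[1], gl$midpoint[1], gl$midpoint[1]),
    yend = c(gl$anterior[2], gl$midpoint[2], gl$midpoint[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        xend = .data$xend, yend = .data$yend,
        colour = .data$what
      ),
      linewidth = 0.8
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$landmark),
      hjust = -0.1, vjust = -0.4, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = shoulder_id,
      x = "medial → lateral (mm)",
      y = "posterior → anterior (mm)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
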