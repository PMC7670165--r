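# ggplot2 views of the matching result and the cohort comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bilateral match
#'
#' XY-projection (the Delaunay projection plane) of both articular point
#' sets, coloured by proximity-region membership at the configured
#' distance.
#'
#' @param object A `coronoid_match` from [match_pair()] or
#'   `run_subject()$match`.
#' @param left_frag,right_frag The aligned fragments the match was built
#'   from; when omitted, only mask summaries can be shown, so both are
#'   required.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coronoid_match <- function(object, left_frag = NULL, right_frag = NULL, ...) {
  if (is.null(left_frag) || is.null(right_frag)) {
    rlang::abort("supply the aligned fragments to plot a match",
                 class = "coronoid_precondition_error")
  }
  a <- left_frag$points[left_frag$articular, , drop = FALSE]
  b <- right_frag$points[right_frag$articular, , drop = FALSE]
  df <- dplyr::bind_rows(
    tibble::tibble(x = a[, 1], y = a[, 2], side = "left (mirrored)",
                   within = object$proximity_mask_left),
    tibble::tibble(x = b[, 1], y = b[, 2], side = "right",
                   within = object$proximity_mask_right)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$within)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::facet_wrap(~side) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Articular covering %.1f%% (d = %g mm)",
                      object$covering_percentage, object$d_mm),
      x = "medial-lateral X (mm)", y = "anterior Y (mm)",
      colour = sprintf("within %g mm", object$d_mm)) +
    ggplot2::theme_minimal()
}

#' Plot cohort comparisons
#'
#' Group means with SD error bars for every parameter/grouping pair in a
#' [build_report()] table.
#'
#' @param object A `cohort_comparisons` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparisons <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, parameter = .data$parameter,
                     grouping = .data$grouping, group = .data$group1,
                     mean = .data$mean_a, sd = .data$sd_a, p = .data$p),
    dplyr::transmute(object, parameter = .data$parameter,
                     grouping = .data$grouping, group = .data$group2,
                     mean = .data$mean_b, sd = .data$sd_b, p = .data$p)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     colour = .data$grouping)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "mean +/- SD (mm or %)") +
    ggplot2::theme_minimal()
}
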