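# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.aligned_set <- function(object, ...) {
  n <- dim(object$coords)[1]
  df <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(ear = i, point = seq_len(dim(object$coords)[2]),
                   x = object$coords[i, , 1], y = object$coords[i, , 2])
  })
  cons <- tibble::tibble(point = seq_len(nrow(object$consensus)),
                         x = object$consensus[, 1], y = object$consensus[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(group = .data$ear),
                        alpha = 0.15, size = 0.6) +
    ggplot2::geom_point(data = cons, colour = "red", size = 1.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Procrustes-aligned ears (red: consensus)",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shape_space <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(PC1 = object$scores[, 1],
                       PC2 = if (ncol(object$scores) > 1)
                         object$scores[, 2] else 0)
  if (!is.null(labels)) df$label <- labels
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.5)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  if (is.null(object$roc) || nrow(object$roc) == 0)
    stop("no ROC curves in this report (no probability scores supplied).",
         call. = FALSE)
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "One-vs-all ROC curves",
                  x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.umap_embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(title = "UMAP embedding", x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
  if ("label" %in% names(object))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8)
  else p + ggplot2::geom_point(alpha = 0.8)
}

#' Plot one or two landmark configurations
#'
#' Quick look at ear configurations: points joined within each template
#' curve, y axis reversed to match image coordinates.
#'
#' @param landmarks an [ear_landmarks()] object or coordinate matrix.
#' @param compare optional second configuration drawn in red.
#' @param template an [default_template()] object.
#' @return A ggplot object.
#' @export
plot_ear <- function(landmarks, compare = NULL,
                     template = default_template()) {
  as_df <- function(m, which) {
    m <- landmark_coords(m)
    purrr::map_dfr(names(template$segments), function(seg) {
      idx <- template$segments[[seg]]
      tibble::tibble(segment = seg, x = m[idx, 1], y = m[idx, 2],
                     which = which)
    })
  }
  df <- as_df(landmarks, "reference")
  if (!is.null(compare)) df <- dplyr::bind_rows(df, as_df(compare, "compare"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = interaction(.data$segment,
                                                       .data$which),
                                   colour = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(reference = "black",
                                            compare = "red"),
                                 guide = if (is.null(compare)) "none" else
                                   "legend") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
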