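# Shape PCA on Procrustes coordinates.

#' Principal component analysis of aligned shapes
#'
#' Eigendecomposition of the covariance of the flattened Procrustes
#' coordinates (x-block then y-block, 2p columns). All components are kept in
#' the loadings/eigenvalue fields; `retained` is the smallest number of
#' leading components whose cumulative variance fraction reaches
#' `variance_target`, and `scores` holds the per-ear scores for those
#' components.
#'
#' @param aligned an [gpa()] / [slide_semilandmarks()] result.
#' @param variance_target cumulative variance fraction to retain (default
#'   0.90).
#' @return An object of class `shape_space`: list with `loadings`
#'   (orthonormal columns over the 2p coordinates), `eigenvalues`,
#'   `variance_fraction`, `retained`, `scores` (n x retained), `center`
#'   (the flattened consensus), `consensus`, `variance_target`.
#' @export
shape_pca <- function(aligned, variance_target = 0.90) {
  stopifnot(inherits(aligned, "aligned_set"))
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1)
    stop("`variance_target` must be in (0, 1].", call. = FALSE)
  n <- dim(aligned$coords)[1]
  if (n < 3L) stop("shape PCA needs at least 3 configurations.", call. = FALSE)
  flat <- flatten_coords(aligned$coords)
  ctr <- colMeans(flat)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  structure(
    list(loadings = pc$rotation, eigenvalues = ev, variance_fraction = frac,
         retained = k, scores = pc$x[, seq_len(k), drop = FALSE],
         center = ctr, consensus = aligned$consensus,
         variance_target = variance_target),
    class = "shape_space"
  )
}

flatten_coords <- function(coords) {
  n <- dim(coords)[1]
  p <- dim(coords)[2]
  out <- matrix(NA_real_, n, 2L * p)
  out[, seq_len(p)] <- coords[, , 1]
  out[, p + seq_len(p)] <- coords[, , 2]
  colnames(out) <- c(paste0("x", seq_len(p)), paste0("y", seq_len(p)))
  out
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d ears, %d retained components (%.1f%% of variance, target %.0f%%)\n",
              nrow(x$scores), x$retained,
              100 * sum(x$variance_fraction[seq_len(x$retained)]),
              100 * x$variance_target))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shape_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction),
    retained = seq_along(x$eigenvalues) <= x$retained
  )
}

#' @export
glance.shape_space <- function(x, ...) {
  tibble::tibble(
    n_ears = nrow(x$scores),
    n_coordinates = length(x$center),
    retained = x$retained,
    variance_retained = sum(x$variance_fraction[seq_len(x$retained)]),
    variance_target = x$variance_target
  )
}

#' Project new configurations into an existing shape space
#'
#' Aligns each new configuration to the training consensus (rotation-only full
#' Procrustes fit), optionally slides its semilandmarks against the frozen
#' consensus, and projects the centered flattened coordinates onto the
#' retained loadings. Used for validation ears, which must not influence the
#' training superimposition or the component axes.
#'
#' @param space a [shape_pca()] result.
#' @param configs list of n x 2 matrices / `ear_landmarks`.
#' @param template template used for sliding; `NULL` disables sliding.
#' @param mode sliding criterion, as in [slide_semilandmarks()].
#' @return n x retained score matrix.
#' @export
project_shapes <- function(space, configs, template = default_template(),
                           mode = c("bending_energy", "procrustes_distance")) {
  stopifnot(inherits(space, "shape_space"))
  mode <- match.arg(mode)
  consensus <- space$consensus
  be <- if (!is.null(template) && mode == "bending_energy")
    bending_energy_matrix(consensus) else NULL
  p <- nrow(consensus)
  # rotation-only placement at unit centroid size, matching the GPA
  # convention (the full-Procrustes scale is divided back out)
  place <- function(m) {
    fit <- align_pair(consensus, m)
    fit$aligned / fit$scale
  }
  aligned <- lapply(configs, function(cf) {
    m <- place(landmark_coords(cf))
    if (!is.null(template)) {
      m <- place(slide_one(m, consensus, template, be, mode))
    }
    m
  })
  flat <- flatten_coords(coords_to_array(aligned))
  sweep(flat, 2, space$center) %*%
    space$loadings[, seq_len(space$retained), drop = FALSE]
}
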