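# Procrustes geometry. All alignment is rotation-only (det +1): reflection is
# handled explicitly by reflect_to_reference_side(), never by the optimizer.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid — the standard scale measure in geometric morphometrics.
#'
#' @param points numeric n x 2 matrix.
#' @return A non-negative scalar.
#' @export
centroid_size <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

# center at origin and scale to unit centroid size
center_scale <- function(points) {
  points <- sweep(as.matrix(points), 2, colMeans(points))
  cs <- sqrt(sum(points^2))
  if (cs <= .Machine$double.eps)
    stop("degenerate configuration: zero centroid size.", call. = FALSE)
  points / cs
}

# optimal rotation (det +1) of unit-centered `target` onto `reference`,
# returned as a 2x2 matrix applied on the right: target %*% R
optimal_rotation <- function(reference, target) {
  m <- crossprod(target, reference)   # 2x2
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Pairwise full Procrustes superimposition
#'
#' Translates, scales and rotates (no reflection) the target configuration to
#' minimize the summed squared distance to the reference after the reference
#' has been centered and scaled to unit centroid size. The returned distance
#' is the full Procrustes distance: the root-sum-of-squares of the residual
#' point differences at the optimum.
#'
#' @param reference,target numeric n x 2 coordinate matrices (or
#'   `ear_landmarks`) with the same point count.
#' @return A list with `aligned` (the fitted target), `distance`
#'   (full Procrustes distance), `rotation` and `scale`.
#' @examples
#' tpl <- default_template()
#' a <- simulate_cohort(simulation_config(group_sizes = c(control = 2), seed = 1))
#' x <- a$landmarks[[1]]$points; y <- a$landmarks[[2]]$points
#' align_pair(x, y)$distance
#' @export
align_pair <- function(reference, target) {
  reference <- landmark_coords(reference)
  target <- landmark_coords(target)
  if (!identical(dim(reference), dim(target)))
    stop("reference and target must have the same dimensions.", call. = FALSE)
  xr <- center_scale(reference)
  xt <- center_scale(target)
  rot <- optimal_rotation(xr, xt)
  # optimal scale for unit-size configurations: trace of the rotated cross-product
  s <- sum(diag(t(xt %*% rot) %*% xr))
  aligned <- s * (xt %*% rot)
  d2 <- max(0, sum((xr - aligned)^2))
  list(aligned = aligned, distance = sqrt(d2), rotation = rot, scale = s)
}

landmark_coords <- function(x) {
  if (inherits(x, "ear_landmarks")) x$points else as.matrix(x)
}

coords_to_array <- function(configs) {
  configs <- lapply(configs, landmark_coords)
  p <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == p))
    stop("all configurations must have the same point count.", call. = FALSE)
  arr <- array(NA_real_, c(length(configs), p, 2L))
  for (i in seq_along(configs)) arr[i, , ] <- configs[[i]]
  arr
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of two or more configurations: each is centered
#' and scaled to unit centroid size, rotated to the current consensus, and the
#' consensus (itself rescaled to unit size) is recomputed until it changes by
#' less than `tol` or `max_iters` is reached. The aligned configurations all
#' have centroid at the origin and unit centroid size; the consensus is their
#' coordinate-wise mean.
#'
#' @param configs list of n x 2 matrices or `ear_landmarks`, length >= 2.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iters iteration cap.
#' @return An object of class `aligned_set`: list with `coords`
#'   (n_configs x n_points x 2 array), `consensus`, `iterations`,
#'   `consensus_change`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iters = 100L) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    configs <- lapply(seq_len(dim(configs)[1]), function(i) configs[i, , ])
  }
  if (length(configs) < 2L)
    stop("GPA needs at least two configurations.", call. = FALSE)
  mats <- lapply(configs, function(m) center_scale(landmark_coords(m)))
  consensus <- center_scale(Reduce(`+`, mats) / length(mats))
  change <- Inf
  iter <- 0L
  while (iter < max_iters && change > tol) {
    iter <- iter + 1L
    mats <- lapply(mats, function(m) m %*% optimal_rotation(consensus, m))
    new_consensus <- center_scale(Reduce(`+`, mats) / length(mats))
    change <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
  }
  structure(
    list(coords = coords_to_array(mats), consensus = consensus,
         iterations = iter, consensus_change = change),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d configurations, %d points, %d GPA iterations (final change %.2e)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$iterations, x$consensus_change))
  invisible(x)
}

#' Pairwise Procrustes distances within an aligned set
#'
#' @param aligned an [gpa()] result.
#' @return A `dist`-like full matrix of pairwise full Procrustes distances.
#' @export
procrustes_distances <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  n <- dim(aligned$coords)[1]
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[i, j] <- out[j, i] <-
        align_pair(aligned$coords[i, , ], aligned$coords[j, , ])$distance
    }
  }
  out
}
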