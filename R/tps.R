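# Thin-plate-spline bending energy and semilandmark sliding.

#' Thin-plate-spline bending-energy matrix
#'
#' Builds the standard 2D TPS bending-energy matrix for a reference
#' configuration: the radial kernel K_ij = r^2 log(r^2) (0 on the diagonal) is
#' bordered with the affine block Q = (1, x, y) into
#' L = \[\[K, Q\], \[Q', 0\]\], and the upper-left p x p block of the inverse
#' of L is returned. The result is symmetric positive semi-definite with the
#' affine transforms of the reference in its null space: rigid or affine
#' displacement fields have zero bending energy.
#'
#' @param reference numeric p x 2 matrix, no coincident points.
#' @return Symmetric p x p matrix.
#' @export
bending_energy_matrix <- function(reference) {
  x <- landmark_coords(reference)
  p <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  if (any(d2[upper.tri(d2)] < 1e-12))
    stop("coincident reference points: bending energy undefined.", call. = FALSE)
  k <- ifelse(d2 > 0, d2 * log(d2), 0)
  q <- cbind(1, x)
  l <- rbind(cbind(k, q), cbind(t(q), matrix(0, 3, 3)))
  linv <- solve(l)
  b <- linv[seq_len(p), seq_len(p), drop = FALSE]
  (b + t(b)) / 2
}

#' Bending energy of a displacement field
#'
#' Quadratic form of per-point displacements against a reference bending-energy
#' matrix, summed over the x and y coordinates.
#'
#' @param be p x p matrix from [bending_energy_matrix()].
#' @param displacement p x 2 matrix of per-point displacements.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(be, displacement) {
  d <- as.matrix(displacement)
  drop(crossprod(d[, 1], be %*% d[, 1]) + crossprod(d[, 2], be %*% d[, 2]))
}

# unit tangent directions for semilandmarks: chord between curve neighbors,
# taken from the configuration itself
semilandmark_tangents <- function(points, template) {
  sl <- which(template$semilandmark_mask)
  tang <- matrix(0, length(sl), 2L)
  for (k in seq_along(sl)) {
    j <- sl[k]
    seg <- template$segments[[which(vapply(template$segments,
                                           function(s) j %in% s, TRUE))]]
    pos <- match(j, seg)
    chord <- points[seg[pos + 1L], ] - points[seg[pos - 1L], ]
    nrm <- sqrt(sum(chord^2))
    tang[k, ] <- if (nrm > 0) chord / nrm else c(1, 0)
  }
  list(index = sl, tangents = tang)
}

# slide one configuration toward the consensus along its tangents.
# bending_energy mode: t = -(U'BU)^{-1} U'B (x - xbar) with B = I2 (x) be.
# procrustes_distance mode: tangent columns are orthonormal, so the 1D optimum
# is the negative tangential component of the deviation.
# Sliding amounts are clamped so a semilandmark never travels past (45% of
# the way to) either curve neighbor: larger moves would leave the curve the
# point parameterizes and destabilize the outer alternation.
slide_one <- function(points, consensus, template, be, mode, damp = 1) {
  tg <- semilandmark_tangents(points, template)
  sl <- tg$index
  m <- length(sl)
  if (m == 0L) return(points)
  dev <- points - consensus            # p x 2
  if (mode == "procrustes_distance") {
    t_amt <- -rowSums(tg$tangents * dev[sl, , drop = FALSE])
  } else {
    # reduced system in the m sliding amounts
    bu_x <- be[, sl, drop = FALSE] %*% diag(tg$tangents[, 1], m, m)
    bu_y <- be[, sl, drop = FALSE] %*% diag(tg$tangents[, 2], m, m)
    utbu <- crossprod(diag(tg$tangents[, 1], m, m), bu_x[sl, , drop = FALSE]) +
      crossprod(diag(tg$tangents[, 2], m, m), bu_y[sl, , drop = FALSE])
    rhs <- crossprod(bu_x, dev[, 1]) + crossprod(bu_y, dev[, 2])
    t_amt <- tryCatch(-solve(utbu, rhs), error = function(e) {
      warning("near-singular sliding system; applying 1e-10 ridge.", call. = FALSE)
      -solve(utbu + diag(1e-10, m), rhs)
    })
  }
  t_amt <- damp * drop(t_amt)
  lim <- 0.45 * neighbor_gaps(points, template, sl)
  t_amt <- pmin(pmax(t_amt, -lim), lim)
  points[sl, ] <- points[sl, , drop = FALSE] + t_amt * tg$tangents
  points
}

# distance to the nearer curve neighbor, per semilandmark
neighbor_gaps <- function(points, template, sl) {
  vapply(sl, function(j) {
    seg <- template$segments[[which(vapply(template$segments,
                                           function(s) j %in% s, TRUE))]]
    pos <- match(j, seg)
    d1 <- sqrt(sum((points[j, ] - points[seg[pos - 1L], ])^2))
    d2 <- sqrt(sum((points[j, ] - points[seg[pos + 1L], ])^2))
    min(d1, d2)
  }, numeric(1))
}

#' Slide semilandmarks against the Procrustes consensus
#'
#' Alternates generalized Procrustes superimposition with tangential sliding
#' of the template's semilandmarks. In each outer iteration the configurations
#' are (re-)aligned, the consensus and its bending-energy matrix are computed,
#' and every semilandmark of every configuration moves along the unit chord
#' between its curve neighbors so as to minimize either the bending energy of
#' its deviation from the consensus (`mode = "bending_energy"`, the default,
#' solved exactly via the reduced linear system) or its squared Procrustes
#' distance to the consensus (`mode = "procrustes_distance"`). Anchor points
#' (first and last of every curve) never move. The mode's objective is
#' tracked across outer iterations and the loop stops when its relative
#' change drops below `tol`.
#'
#' @param configs list of n x 2 matrices / `ear_landmarks`, or an
#'   n_configs x p x 2 array.
#' @param template an [default_template()] object.
#' @param mode sliding criterion.
#' @param max_outer_iters outer GPA/slide alternations (default 5).
#' @param tol relative objective-change tolerance.
#' @return An object of class `slid_set`: an `aligned_set` (final GPA of the
#'   slid configurations) with extra fields `objective` (per-iteration trace),
#'   `mode`, `outer_iterations`.
#' @export
slide_semilandmarks <- function(configs, template = default_template(),
                                mode = c("bending_energy", "procrustes_distance"),
                                max_outer_iters = 5L, tol = 1e-6) {
  mode <- match.arg(mode)
  aligned <- gpa(configs)
  n <- dim(aligned$coords)[1]
  # the recorded objective is the state objective at each outer-iteration
  # boundary: the mode's criterion for the current configurations against
  # their current consensus. The alternation is monotone-safeguarded: a
  # sliding step whose re-superimposed state raises the objective is retried
  # with halved sliding amounts, and the loop stops when no damping improves.
  state_objective <- function(al) {
    be <- if (mode == "bending_energy")
      bending_energy_matrix(al$consensus) else NULL
    slide_objective(al$coords, al$consensus, be, mode)
  }
  obj <- state_objective(aligned)
  trace <- obj
  for (it in seq_len(max_outer_iters)) {
    consensus <- aligned$consensus
    be <- if (mode == "bending_energy") bending_energy_matrix(consensus) else NULL
    accepted <- FALSE
    damp <- 1
    for (try in 1:5) {
      coords <- aligned$coords
      for (i in seq_len(n)) {
        coords[i, , ] <- slide_one(coords[i, , ], consensus, template, be,
                                   mode, damp = damp)
      }
      candidate <- gpa(coords)
      cand_obj <- state_objective(candidate)
      if (cand_obj <= obj * (1 + 1e-12)) {
        accepted <- TRUE
        break
      }
      damp <- damp / 2
    }
    if (!accepted) break
    improved <- obj - cand_obj
    aligned <- candidate
    obj <- cand_obj
    trace <- c(trace, obj)
    if (improved < tol * max(trace[1], .Machine$double.eps)) break
  }
  aligned$objective <- trace
  aligned$mode <- mode
  aligned$outer_iterations <- length(trace) - 1L
  class(aligned) <- c("slid_set", class(aligned))
  aligned
}

slide_objective <- function(coords, consensus, be, mode) {
  n <- dim(coords)[1]
  total <- 0
  for (i in seq_len(n)) {
    dev <- coords[i, , ] - consensus
    total <- total + if (is.null(be)) sum(dev^2) else bending_energy(be, dev)
  }
  total
}
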