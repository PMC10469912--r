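#' The 41-point external-ear landmark template
#'
#' Returns the fixed landmark catalogue used throughout the package: 41 named
#' 2D points organised into seven anatomical curve segments of the pinna
#' (outer helix, inner helix, lobe, tragus, antitragus, crus helicis, concha).
#' There is deliberately no antihelix segment: antihelix points are not
#' reproducible between annotators and are excluded from the catalogue.
#'
#' Within each curve the first and last points are fixed anatomical anchors;
#' interior points are semilandmarks allowed to slide tangentially during
#' superimposition (see [slide_semilandmarks()]). Every semilandmark therefore
#' has both a predecessor and a successor on its curve.
#'
#' @return An object of class `ear_template`: a list with
#'   \describe{
#'     \item{point_names}{character vector of 41 landmark identifiers.}
#'     \item{segments}{named list mapping each curve to its ordered point
#'       indices (1-based).}
#'     \item{semilandmark_mask}{logical vector of length 41; `TRUE` for points
#'       that slide along their curve.}
#'   }
#' @examples
#' tpl <- default_template()
#' tpl$segments$concha
#' sum(tpl$semilandmark_mask)
#' @export
default_template <- function() {
  seg_sizes <- c(
    outer_helix  = 12L,
    inner_helix  = 8L,
    lobe         = 5L,
    tragus       = 3L,
    antitragus   = 3L,
    crus_helicis = 3L,
    concha       = 7L
  )
  stopifnot(sum(seg_sizes) == 41L)
  idx <- 0L
  segments <- lapply(seg_sizes, function(k) {
    out <- idx + seq_len(k)
    idx <<- idx + k
    out
  })
  point_names <- unlist(lapply(names(seg_sizes), function(nm) {
    sprintf("%s_%02d", nm, seq_len(seg_sizes[[nm]]))
  }), use.names = FALSE)
  mask <- rep(FALSE, 41L)
  for (s in segments) {
    if (length(s) > 2L) mask[s[-c(1L, length(s))]] <- TRUE
  }
  structure(
    list(point_names = point_names, segments = segments,
         semilandmark_mask = mask),
    class = "ear_template"
  )
}

#' @export
print.ear_template <- function(x, ...) {
  cat("<ear_template> 41 points,", length(x$segments), "curve segments\n")
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat(sprintf("  %-13s %2d points (indices %d-%d), %d sliding\n",
                nm, length(s), min(s), max(s),
                sum(x$semilandmark_mask[s])))
  }
  invisible(x)
}

#' Construct an ear landmark configuration
#'
#' Bundles a 41 x 2 coordinate matrix (image pixels, x rightward, y downward)
#' with the ear side and the template it follows. Coordinates must be finite
#' and not all identical (the centroid size must be positive).
#'
#' @param points numeric matrix, one row per template point, columns x and y.
#' @param side `"left"` or `"right"`.
#' @param template an [default_template()] object.
#' @return An object of class `ear_landmarks`.
#' @export
ear_landmarks <- function(points, side = c("right", "left"),
                          template = default_template()) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric matrix with two columns (x, y).", call. = FALSE)
  n <- length(template$point_names)
  if (nrow(points) != n)
    stop(sprintf("expected %d points, got %d.", n, nrow(points)), call. = FALSE)
  if (!all(is.finite(points)))
    stop("all landmark coordinates must be finite.", call. = FALSE)
  if (centroid_size(points) <= .Machine$double.eps)
    stop("degenerate configuration: all points coincide.", call. = FALSE)
  dimnames(points) <- list(template$point_names, c("x", "y"))
  structure(list(points = points, side = side, template = template),
            class = "ear_landmarks")
}

#' @export
print.ear_landmarks <- function(x, ...) {
  cat(sprintf("<ear_landmarks> %s ear, %d points, centroid size %.2f px\n",
              x$side, nrow(x$points), centroid_size(x$points)))
  invisible(x)
}

#' Mirror a landmark configuration about the vertical axis
#'
#' Applies the raw reflection x -> -x, keeping point order and side label.
#' This is an involution: mirroring twice restores the original coordinates.
#'
#' @param landmarks an [ear_landmarks()] object.
#' @return The mirrored `ear_landmarks`.
#' @seealso [reflect_to_reference_side()]
#' @export
mirror_landmarks <- function(landmarks) {
  stopifnot(inherits(landmarks, "ear_landmarks"))
  landmarks$points[, 1] <- -landmarks$points[, 1]
  landmarks
}

#' Reflect a left ear into the right-ear reference frame
#'
#' Left and right ears are pooled in one shape space by mirroring every left
#' ear about the vertical axis before superimposition. Right ears pass through
#' unchanged, so the operation is idempotent. Reflection is explicit and
#' happens only here: the Procrustes machinery itself is rotation-only
#' (determinant +1), because a silent reflection during alignment would erase
#' the left/right asymmetry signal the fluctuating-asymmetry index measures.
#'
#' @param landmarks an [ear_landmarks()] object.
#' @return `ear_landmarks` in the right-ear frame (`side` set to `"right"`).
#' @export
reflect_to_reference_side <- function(landmarks) {
  stopifnot(inherits(landmarks, "ear_landmarks"))
  if (landmarks$side == "left") {
    landmarks <- mirror_landmarks(landmarks)
    landmarks$side <- "right"
  }
  landmarks
}
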