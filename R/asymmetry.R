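# Fluctuating asymmetry: shape difference between an ear and the mirrored
# contralateral ear, after removal of position, size and rotation.

#' Raw fluctuating-asymmetry index for one ear pair
#'
#' Mirrors the left ear into the right-ear frame and returns the full
#' Procrustes distance between the two configurations ([align_pair()]:
#' translation, scale and rotation removed, no reflection). A perfectly
#' symmetric pair scores 0.
#'
#' @param left,right `ear_landmarks` for the two ears of one patient; both
#'   must carry landmarks (only Marx grade 0-I ears can be landmarked).
#' @return Non-negative scalar.
#' @export
fluctuating_asymmetry_index <- function(left, right) {
  if (is.null(left) || is.null(right))
    stop("both ears must carry landmarks to compute fluctuating asymmetry.",
         call. = FALSE)
  stopifnot(inherits(left, "ear_landmarks"), inherits(right, "ear_landmarks"))
  lref <- reflect_to_reference_side(left)
  rref <- reflect_to_reference_side(right)
  align_pair(rref$points, lref$points)$distance
}

#' Normalize raw fluctuating-asymmetry values to \[0, 1\]
#'
#' Divides by the cohort maximum. The normalization constant is frozen from
#' the training cohort: pass it via `reference_max` when scoring new patients,
#' in which case values are clipped into \[0, 1\].
#'
#' @param raw numeric vector of raw FA indices.
#' @param reference_max training-cohort maximum; defaults to `max(raw)`.
#' @return Numeric vector in \[0, 1\], with attribute `reference_max`.
#' @export
normalize_fa <- function(raw, reference_max = NULL) {
  if (any(raw < 0, na.rm = TRUE))
    stop("raw FA indices must be non-negative.", call. = FALSE)
  if (is.null(reference_max)) reference_max <- max(raw, na.rm = TRUE)
  if (!is.finite(reference_max) || reference_max <= 0)
    stop("`reference_max` must be a positive finite scalar.", call. = FALSE)
  out <- pmin(pmax(raw / reference_max, 0), 1)
  attr(out, "reference_max") <- reference_max
  out
}
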