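# Spinal morphometry: kyphosis index, body length, pedicle length, and
# the curved L4-L6 canal length.

#' Kyphosis index
#'
#' KI = AB / CD, where AB is the straight (chord) distance between two
#' landmark points on the dorsal profile and CD is the maximum
#' perpendicular distance from the chord to the profile between them.
#' Lower KI means a more kyphotic spine. A perfectly straight profile has
#' CD = 0 and is reported as +Inf with a warning.
#'
#' @param dorsal_profile a `polyline3d` (2D points accepted) tracing the
#'   dorsal contour on the lateral projection.
#' @param start_landmark,end_landmark indices into the profile points
#'   marking the chord endpoints (defaults: first and last point).
#' @return dimensionless kyphosis index.
#' @export
kyphosis_index <- function(dorsal_profile, start_landmark = 1,
                           end_landmark = NULL) {
  if (!inherits(dorsal_profile, "polyline3d"))
    dorsal_profile <- polyline3d(dorsal_profile)
  p <- dorsal_profile$points
  if (is.null(end_landmark)) end_landmark <- nrow(p)
  if (nrow(p) < 3L) stop_bad("profile needs at least 3 points")
  if (start_landmark < 1L || end_landmark > nrow(p) ||
      start_landmark >= end_landmark)
    stop_bad("landmarks must index the profile with start < end")
  a <- p[start_landmark, ]; b <- p[end_landmark, ]
  ab <- b - a
  chord <- sqrt(sum(ab^2))
  if (chord == 0) stop_bad("chord landmarks coincide")
  seg <- p[start_landmark:end_landmark, , drop = FALSE]
  rel <- sweep(seg, 2, a)
  proj <- (rel %*% ab) / chord
  perp2 <- rowSums(rel^2) - proj^2
  cd <- sqrt(max(pmax(perp2, 0)))
  if (cd < .Machine$double.eps^0.5 * chord) {
    warning("profile is straight between the landmarks; KI is +Inf")
    return(Inf)
  }
  chord / cd
}

#' Body length from nasal tip to first caudal vertebra
#'
#' Euclidean distance between the "nasal_tip" and "first_caudal_base"
#' landmarks on the radiograph.
#'
#' @param landmarks a `landmark_set` containing both labels (2D).
#' @return length in mm.
#' @export
body_length <- function(landmarks) {
  need <- c("nasal_tip", "first_caudal_base")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop_bad("missing landmark(s): ",
                             paste(miss, collapse = ", "))
  sqrt(sum((landmarks[["nasal_tip"]] - landmarks[["first_caudal_base"]])^2))
}

#' Mean L5 pedicle length
#'
#' Mean of the left and right apex-to-base distances.
#'
#' @param landmarks a `landmark_set` with 3D points `left_apex`,
#'   `left_base`, `right_apex`, `right_base`.
#' @return mean pedicle length in mm.
#' @export
pedicle_length <- function(landmarks) {
  need <- c("left_apex", "left_base", "right_apex", "right_base")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop_bad("missing landmark(s): ",
                             paste(miss, collapse = ", "))
  l <- sqrt(sum((landmarks[["left_apex"]] - landmarks[["left_base"]])^2))
  r <- sqrt(sum((landmarks[["right_apex"]] - landmarks[["right_base"]])^2))
  (l + r) / 2
}

#' Curved L4-L6 length
#'
#' Length of the seed polyline drawn through the vertebral foramen from
#' the proximal end of L4 to the distal end of L6; identical semantics to
#' [curved_length()].
#'
#' @inheritParams curved_length
#' @return length in mm.
#' @export
l4l6_curved_length <- function(seeds, ...) curved_length(seeds, ...)
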