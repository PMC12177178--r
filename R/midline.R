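#' Midline frame: plane, injection side and exclusion band
#'
#' Describes the hemisphere partition used throughout the pipeline: the
#' midline plane `a*x + b*y + c*z + d = 0` in world micrometres (unit normal
#' `(a, b, c)`), the sign of the signed distance on the injection
#' (ipsilateral) side, and the half-width `w` of the sagittal
#' corticospinal-tract exclusion band bounded by the two planes parallel to
#' the midline at signed distances `-w` and `+w`.
#'
#' @param normal length-3 numeric, normalized internally to unit length.
#' @param offset scalar plane offset `d` in micrometres.
#' @param injection_side_sign `+1` or `-1`: the sign of `a*p + b*p + c*p + d`
#'   for points on the injection side; `NA` until set (see
#'   [set_injection_side()]).
#' @param exclusion_halfwidth_um half-width `w >= 0` of the exclusion band.
#' @return an object of class `midline_frame`.
#' @export
midline_frame <- function(normal, offset, injection_side_sign = NA_real_,
                          exclusion_halfwidth_um = 0) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || any(!is.finite(normal))) {
    stop("normal must be a finite length-3 vector", call. = FALSE)
  }
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("degenerate geometry: zero-length plane normal", call. = FALSE)
  normal <- normal / nn
  if (!is.na(injection_side_sign) && !injection_side_sign %in% c(-1, 1)) {
    stop("injection_side_sign must be +1 or -1", call. = FALSE)
  }
  if (exclusion_halfwidth_um < 0) {
    stop("exclusion_halfwidth_um must be >= 0", call. = FALSE)
  }
  structure(
    list(normal = normal,
         offset = as.numeric(offset),
         injection_side_sign = as.numeric(injection_side_sign),
         exclusion_halfwidth_um = as.numeric(exclusion_halfwidth_um)),
    class = "midline_frame"
  )
}

#' @export
print.midline_frame <- function(x, ...) {
  cat(sprintf("<midline_frame> %.4f x + %.4f y + %.4f z + %.4f = 0\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  cat(sprintf("  injection side sign: %s; exclusion half-width: %g um\n",
              ifelse(is.na(x$injection_side_sign), "unset",
                     sprintf("%+d", as.integer(x$injection_side_sign))),
              x$exclusion_halfwidth_um))
  invisible(x)
}

#' Fit the midline plane through three coplanar points
#'
#' Computes the plane `a*x + b*y + c*z + d = 0` through three
#' operator-chosen points on the brain midline (world micrometres). The unit
#' normal is canonicalized to point toward the positive mediolateral axis so
#' the same point set always yields the same signed-distance convention,
#' regardless of the order of the three points.
#'
#' @param p1,p2,p3 length-3 numeric points in micrometres; pairwise distinct
#'   and not collinear.
#' @param ml_axis which world coordinate is mediolateral (1, 2 or 3);
#'   used only to canonicalize the normal's sign.
#' @param exclusion_halfwidth_um half-width of the CST exclusion band carried
#'   by the returned frame (default 0).
#' @return a [midline_frame()] with the injection side sign unset.
#' @export
fit_plane <- function(p1, p2, p3, ml_axis = 1L, exclusion_halfwidth_um = 0) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  if (length(p1) != 3L || length(p2) != 3L || length(p3) != 3L) {
    stop("midline points must be length-3", call. = FALSE)
  }
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  # Collinearity test on the triangle area, relative to the points' scale.
  scale2 <- max(sum(v1^2), sum(v2^2), sum((p3 - p2)^2), 1)
  if (sqrt(sum(n^2)) < 1e-9 * scale2) {
    stop("degenerate geometry: the three midline points are collinear",
         call. = FALSE)
  }
  n <- n / sqrt(sum(n^2))
  ml_axis <- as.integer(ml_axis)
  if (!ml_axis %in% 1:3) stop("ml_axis must be 1, 2 or 3", call. = FALSE)
  # Canonical sign: positive component along the ML axis; fall back to the
  # first nonzero component for planes parallel to ML.
  pivot <- if (abs(n[ml_axis]) > 1e-12) n[ml_axis] else n[which(abs(n) > 1e-12)[1]]
  if (pivot < 0) n <- -n
  d <- -sum(n * p1)
  midline_frame(n, d, exclusion_halfwidth_um = exclusion_halfwidth_um)
}

#' Set the injection (ipsilateral) side of a midline frame
#'
#' @param frame a [midline_frame()].
#' @param side `+1`/`-1`, or one of `"positive"`, `"negative"`; the sign of
#'   the signed distance on the injection side. With the default axis
#'   convention (canonical normal toward +ML), `"positive"` means the
#'   injection hemisphere lies at larger mediolateral coordinates.
#' @return the frame with `injection_side_sign` set.
#' @export
set_injection_side <- function(frame, side) {
  stopifnot(inherits(frame, "midline_frame"))
  sgn <- if (is.character(side)) {
    switch(match.arg(side, c("positive", "negative")), positive = 1, negative = -1)
  } else {
    as.numeric(side)
  }
  if (!sgn %in% c(-1, 1)) stop("side must resolve to +1 or -1", call. = FALSE)
  frame$injection_side_sign <- sgn
  frame
}

#' Signed distance from the midline plane
#'
#' Evaluates `a*px + b*py + c*pz + d` for one or more world points. Because
#' the normal is unit length this is the signed Euclidean distance in
#' micrometres: positive on the side the canonical normal points to, zero
#' exactly on the plane.
#'
#' @param frame a [midline_frame()].
#' @param points length-3 point or an `n x 3` matrix of points (um).
#' @return numeric vector of signed distances.
#' @export
signed_distance <- function(frame, points) {
  stopifnot(inherits(frame, "midline_frame"))
  p <- as_point_matrix(points)
  as.vector(p %*% frame$normal) + frame$offset
}

#' Classify points as ipsi, contra, on-plane or excluded
#'
#' Applies the hemisphere partition: a point is `excluded` when it falls
#' strictly inside the CST exclusion band (`|distance| < w`); otherwise
#' `on_plane` when its signed distance is exactly zero; otherwise `ipsi`
#' when the sign of its distance matches the injection side sign, and
#' `contra` when it does not. Exclusion is applied before hemisphere
#' assignment, so the lateralization index never sees tract voxels.
#'
#' @param frame a [midline_frame()] with the injection side sign set.
#' @param points length-3 point or `n x 3` matrix (um).
#' @return character vector over `{"ipsi", "contra", "on_plane", "excluded"}`.
#' @export
classify_side <- function(frame, points) {
  stopifnot(inherits(frame, "midline_frame"))
  if (is.na(frame$injection_side_sign)) {
    stop("configuration error: injection side sign is unset (see set_injection_side)",
         call. = FALSE)
  }
  d <- signed_distance(frame, points)
  out <- character(length(d))
  w <- frame$exclusion_halfwidth_um
  excl <- abs(d) < w
  onp <- !excl & d == 0
  ipsi <- !excl & !onp & sign(d) == frame$injection_side_sign
  out[excl] <- "excluded"
  out[onp] <- "on_plane"
  out[ipsi] <- "ipsi"
  out[!excl & !onp & !ipsi] <- "contra"
  out
}
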