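#' Parameters of the three-convexity curve family
#'
#' The spinal canal cross-section is modelled by the two-parameter sextic
#' \deqn{C_{a,b}: (x^2+y^2)^3 = (a(x^2+y^2) - b(x^3-3xy^2))^2,}
#' whose bounded branch has the closed polar form
#' \eqn{r(\theta) = a / (1 + b\cos 3\theta)} about the family origin.
#' `a` sets the overall scale and `b` the depth of the three convexities;
#' `b = 0` degenerates to the circle of radius `a`.  The family carries no
#' translation parameters: it is always evaluated in a working frame whose
#' origin is the per-slice canal-center estimate (see [working_frame()]).
#'
#' @param a scale parameter, working-frame units, `> 0`.
#' @param b convexity-depth parameter, dimensionless, `|b| < 1` (the polar
#'   radius diverges otherwise and the curve is unbounded).
#' @param center numeric length-2, working-frame coordinates of the family
#'   origin (almost always `c(0, 0)`; kept explicit for plotting).
#' @return An object of class `three_convexity_params`.
#' @seealso [three_convexity_radius()], [three_convexity_residual()]
#' @export
three_convexity_params <- function(a, b, center = c(0, 0)) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(center), length(center) == 2L, all(is.finite(center)))
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (abs(b) >= 1) stop("|b| must be < 1 for a bounded curve", call. = FALSE)
  structure(list(a = a, b = b, center = as.numeric(center)),
            class = "three_convexity_params")
}

#' Parameters of the four-parameter ellipse family
#'
#' The spinal cord cross-section is modelled by the axis-aligned ellipse
#' \deqn{E_{a,b,c,d}: b^2(x-c)^2 + a^2(y-d)^2 - a^2 b^2 = 0,}
#' with semi-axes `a` (along x) and `b` (along y) and center `(c, d)`.
#'
#' @param a,b semi-axes in working-frame units, both `> 0`.
#' @param c,d center coordinates in working-frame units.
#' @return An object of class `ellipse_params`.
#' @export
ellipse_params <- function(a, b, c = 0, d = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L,
            all(is.finite(c(a, b, c, d))))
  if (a <= 0 || b <= 0) stop("semi-axes must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d), class = "ellipse_params")
}

#' @export
print.three_convexity_params <- function(x, ...) {
  cat(sprintf("<three-convexity curve>  a = %.4g, b = %.4g, center = (%.4g, %.4g)\n",
              x$a, x$b, x$center[1], x$center[2]))
  invisible(x)
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("<ellipse>  semi-axes = (%.4g, %.4g), center = (%.4g, %.4g)\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Working frame: pixel-to-parameter-space coordinate mapping
#'
#' The curve families are detected in a dimensionless working frame so
#' that the fixed 0.02 accumulator cell side is a meaningful (roughly
#' 3--10\%) relative resolution on the canal scale.  The frame maps the
#' pixel coordinate `origin` to `(0, 0)` and `scale` pixels to one working
#' unit; with the default 55 mm scale on 1 mm pixels a typical adult
#' canal radius falls at 0.2--0.6 working units.
#'
#' @param origin numeric length-2 pixel coordinate (x, y) mapped to (0, 0).
#' @param scale length in pixels mapped to 1 working unit, `> 0`.
#' @return An object of class `working_frame`.
#' @export
working_frame <- function(origin, scale) {
  stopifnot(is.numeric(origin), length(origin) == 2L, all(is.finite(origin)),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("'scale' must be > 0", call. = FALSE)
  structure(list(origin = as.numeric(origin), scale = scale),
            class = "working_frame")
}

#' Convert between pixel and working-frame coordinates
#'
#' @param frame a [working_frame()].
#' @param xy numeric matrix (n x 2) or length-2 vector of coordinates.
#' @return Matrix (n x 2) of converted coordinates.
#' @export
pixel_to_frame <- function(frame, xy) {
  xy <- rbind2cols(xy)
  cbind((xy[, 1] - frame$origin[1]) / frame$scale,
        (xy[, 2] - frame$origin[2]) / frame$scale)
}

#' @rdname pixel_to_frame
#' @export
frame_to_pixel <- function(frame, xy) {
  xy <- rbind2cols(xy)
  cbind(xy[, 1] * frame$scale + frame$origin[1],
        xy[, 2] * frame$scale + frame$origin[2])
}

# coerce a length-2 vector or n x 2 matrix to matrix form
rbind2cols <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  stopifnot(ncol(xy) == 2L)
  xy
}

#' Signed residual of the three-convexity curve
#'
#' Evaluates \eqn{(x^2+y^2)^3 - (a(x^2+y^2) - b(x^3-3xy^2))^2} at
#' `p - center`.  The residual is zero iff the point lies on the curve
#' (the origin is an algebraic double root satisfied by every member of
#' the family, which is why voting excludes a small disk around it) and
#' strictly negative inside the bounded lobe away from the origin.
#'
#' @param p numeric matrix (n x 2) or length-2 vector, working-frame point(s).
#' @param params a [three_convexity_params()].
#' @return Numeric vector of signed residuals.
#' @export
three_convexity_residual <- function(p, params) {
  p <- rbind2cols(p)
  x <- p[, 1] - params$center[1]
  y <- p[, 2] - params$center[2]
  r2 <- x^2 + y^2
  r2^3 - (params$a * r2 - params$b * (x^3 - 3 * x * y^2))^2
}

#' Polar radius of the three-convexity curve
#'
#' Closed polar form \eqn{r(\theta) = a / (1 + b \cos 3\theta)} of the
#' bounded branch, valid for `|b| < 1`.
#'
#' @param theta angle(s) in radians, measured about the family center.
#' @param params a [three_convexity_params()].
#' @return Numeric vector of radii (working-frame units, all `> 0`).
#' @export
three_convexity_radius <- function(theta, params) {
  if (abs(params$b) >= 1)
    stop("|b| must be < 1: the curve is unbounded", call. = FALSE)
  params$a / (1 + params$b * cos(3 * theta))
}

#' Signed residual of the ellipse
#'
#' Evaluates \eqn{b^2(x-c)^2 + a^2(y-d)^2 - a^2 b^2}; zero on the
#' ellipse, negative strictly inside.
#'
#' @inheritParams three_convexity_residual
#' @param params an [ellipse_params()].
#' @return Numeric vector of signed residuals.
#' @export
ellipse_residual <- function(p, params) {
  p <- rbind2cols(p)
  params$b^2 * (p[, 1] - params$c)^2 +
    params$a^2 * (p[, 2] - params$d)^2 - params$a^2 * params$b^2
}

#' Sample points on a curve boundary
#'
#' Returns `n` points at uniformly spaced polar angles on the boundary of
#' a three-convexity curve or ellipse; used by the phantom generator and
#' as test fixtures for the Hough machinery.
#'
#' @param params a [three_convexity_params()] or [ellipse_params()].
#' @param n number of points, `>= 3`.
#' @return Numeric matrix (n x 2) of working-frame coordinates.
#' @export
sample_curve <- function(params, n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 3) stop("'n' must be at least 3", call. = FALSE)
  UseMethod("sample_curve")
}

#' @export
sample_curve.three_convexity_params <- function(params, n) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  r <- three_convexity_radius(theta, params)
  cbind(params$center[1] + r * cos(theta),
        params$center[2] + r * sin(theta))
}

#' @export
sample_curve.ellipse_params <- function(params, n) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(params$c + params$a * cos(theta),
        params$d + params$b * sin(theta))
}

#' Test whether points lie strictly inside a curve
#'
#' The inside test used to rasterize binary masks: for the ellipse, the
#' sign of the residual; for the three-convexity curve, comparison of the
#' point's polar radius about the family center with the boundary radius
#' at the same angle.
#'
#' @param p numeric matrix (n x 2) or length-2 vector of working-frame points.
#' @param params a [three_convexity_params()] or [ellipse_params()].
#' @return Logical vector.
#' @export
point_inside <- function(p, params) UseMethod("point_inside", params)

#' @export
point_inside.three_convexity_params <- function(p, params) {
  p <- rbind2cols(p)
  x <- p[, 1] - params$center[1]
  y <- p[, 2] - params$center[2]
  rp <- sqrt(x^2 + y^2)
  rp < three_convexity_radius(atan2(y, x), params)
}

#' @export
point_inside.ellipse_params <- function(p, params) {
  ellipse_residual(p, params) < 0
}

#' Enclosed area of a curve family member
#'
#' Closed forms used as analytic ground truth: the three-convexity lobe
#' has area \eqn{\pi a^2 / (1-b^2)^{3/2}} (polar area integral of
#' \eqn{r(\theta)}, identical to a conic of semi-latus rectum `a` and
#' eccentricity `|b|` because \eqn{\cos 3\theta} completes three full
#' periods), the ellipse \eqn{\pi a b}.
#'
#' @param params a [three_convexity_params()] or [ellipse_params()].
#' @return Area in squared working-frame units.
#' @export
curve_area <- function(params) UseMethod("curve_area")

#' @export
curve_area.three_convexity_params <- function(params) {
  pi * params$a^2 / (1 - params$b^2)^1.5
}

#' @export
curve_area.ellipse_params <- function(params) pi * params$a * params$b
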