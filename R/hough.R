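#' Discretized parameter grid for Hough voting
#'
#' The parameter space of a curve family is discretized into cells of a
#' fixed side: 0.02 in working units, for both the two-dimensional
#' (canal) and four-dimensional (cord) spaces.  Cell k along a dimension
#' is centered at `lower + (k - 1/2) * side`; the number of cells per
#' dimension is `ceiling((upper - lower) / side)`.
#'
#' @param lower,upper numeric vectors of per-dimension bounds
#'   (length 2 for the three-convexity family, 4 for the ellipse family).
#' @param side cell side in working units (default 0.02).
#' @return A `parameter_grid` object.
#' @export
parameter_grid <- function(lower, upper, side = 0.02) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper),
            length(lower) %in% c(2L, 4L),
            is.numeric(side), length(side) == 1L)
  if (side <= 0) stop("cell side must be > 0", call. = FALSE)
  if (any(upper <= lower)) stop("need upper > lower in every dimension",
                                call. = FALSE)
  ncell <- as.integer(ceiling((upper - lower) / side - 1e-9))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 side = side, ncell = ncell, ndim = length(lower)),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter grid>  %dD, side %.3g, %s cells\n",
              x$ndim, x$side, paste(x$ncell, collapse = " x ")))
  invisible(x)
}

# cell centers along one grid dimension
grid_centers <- function(grid, dim) {
  grid$lower[dim] + (seq_len(grid$ncell[dim]) - 0.5) * grid$side
}

#' Hough voting: build the accumulator over a parameter grid
#'
#' Each edge point votes for every cell whose family member passes within
#' the point's tolerance band: the radial distance from the point to the
#' curve at the cell center must not exceed the maximum boundary
#' displacement induced by perturbing each parameter by half a cell side
#' (first-order bound, so a point lying exactly on a curve whose
#' parameters fall anywhere inside a cell votes for that cell).  The
#' accumulator value of a cell is then the number of Hough transforms
#' (one per edge point) passing through it.
#'
#' Points within `exclude_radius` of the working-frame origin are ignored
#' for the three-convexity family: the origin is an algebraic double root
#' satisfied by every member, and would vote indiscriminately.
#'
#' @param points an `edge_point_set` in working-frame coordinates.
#' @param grid a [parameter_grid()]; 2D for `"three_convexity"`
#'   (dimensions a, b), 4D for `"ellipse"` (a, b, c, d).
#' @param family `"three_convexity"` or `"ellipse"`.
#' @param exclude_radius origin exclusion radius for the three-convexity
#'   family (working units).
#' @return An `accumulator`: list with `counts` (integer array over the
#'   grid), `grid`, `family`, `n_points`.
#' @export
vote <- function(points, grid, family = c("three_convexity", "ellipse"),
                 exclude_radius = 0.05) {
  family <- match.arg(family)
  stopifnot(inherits(points, "edge_point_set"),
            inherits(grid, "parameter_grid"))
  need <- if (family == "three_convexity") 2L else 4L
  if (grid$ndim != need)
    stop(sprintf("grid dimensionality %d does not match family '%s' (needs %d)",
                 grid$ndim, family, need), call. = FALSE)

  counts <- if (family == "three_convexity")
    vote_canal(points$points, grid, exclude_radius)
  else
    vote_ellipse(points$points, grid)

  structure(list(counts = counts, grid = grid, family = family,
                 n_points = points$n),
            class = "accumulator")
}

# canal family: point (r, theta) lies on C_{a,b} iff a = r (1 + b cos 3theta);
# vote when |r - a/(1+b c3)| <= (s/2) (|dr/da| + |dr/db|)
vote_canal <- function(pts, grid, exclude_radius) {
  na <- grid$ncell[1]; nb <- grid$ncell[2]
  counts <- matrix(0L, na, nb)
  if (nrow(pts) == 0L) return(counts)
  A <- matrix(grid_centers(grid, 1), na, nb)
  B <- matrix(grid_centers(grid, 2), na, nb, byrow = TRUE)
  h <- grid$side / 2
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  c3 <- cos(3 * th)
  for (k in seq_along(r)) {
    if (r[k] < exclude_radius) next
    denom <- 1 + B * c3[k]
    ok <- denom > 0
    rc <- A / denom
    tol <- h * (1 / denom + A * abs(c3[k]) / denom^2)
    hit <- ok & abs(r[k] - rc) <= tol
    counts <- counts + hit
  }
  storage.mode(counts) <- "integer"
  counts
}

# ellipse family: radial distance about the candidate center, first-order
# tolerance in all four parameters
vote_ellipse <- function(pts, grid) {
  nc <- grid$ncell
  ctrs <- lapply(1:4, grid_centers, grid = grid)
  ntot <- prod(nc)
  # flat cell-center vectors, first dimension fastest (array order)
  A <- rep(ctrs[[1]], times = ntot / nc[1])
  B <- rep(rep(ctrs[[2]], each = nc[1]), times = ntot / (nc[1] * nc[2]))
  C <- rep(rep(ctrs[[3]], each = nc[1] * nc[2]), times = nc[4])
  D <- rep(ctrs[[4]], each = nc[1] * nc[2] * nc[3])
  counts <- integer(ntot)
  if (nrow(pts) > 0L) {
    h <- grid$side / 2
    A2 <- A^2; B2 <- B^2; AB <- A * B
    dAB2 <- AB * (A2 - B2)
    for (k in seq_len(nrow(pts))) {
      dx <- pts[k, 1] - C
      dy <- pts[k, 2] - D
      rho2 <- dx^2 + dy^2
      rho <- sqrt(rho2)
      small <- rho < 1e-12           # point at the candidate center: no vote
      rho2s <- ifelse(small, 1, rho2)
      cs2 <- dx^2 / rho2s            # cos^2 phi
      sn2 <- dy^2 / rho2s
      K <- B2 * cs2 + A2 * sn2
      K[small] <- 1
      Ki <- 1 / sqrt(K)
      re <- AB * Ki                  # boundary radius at the point's angle
      K32 <- Ki / K
      wa <- B * B2 * cs2 * K32
      wb <- A * A2 * sn2 * K32
      rp <- abs(dAB2) * sqrt(cs2 * sn2) * K32   # |r_e'(phi)|
      invrho <- ifelse(small, 0, 1 / rho)
      wc <- sqrt(cs2) + rp * sqrt(sn2) * invrho
      wd <- sqrt(sn2) + rp * sqrt(cs2) * invrho
      tol <- h * (wa + wb + wc + wd)
      counts <- counts + (!small & abs(rho - re) <= tol)
    }
  }
  array(as.integer(counts), dim = nc)
}

#' @export
print.accumulator <- function(x, ...) {
  cat(sprintf("<accumulator>  %s family, %s cells, %d points, max votes %d\n",
              x$family, paste(x$grid$ncell, collapse = " x "),
              x$n_points, if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

# radial point-to-curve distances for tie-breaking
radial_misfit <- function(pts, family, params) {
  if (family == "three_convexity") {
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    c3 <- cos(3 * atan2(pts[, 2], pts[, 1]))
    abs(r - params[1] / (1 + params[2] * c3))
  } else {
    dx <- pts[, 1] - params[3]; dy <- pts[, 2] - params[4]
    rho <- sqrt(dx^2 + dy^2)
    re <- params[1] * params[2] /
      sqrt(params[2]^2 * dx^2 / pmax(rho^2, 1e-24) +
           params[1]^2 * dy^2 / pmax(rho^2, 1e-24))
    abs(rho - re)
  }
}

#' Locate the accumulator maximum
#'
#' Returns the cell where the accumulator reaches its maximum.  The
#' half-cell tolerance band of [vote()] guarantees no missed votes but
#' lets several adjacent cells collect identical counts for clean
#' curves, so exact ties are structural.  When the edge points are
#' supplied, ties are broken by the smallest total squared radial
#' misfit of the tied cells' curves against the points (capped at one
#' cell side per point so clutter cannot dominate); any remaining tie,
#' and all ties when points are absent, fall back to the lowest
#' lexicographic multi-index.  Every path is fully deterministic.
#'
#' @param acc an `accumulator` from [vote()].
#' @param points optional `edge_point_set` used for misfit tie-breaking
#'   (normally the set that built the accumulator).
#' @return List with `index` (integer multi-index), `params` (parameter
#'   values at the cell center) and `votes`.
#' @export
find_peak <- function(acc, points = NULL) {
  stopifnot(inherits(acc, "accumulator"))
  m <- max(acc$counts)
  if (m == 0L)
    stop_no_curve("accumulator has no votes: no curve found")
  flat <- which(acc$counts == m)
  ind <- arrayInd(flat, dim(acc$counts))
  ord <- do.call(order, lapply(seq_len(ncol(ind)), function(j) ind[, j]))
  ind <- ind[ord, , drop = FALSE]
  best <- 1L
  if (nrow(ind) > 1L && !is.null(points) && points$n > 0L) {
    cap <- acc$grid$side
    score <- vapply(seq_len(nrow(ind)), function(k) {
      pars <- vapply(seq_len(ncol(ind)),
                     function(d) grid_centers(acc$grid, d)[ind[k, d]],
                     numeric(1))
      sum(pmin(radial_misfit(points$points, acc$family, pars), cap)^2)
    }, numeric(1))
    best <- which.min(score)   # first minimum: lexicographic fallback
  }
  bi <- ind[best, ]
  params <- vapply(seq_along(bi),
                   function(d) grid_centers(acc$grid, d)[bi[d]],
                   numeric(1))
  list(index = as.integer(bi), params = params, votes = m)
}

stop_no_curve <- function(msg) {
  stop(structure(class = c("no_curve_found", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Detect the spinal canal curve on one slice
#'
#' Runs the Hough vote of the edge points against the two-parameter
#' three-convexity family and returns the accumulator peak.
#'
#' @param points `edge_point_set` in working-frame coordinates.
#' @param grid 2D [parameter_grid()] over (a, b).
#' @param min_points minimum number of edge points required.
#' @param min_votes minimum accumulator peak height to accept a detection.
#' @param exclude_radius origin exclusion radius (working units).
#' @return List with `params` ([three_convexity_params()]) and `votes`.
#' @export
detect_canal <- function(points, grid, min_points = 10L, min_votes = 5L,
                         exclude_radius = 0.05) {
  stopifnot(inherits(points, "edge_point_set"))
  if (points$n < min_points)
    stop_no_curve(sprintf("only %d edge points (need >= %d)",
                          points$n, min_points))
  acc <- vote(points, grid, "three_convexity", exclude_radius = exclude_radius)
  keep <- sqrt(rowSums(points$points^2)) >= exclude_radius
  pk <- find_peak(acc, edge_point_set(points$points[keep, , drop = FALSE]))
  if (pk$votes < min_votes)
    stop_no_curve(sprintf("peak has %d votes (need >= %d)", pk$votes, min_votes))
  list(params = three_convexity_params(pk$params[1], pk$params[2]),
       votes = pk$votes)
}

#' Detect the spinal cord ellipse on one slice
#'
#' Runs the Hough vote of edge points (pre-filtered to the canal
#' interior) against the four-parameter ellipse family.
#'
#' Candidate ellipses are restricted to a plausible cord shape: cells
#' whose semi-axis ratio exceeds `max_axis_ratio` are excluded from the
#' peak search.  Near-degenerate (very flat) ellipse cells have
#' geometrically enormous capture bands along their long axis -- the
#' boundary radius there moves superlinearly with the short semi-axis --
#' so without this constraint they act as vote sinks in cluttered
#' scenes, while an actual spinal cord cross-section never exceeds an
#' axis ratio of about 2.
#'
#' @param points `edge_point_set`, canal-interior points in working-frame
#'   coordinates.
#' @param grid 4D [parameter_grid()] over (a, b, c, d).
#' @param max_axis_ratio maximum admissible semi-axis ratio.
#' @inheritParams detect_canal
#' @return List with `params` ([ellipse_params()]) and `votes`.
#' @export
detect_cord <- function(points, grid, min_points = 10L, min_votes = 5L,
                        max_axis_ratio = 2.5) {
  stopifnot(inherits(points, "edge_point_set"))
  if (points$n < min_points)
    stop_no_curve(sprintf("only %d edge points (need >= %d)",
                          points$n, min_points))
  acc <- vote(points, grid, "ellipse")
  ca <- grid_centers(grid, 1); cb <- grid_centers(grid, 2)
  ratio <- outer(ca, cb, function(a, b) pmax(a / b, b / a))
  bad <- which(ratio > max_axis_ratio, arr.ind = TRUE)
  if (nrow(bad) > 0)
    for (k in seq_len(nrow(bad)))
      acc$counts[bad[k, 1], bad[k, 2], , ] <- 0L
  pk <- find_peak(acc, points)
  if (pk$votes < min_votes)
    stop_no_curve(sprintf("peak has %d votes (need >= %d)", pk$votes, min_votes))
  list(params = ellipse_params(pk$params[1], pk$params[2],
                               pk$params[3], pk$params[4]),
       votes = pk$votes)
}
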