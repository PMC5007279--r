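#' Canny edge detection on a 2D slice
#'
#' Standard Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and two-threshold
#' hysteresis (weak edges are kept only when 8-connected to a strong
#' edge).  Thresholds are given as fractions of the maximum gradient
#' magnitude of the smoothed slice, so the same settings work across
#' scanners once the slice has been intensity-windowed.
#'
#' @param slice numeric matrix, indexed `[x, y]`.
#' @param sigma Gaussian smoothing scale in pixels (default 1).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= low <= high`.
#' @return An `edge_point_set`: list with `points` (n x 2 matrix of pixel
#'   coordinates, 1-based, x = first array index) and `n`.
#' @export
detect_edges <- function(slice, sigma = 1, low = 0.1, high = 0.3) {
  stopifnot(is.matrix(slice), is.numeric(slice))
  if (nrow(slice) < 2L || ncol(slice) < 2L)
    stop("slice must be at least 2 x 2 pixels", call. = FALSE)
  if (low < 0 || high < low)
    stop("need 0 <= low <= high", call. = FALSE)

  sm <- if (sigma > 0)
    EBImage::gblur(slice, sigma = sigma, boundary = "replicate")
  else slice
  nx <- nrow(sm); ny <- ncol(sm)

  # Sobel gradients, replicated borders
  pad <- sm[c(1L, seq_len(nx), nx), c(1L, seq_len(ny), ny)]
  i <- seq_len(nx) + 1L; j <- seq_len(ny) + 1L
  gx <- (pad[i + 1L, j - 1L] + 2 * pad[i + 1L, j] + pad[i + 1L, j + 1L] -
         pad[i - 1L, j - 1L] - 2 * pad[i - 1L, j] - pad[i - 1L, j + 1L])
  gy <- (pad[i - 1L, j + 1L] + 2 * pad[i, j + 1L] + pad[i + 1L, j + 1L] -
         pad[i - 1L, j - 1L] - 2 * pad[i, j - 1L] - pad[i + 1L, j - 1L])
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0)
    return(structure(list(points = matrix(numeric(0), ncol = 2L), n = 0L),
                     class = "edge_point_set"))

  # non-maximum suppression with bilinear interpolation of the gradient
  # magnitude one pixel along +/- the gradient direction
  padm <- matrix(0, nx + 2L, ny + 2L)
  padm[i, j] <- mag
  ux <- ifelse(mag > 0, gx / mag, 0)
  uy <- ifelse(mag > 0, gy / mag, 0)
  I <- matrix(seq_len(nx), nx, ny)
  J <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  interp <- function(xq, yq) {
    xq <- clamp(xq, 0, nx + 0.9999); yq <- clamp(yq, 0, ny + 0.9999)
    fx <- floor(xq); fy <- floor(yq)
    tx <- xq - fx; ty <- yq - fy
    at <- function(ii, jj) padm[cbind(as.vector(ii) + 1L, as.vector(jj) + 1L)]
    v <- (1 - tx) * (1 - ty) * at(fx, fy) + tx * (1 - ty) * at(fx + 1, fy) +
      (1 - tx) * ty * at(fx, fy + 1) + tx * ty * at(fx + 1, fy + 1)
    matrix(v, nx, ny)
  }
  n1 <- interp(I + ux, J + uy)
  n2 <- interp(I - ux, J - uy)
  keep <- mag >= n1 & mag >= n2 & mag > 0

  strong <- keep & (mag >= high * mmax)
  weak <- keep & (mag >= low * mmax)
  if (!any(strong))
    return(structure(list(points = matrix(numeric(0), ncol = 2L), n = 0L),
                     class = "edge_point_set"))

  # hysteresis: weak components containing at least one strong pixel survive
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  good <- unique(lab[strong])
  final <- weak & (lab %in% good) & lab > 0
  dim(final) <- dim(weak)

  idx <- which(final, arr.ind = TRUE)
  structure(list(points = cbind(as.numeric(idx[, 1]), as.numeric(idx[, 2])),
                 n = nrow(idx)),
            class = "edge_point_set")
}

#' Construct an edge point set from raw coordinates
#'
#' @param points numeric matrix (n x 2) of coordinates.
#' @param source_slice optional slice index the points came from.
#' @return An `edge_point_set`.
#' @export
edge_point_set <- function(points, source_slice = NA_integer_) {
  points <- rbind2cols(points)
  structure(list(points = points, n = nrow(points),
                 source_slice = source_slice),
            class = "edge_point_set")
}

#' @export
print.edge_point_set <- function(x, ...) {
  cat(sprintf("<edge point set>  %d points\n", x$n))
  invisible(x)
}
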