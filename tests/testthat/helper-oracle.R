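# Independent brute-force Hough oracle: plain scalar loops over every
# (point, cell) pair, applying the documented compatibility rule (radial
# distance to the curve at the cell center vs. the half-cell-side
# first-order boundary-displacement bound).  Shares no code with vote().

oracle_vote_canal <- function(pts, grid, exclude_radius = 0.05) {
  s <- grid$side
  ca <- grid$lower[1] + (seq_len(grid$ncell[1]) - 0.5) * s
  cb <- grid$lower[2] + (seq_len(grid$ncell[2]) - 0.5) * s
  counts <- matrix(0L, length(ca), length(cb))
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]
    r <- sqrt(x^2 + y^2)
    if (r < exclude_radius) next
    c3 <- cos(3 * atan2(y, x))
    for (i in seq_along(ca)) for (j in seq_along(cb)) {
      den <- 1 + cb[j] * c3
      if (den <= 0) next
      rc <- ca[i] / den
      tol <- (s / 2) * (1 / den + ca[i] * abs(c3) / den^2)
      if (abs(r - rc) <= tol) counts[i, j] <- counts[i, j] + 1L
    }
  }
  counts
}

oracle_vote_ellipse <- function(pts, grid) {
  s <- grid$side
  ctr <- lapply(1:4, function(d)
    grid$lower[d] + (seq_len(grid$ncell[d]) - 0.5) * s)
  counts <- array(0L, grid$ncell)
  # loop semi-axis cells and points; sweep the (c, d) center plane in one go
  cd <- expand.grid(c = ctr[[3]], d = ctr[[4]])
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]
    dx <- x - cd$c; dy <- y - cd$d
    rho <- sqrt(dx^2 + dy^2)
    ok0 <- rho >= 1e-12   # point at the candidate center: never on the ellipse
    cs2 <- ifelse(ok0, dx^2 / rho^2, 0); sn2 <- ifelse(ok0, dy^2 / rho^2, 0)
    for (i1 in seq_along(ctr[[1]])) for (i2 in seq_along(ctr[[2]])) {
      a <- ctr[[1]][i1]; b <- ctr[[2]][i2]
      K <- b^2 * cs2 + a^2 * sn2
      K[!ok0] <- 1
      re <- a * b / sqrt(K)
      K32 <- K^-1.5
      wa <- b^3 * cs2 * K32
      wb <- a^3 * sn2 * K32
      rp <- abs(a * b * (a^2 - b^2)) * sqrt(cs2 * sn2) * K32
      wc <- sqrt(cs2) + ifelse(ok0, rp * sqrt(sn2) / rho, 0)
      wd <- sqrt(sn2) + ifelse(ok0, rp * sqrt(cs2) / rho, 0)
      hit <- ok0 & abs(rho - re) <= (s / 2) * (wa + wb + wc + wd)
      counts[i1, i2, , ] <- counts[i1, i2, , ] +
        matrix(as.integer(hit), length(ctr[[3]]), length(ctr[[4]]))
    }
  }
  counts
}
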