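#' Pipeline configuration
#'
#' Collects every tunable of the per-slice detection chain.  Defaults
#' follow the method's fixed choices (0.02 parameter-cell side) and
#' otherwise use documented, configurable values.
#'
#' @param frame_scale_mm working-frame scale: physical length mapped to
#'   one working unit (default 55 mm, placing a typical canal radius at
#'   0.2--0.6 working units).
#' @param cell_side accumulator cell side in working units (0.02).
#' @param canal_lower,canal_upper bounds of the (a, b) canal grid.
#' @param cord_lower,cord_upper bounds of the (a, b, c, d) cord grid.
#' @param canny_sigma Gaussian scale (px) for edge detection.
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param bone_window HU clamp applied before canal edge detection.
#' @param soft_window HU clamp applied before cord edge detection (the
#'   cord/CSF step is tens of HU and would not survive thresholds scaled
#'   to a bone-windowed gradient range).
#' @param interior_margin canal-interior filter: cord voting keeps edge
#'   points with radius below `interior_margin` times the canal boundary
#'   radius at their angle, so rasterized canal-boundary pixels do not
#'   pollute the ellipse vote.
#' @param min_points,min_votes detection acceptance minima.
#' @param exclude_radius origin exclusion radius for canal voting.
#' @param bone_hu HU threshold defining bone for the canal-center
#'   initialization.
#' @param center_jump_tol maximum per-slice canal-center re-estimate
#'   displacement (working units) accepted before falling back to the
#'   propagated center.
#' @return A `seg_config` list.
#' @export
seg_config <- function(frame_scale_mm = 55,
                       cell_side = 0.02,
                       canal_lower = c(0.10, -0.5),
                       canal_upper = c(0.70, 0.5),
                       cord_lower = c(0.02, 0.02, -0.3, -0.3),
                       cord_upper = c(0.40, 0.40, 0.3, 0.3),
                       canny_sigma = 1.0,
                       canny_low = 0.1,
                       canny_high = 0.3,
                       bone_window = c(-100, 1500),
                       soft_window = c(-100, 100),
                       interior_margin = 0.85,
                       min_points = 10L,
                       min_votes = 5L,
                       exclude_radius = 0.05,
                       bone_hu = 200,
                       center_jump_tol = 0.2) {
  cfg <- as.list(environment())
  stopifnot(cfg$frame_scale_mm > 0, cfg$cell_side > 0,
            cfg$interior_margin > 0, cfg$interior_margin <= 1)
  structure(cfg, class = "seg_config")
}

#' Anatomical segment definition from user-marked planes
#'
#' The operator marks three axial planes: the occipital skull border,
#' the plane adjacent to the caudal face of C7, and the plane adjacent
#' to the caudal face of D12.  The cervical segment is the half-open
#' slice interval `[occiput, c7)` and the dorsal segment the closed
#' interval `[c7, d12]`; slices caudal to D12 (lumbar/sacral canal) are
#' considered free of cord and excluded.  Slice indices are 1-based,
#' slice 1 most cranial.
#'
#' @param volume an [image_volume()] (or its slice count).
#' @param occiput,c7,d12 axial slice indices, strictly ordered
#'   `occiput < c7 <= d12`.
#' @return A `segment_definition` with `cervical` and `dorsal` slice
#'   index vectors.
#' @export
partition_segments <- function(volume, occiput, c7, d12) {
  nslice <- if (inherits(volume, "image_volume")) dim(volume$data)[3]
            else as.integer(volume)
  idx <- c(occiput, c7, d12)
  if (any(idx != round(idx)) || any(idx < 1) || any(idx > nslice))
    stop("plane indices must be slice indices within the volume", call. = FALSE)
  if (!(occiput < c7 && c7 <= d12))
    stop("plane indices must satisfy occiput < c7 <= d12", call. = FALSE)
  structure(list(occiput = as.integer(occiput), c7 = as.integer(c7),
                 d12 = as.integer(d12),
                 cervical = seq.int(occiput, c7 - 1L),
                 dorsal = seq.int(c7, d12)),
            class = "segment_definition")
}

#' @export
print.segment_definition <- function(x, ...) {
  cat(sprintf("<segments>  cervical: slices %d-%d (%d), dorsal: %d-%d (%d)\n",
              x$occiput, x$c7 - 1L, length(x$cervical),
              x$c7, x$d12, length(x$dorsal)))
  invisible(x)
}

#' Estimate the canal center from bone anatomy
#'
#' Initialization for the working frame on the first slice: the largest
#' connected component of bone-range pixels (the vertebra) is
#' hole-filled and the centroid of its largest internal cavity (the
#' canal lumen) is returned.  Returns `NULL` when no bone or no cavity
#' is present.
#'
#' @param slice numeric HU matrix.
#' @param bone_hu HU threshold defining bone.
#' @return Numeric length-2 pixel coordinate, or `NULL`.
#' @export
estimate_canal_center <- function(slice, bone_hu = 200) {
  bone <- slice > bone_hu
  if (!any(bone)) return(NULL)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bone * 1))))
  tab <- tabulate(lab[lab > 0])
  big <- (lab == which.max(tab))
  filled <- as.matrix(EBImage::imageData(
    EBImage::fillHull(EBImage::Image(big * 1)))) > 0
  cavity <- filled & !big
  if (!any(cavity)) return(NULL)
  clab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(cavity * 1))))
  ctab <- tabulate(clab[clab > 0])
  cav <- which(clab == which.max(ctab), arr.ind = TRUE)
  c(mean(cav[, 1]), mean(cav[, 2]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Segment one axial CT slice
#'
#' Full per-slice chain: bone-window preprocessing, Canny edge
#' detection, working frame centered on the canal-center estimate,
#' Hough detection of the canal (three-convexity family), filtering of a
#' soft-tissue-window edge set to the canal interior, Hough detection of
#' the cord (ellipse family), and rasterization of both fitted curves to
#' binary masks (cord mask intersected with the canal mask so nesting
#' holds by construction).
#'
#' @param ct_slice numeric HU matrix `[x, y]`.
#' @param spacing_mm in-plane pixel spacing (mm).
#' @param prior_center propagated canal-center pixel coordinate, or
#'   `NULL` to estimate from bone anatomy.
#' @param config a [seg_config()].
#' @return List with `canal`, `cord` (fitted parameter objects),
#'   `canal_votes`, `cord_votes`, `canal_mask`, `cord_mask`, `center`
#'   (working-frame origin used, pixel coordinates), `status` (`"ok"`).
#'   Signals a `no_curve_found` condition on failure.
#' @export
segment_slice <- function(ct_slice, spacing_mm = 1, prior_center = NULL,
                          config = seg_config()) {
  stopifnot(is.matrix(ct_slice))
  center <- estimate_canal_center(ct_slice, config$bone_hu)
  if (!is.null(prior_center)) {
    scale_px <- config$frame_scale_mm / spacing_mm
    if (is.null(center) ||
        sqrt(sum((center - prior_center)^2)) / scale_px > config$center_jump_tol)
      center <- prior_center
  }
  if (is.null(center))
    stop_no_curve("no canal-center estimate (no bone cavity found)")

  scale_px <- config$frame_scale_mm / spacing_mm
  frame <- working_frame(center, scale_px)

  # canal: bone-windowed edges
  bw <- clamp(ct_slice, config$bone_window[1], config$bone_window[2])
  edges <- detect_edges(bw, config$canny_sigma, config$canny_low,
                        config$canny_high)
  if (edges$n < config$min_points)
    stop_no_curve("too few bone-window edge points")
  fpts <- edge_point_set(pixel_to_frame(frame, edges$points))
  canal_grid <- parameter_grid(config$canal_lower, config$canal_upper,
                               config$cell_side)
  canal <- detect_canal(fpts, canal_grid, config$min_points,
                        config$min_votes, config$exclude_radius)

  # cord: soft-window edges restricted to the canal interior
  sw <- clamp(ct_slice, config$soft_window[1], config$soft_window[2])
  sedges <- detect_edges(sw, config$canny_sigma, config$canny_low,
                         config$canny_high)
  spts <- pixel_to_frame(frame, sedges$points)
  r <- sqrt(spts[, 1]^2 + spts[, 2]^2)
  th <- atan2(spts[, 2], spts[, 1])
  keep <- r < config$interior_margin *
    three_convexity_radius(th, canal$params)
  inner <- edge_point_set(spts[keep, , drop = FALSE])
  cord_grid <- parameter_grid(config$cord_lower, config$cord_upper,
                              config$cell_side)
  cord <- detect_cord(inner, cord_grid, config$min_points, config$min_votes)

  # rasterize fitted curves to masks on the pixel grid
  nx <- nrow(ct_slice); ny <- ncol(ct_slice)
  px <- cbind(rep(seq_len(nx), times = ny), rep(seq_len(ny), each = nx))
  fpx <- pixel_to_frame(frame, px)
  canal_mask <- matrix(point_inside(fpx, canal$params), nx, ny)
  cord_mask <- matrix(point_inside(fpx, cord$params), nx, ny) & canal_mask

  list(canal = canal$params, cord = cord$params,
       canal_votes = canal$votes, cord_votes = cord$votes,
       canal_mask = canal_mask, cord_mask = cord_mask,
       center = center, status = "ok")
}

empty_fit_row <- function(slice, segment, status) {
  tibble::tibble(slice = slice, segment = segment,
                 canal_a = NA_real_, canal_b = NA_real_,
                 cord_a = NA_real_, cord_b = NA_real_,
                 cord_c = NA_real_, cord_d = NA_real_,
                 canal_votes = NA_integer_, cord_votes = NA_integer_,
                 status = status)
}

#' Segment the cord-bearing portion of a CT volume
#'
#' Iterates [segment_slice()] cranial to caudal over the cervical and
#' dorsal slice ranges, propagating each slice's canal-center as the
#' next slice's prior.  A failed slice is logged and contributes empty
#' masks; a segment with more than half of its slices failed aborts the
#' run.
#'
#' @param ct a CT [image_volume()].
#' @param segdef a [partition_segments()] result.
#' @param config a [seg_config()].
#' @return A `segmentation_result`: `fits` (per-slice tibble), lists of
#'   `canal_masks`/`cord_masks` keyed by slice index, `volumes` tibble
#'   (canal and cord mL per segment), `segdef`, `spacing`, `config`.
#' @export
segment_volume_run <- function(ct, segdef, config = seg_config()) {
  stopifnot(inherits(ct, "image_volume"), ct$modality == "CT",
            inherits(segdef, "segment_definition"))
  slices <- c(segdef$cervical, segdef$dorsal)
  segment <- rep(c("cervical", "dorsal"),
                 c(length(segdef$cervical), length(segdef$dorsal)))
  shp <- dim(ct$data)[1:2]
  empty <- matrix(FALSE, shp[1], shp[2])

  fits <- vector("list", length(slices))
  canal_masks <- cord_masks <- vector("list", length(slices))
  prior <- NULL
  for (k in seq_along(slices)) {
    s <- slices[k]
    res <- tryCatch(
      segment_slice(ct$data[, , s], spacing_mm = ct$spacing[1],
                    prior_center = prior, config = config),
      no_curve_found = function(e) e)
    if (inherits(res, "condition")) {
      fits[[k]] <- empty_fit_row(s, segment[k], conditionMessage(res))
      canal_masks[[k]] <- empty
      cord_masks[[k]] <- empty
    } else {
      fits[[k]] <- tibble::tibble(
        slice = s, segment = segment[k],
        canal_a = res$canal$a, canal_b = res$canal$b,
        cord_a = res$cord$a, cord_b = res$cord$b,
        cord_c = res$cord$c, cord_d = res$cord$d,
        canal_votes = as.integer(res$canal_votes),
        cord_votes = as.integer(res$cord_votes),
        status = "ok")
      canal_masks[[k]] <- res$canal_mask
      cord_masks[[k]] <- res$cord_mask
      prior <- res$center
    }
  }
  fits <- do.call(rbind, fits)
  names(canal_masks) <- names(cord_masks) <- as.character(slices)

  for (seg in c("cervical", "dorsal")) {
    rows <- fits$segment == seg
    if (any(rows) && mean(fits$status[rows] != "ok") > 0.5)
      stop(sprintf("segmentation failed: >50%% of %s slices unusable", seg),
           call. = FALSE)
  }

  volumes <- do.call(rbind, lapply(c("cervical", "dorsal"), function(seg) {
    ks <- which(fits$segment == seg)
    tibble::tibble(
      segment = seg,
      n_slices = length(ks),
      canal_volume_ml = compute_volume(canal_masks[ks], ct$spacing),
      cord_volume_ml = compute_volume(cord_masks[ks], ct$spacing))
  }))

  structure(list(fits = fits, canal_masks = canal_masks,
                 cord_masks = cord_masks, volumes = volumes,
                 segdef = segdef, spacing = ct$spacing, config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  ok <- sum(x$fits$status == "ok")
  cat(sprintf("<segmentation result>  %d/%d slices fitted\n",
              ok, nrow(x$fits)))
  print(x$volumes)
  invisible(x)
}

#' Masks of a segmentation result as a 3D array aligned to the input
#'
#' @param result a `segmentation_result`.
#' @param what `"cord"` or `"canal"`.
#' @param nslice total slice count of the source volume.
#' @return 3D logical array; slices outside the segmented range are all
#'   `FALSE`.
#' @export
mask_array <- function(result, what = c("cord", "canal"), nslice) {
  what <- match.arg(what)
  masks <- if (what == "cord") result$cord_masks else result$canal_masks
  shp <- dim(masks[[1]])
  out <- array(FALSE, c(shp, nslice))
  for (s in names(masks)) out[, , as.integer(s)] <- masks[[s]]
  out
}
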