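#' Ground-truth description of a digital spine phantom
#'
#' Encodes everything the generator needs: canal/cord geometry in
#' working units (constant or per-slice), anatomical plane indices,
#' tissue HU values, uptake values expressed as true SUVs, the scanner
#' point-spread FWHM and the PET noise scale.  The cord ellipse must lie
#' strictly inside the canal curve (checked at sampled boundary points).
#'
#' Geometry notes: the outer vertebral boundary is deliberately
#' irregular (harmonic perturbation of the ring thickness) so that it is
#' not itself a member of the three-convexity family -- mirroring real
#' vertebrae, whose outer contour is far less regular than the canal.
#' The canal center drifts sinusoidally across slices by `drift_px`.
#'
#' @param canal_a,canal_b canal curve parameters (working units).
#' @param cord_a,cord_b,cord_c,cord_d cord ellipse semi-axes and center
#'   offset from the canal center (working units).
#' @param nslice total slice count.
#' @param occiput,c7,d12 anatomical plane indices (1-based slices).
#' @param frame_scale_mm working-frame scale (mm per working unit).
#' @param hu named numeric: `air`, `soft`, `bone`, `fluid` (canal
#'   content), `cord_contrast` (cord HU above fluid), `liver`.
#' @param liver_suv true liver SUV (normalization reference).
#' @param cervical_nsuv,dorsal_nsuv true cord NSUVs per segment.
#' @param fluid_nsuv true NSUV of canal content outside the cord.
#' @param soft_suv,bone_suv true SUVs of soft tissue and bone.
#' @param fwhm_mm PET point-spread FWHM (default 4.0 mm).
#' @param noise_sd additive Gaussian PET noise, SUV units,
#'   post-smoothing.
#' @param drift_px amplitude of the cranio-caudal canal-center drift.
#' @param injected_activity_mbq,weight_kg subject values converting true
#'   SUV to activity concentration.
#' @param seed RNG seed for the noise draw.
#' @return A `phantom_truth`.
#' @export
phantom_truth <- function(canal_a = 0.35, canal_b = 0.15,
                          cord_a = 0.10, cord_b = 0.07,
                          cord_c = 0.02, cord_d = -0.03,
                          nslice = 60L, occiput = 3L, c7 = 23L, d12 = 50L,
                          frame_scale_mm = 55,
                          hu = c(air = -1000, soft = 40, bone = 1200,
                                 fluid = 15, cord_contrast = 30, liver = 60),
                          liver_suv = 2.0,
                          cervical_nsuv = 0.99, dorsal_nsuv = 0.72,
                          fluid_nsuv = 0.6,
                          soft_suv = 0.5, bone_suv = 0.3,
                          fwhm_mm = 4.0, noise_sd = 0.05,
                          drift_px = 0.5,
                          injected_activity_mbq = 370, weight_kg = 74,
                          seed = 1L) {
  n_seg <- d12 - occiput + 1L
  expand <- function(v) if (length(v) == 1L) rep(v, n_seg) else
    { stopifnot(length(v) == n_seg); as.numeric(v) }
  tr <- list(canal_a = expand(canal_a), canal_b = expand(canal_b),
             cord_a = expand(cord_a), cord_b = expand(cord_b),
             cord_c = expand(cord_c), cord_d = expand(cord_d),
             nslice = as.integer(nslice), occiput = as.integer(occiput),
             c7 = as.integer(c7), d12 = as.integer(d12),
             frame_scale_mm = frame_scale_mm, hu = hu,
             liver_suv = liver_suv,
             cervical_nsuv = cervical_nsuv, dorsal_nsuv = dorsal_nsuv,
             fluid_nsuv = fluid_nsuv, soft_suv = soft_suv,
             bone_suv = bone_suv, fwhm_mm = fwhm_mm, noise_sd = noise_sd,
             drift_px = drift_px,
             injected_activity_mbq = injected_activity_mbq,
             weight_kg = weight_kg, seed = seed)
  stopifnot(occiput >= 1, occiput < c7, c7 <= d12, d12 <= nslice)
  # nesting check: cord boundary strictly inside the canal on every slice
  for (k in seq_len(n_seg)) {
    ell <- ellipse_params(tr$cord_a[k], tr$cord_b[k], tr$cord_c[k], tr$cord_d[k])
    can <- three_convexity_params(tr$canal_a[k], tr$canal_b[k])
    if (!all(point_inside(sample_curve(ell, 180L), can)))
      stop("cord ellipse is not strictly inside the canal curve on slice ",
           tr$occiput + k - 1L, call. = FALSE)
  }
  structure(tr, class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom truth>  %d slices (cervical %d-%d, dorsal %d-%d), canal a=%.3g b=%.3g\n",
    x$nslice, x$occiput, x$c7 - 1L, x$c7, x$d12,
    x$canal_a[1], x$canal_b[1]))
  invisible(x)
}

# per-slice canal center (pixel coords) with sinusoidal drift
phantom_centers <- function(truth, shape) {
  s <- seq_len(truth$nslice)
  cx <- (shape[1] + 1) / 2 + truth$drift_px * sin(2 * pi * s / truth$nslice)
  cy <- (shape[2] + 1) / 2 + truth$drift_px * cos(2 * pi * s / truth$nslice)
  cbind(cx, cy)
}

# separable Gaussian blur along the slice axis
blur_z <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  nz <- dim(arr)[3]
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- -half:half
  K <- matrix(0, nz, nz)
  for (z in seq_len(nz)) {
    zz <- z + offs
    ok <- zz >= 1 & zz <= nz
    w <- exp(-offs[ok]^2 / (2 * sigma_vox^2))
    K[zz[ok], z] <- w / sum(w)           # renormalized at the borders
  }
  d <- dim(arr)
  out <- matrix(arr, ncol = nz) %*% K
  array(out, dim = d)
}

#' Generate a coregistered CT/PET phantom pair
#'
#' CT is a piecewise-constant HU map: a high-attenuation vertebral ring
#' around the canal boundary, canal content at fluid HU with the cord at
#' a small configurable positive contrast, soft tissue elsewhere, and a
#' liver block in the caudal slices.  PET is the piecewise-constant
#' uptake map (true SUVs converted to kBq/mL via the subject's dose and
#' weight) convolved with a Gaussian of the stated FWHM, plus seeded
#' additive Gaussian noise.  Both volumes share one grid (perfect
#' coregistration).
#'
#' @param truth a [phantom_truth()].
#' @param shape volume dimensions, at least `c(32, 32, 10)`.
#' @param spacing voxel spacing in mm.
#' @return List with `ct`, `pet` (both [image_volume()]), `subject`
#'   ([subject_info()]), `truth_record` (per-slice parameter tibble plus
#'   analytic areas/volumes and the liver ROI center), and `truth`.
#' @export
generate_phantom <- function(truth = phantom_truth(),
                             shape = c(64, 64, 60),
                             spacing = c(1, 1, 2)) {
  stopifnot(inherits(truth, "phantom_truth"),
            all(shape >= c(32, 32, 10)), shape[3] == truth$nslice)
  hu <- truth$hu
  scale_px <- truth$frame_scale_mm / spacing[1]
  suv_to_kbq <- truth$injected_activity_mbq * 1000 / (truth$weight_kg * 1000)
  centers <- phantom_centers(truth, shape)

  ct <- array(hu[["soft"]], dim = shape)
  pet_suv <- array(truth$soft_suv, dim = shape)
  fluid_suv <- truth$fluid_nsuv * truth$liver_suv

  px <- cbind(rep(seq_len(shape[1]), times = shape[2]),
              rep(seq_len(shape[2]), each = shape[1]))
  # the cord and canal continue beyond the marked planes (brainstem above
  # the skull base, conus below D12), so the structure extends a few
  # slices past the segmented range to avoid an unphysical axial
  # truncation of the uptake at the segment ends
  zext <- 3L
  seg_slices <- seq.int(max(1L, truth$occiput - zext),
                        min(shape[3], truth$d12 + zext))
  rows <- vector("list", length(seg_slices))
  for (i in seq_along(seg_slices)) {
    s <- seg_slices[i]
    j <- min(max(s, truth$occiput), truth$d12) - truth$occiput + 1L
    can <- three_convexity_params(truth$canal_a[j], truth$canal_b[j])
    ell <- ellipse_params(truth$cord_a[j], truth$cord_b[j],
                          truth$cord_c[j], truth$cord_d[j])
    frame <- working_frame(centers[s, ], scale_px)
    fp <- pixel_to_frame(frame, px)
    r <- sqrt(fp[, 1]^2 + fp[, 2]^2)
    th <- atan2(fp[, 2], fp[, 1])
    r_canal <- three_convexity_radius(th, can)
    # irregular outer boundary: base thickness 4 px + harmonics, in px units
    thick_px <- 4 + 1.5 * sin(7 * th + 0.3 * s) + 1.0 * sin(2 * th + 1)
    ring <- r >= r_canal & r < r_canal + thick_px / scale_px
    lumen <- r < r_canal
    cordm <- point_inside(fp, ell) & lumen

    sl_ct <- rep(hu[["soft"]], nrow(px))
    sl_ct[ring] <- hu[["bone"]]
    sl_ct[lumen] <- hu[["fluid"]]
    sl_ct[cordm] <- hu[["fluid"]] + hu[["cord_contrast"]]
    ct[, , s] <- matrix(sl_ct, shape[1], shape[2])

    seg <- if (s < truth$c7) "cervical" else "dorsal"
    cord_suv <- if (seg == "cervical") truth$cervical_nsuv * truth$liver_suv
                else truth$dorsal_nsuv * truth$liver_suv
    sl_pet <- rep(truth$soft_suv, nrow(px))
    sl_pet[ring] <- truth$bone_suv
    sl_pet[lumen] <- fluid_suv
    sl_pet[cordm] <- cord_suv
    pet_suv[, , s] <- matrix(sl_pet, shape[1], shape[2])

    if (s < truth$occiput || s > truth$d12) next
    area_scale <- truth$frame_scale_mm^2
    rows[[i]] <- tibble::tibble(
      slice = s, segment = seg,
      canal_a = can$a, canal_b = can$b,
      cord_a = ell$a, cord_b = ell$b, cord_c = ell$c, cord_d = ell$d,
      center_x = centers[s, 1], center_y = centers[s, 2],
      canal_area_mm2 = curve_area(can) * area_scale,
      cord_area_mm2 = curve_area(ell) * area_scale)
  }
  truth_tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  # liver block in caudal slices (below D12, outside the segmented range);
  # omitted when the volume has no room below D12
  liver_center <- c(NA_real_, NA_real_, NA_real_)
  if (truth$d12 + zext + 2L <= shape[3] - 1L) {
    liver_slices <- seq.int(truth$d12 + zext + 2L, shape[3] - 1L)
    lx <- seq.int(ceiling(shape[1] * 0.2), floor(shape[1] * 0.8))
    ly <- seq.int(ceiling(shape[2] * 0.2), floor(shape[2] * 0.8))
    ct[lx, ly, liver_slices] <- hu[["liver"]]
    pet_suv[lx, ly, liver_slices] <- truth$liver_suv
    liver_center <- c(mean(lx), mean(ly), mean(liver_slices))
  }

  # PSF: separable 3D Gaussian of the stated FWHM
  if (truth$fwhm_mm > 0) {
    sigma_mm <- truth$fwhm_mm / (2 * sqrt(2 * log(2)))
    sxy <- sigma_mm / spacing[1]
    for (s in seq_len(shape[3]))
      pet_suv[, , s] <- EBImage::gblur(pet_suv[, , s], sigma = sxy,
                                      boundary = "replicate")
    pet_suv <- blur_z(pet_suv, sigma_mm / spacing[3])
  }
  if (truth$noise_sd > 0) {
    if (!is.null(truth$seed)) set.seed(truth$seed)
    pet_suv <- pet_suv + stats::rnorm(length(pet_suv), sd = truth$noise_sd)
  }

  dz <- spacing[3]
  vols <- stats::aggregate(cbind(canal_area_mm2, cord_area_mm2) ~ segment,
                           truth_tab, sum)
  truth_record <- list(
    fits = truth_tab,
    volumes = tibble::tibble(
      segment = vols$segment,
      canal_volume_ml = vols$canal_area_mm2 * dz / 1000,
      cord_volume_ml = vols$cord_area_mm2 * dz / 1000),
    liver_center_vox = liver_center,
    liver_suv = truth$liver_suv,
    cervical_nsuv = truth$cervical_nsuv,
    dorsal_nsuv = truth$dorsal_nsuv,
    planes = c(occiput = truth$occiput, c7 = truth$c7, d12 = truth$d12))

  subject <- subject_info(truth$injected_activity_mbq, truth$weight_kg)
  list(ct = image_volume(ct, spacing, "CT"),
       pet = image_volume(pet_suv * suv_to_kbq, spacing, "PET"),
       subject = subject, truth_record = truth_record, truth = truth)
}

# draw from Normal(mean, sd) truncated below at `lo`
rnorm_trunc <- function(n, mean, sd, lo = 0.05) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- stats::rnorm(length(need), mean, sd)
    need <- which(out < lo)
  }
  out
}

#' Simulate a case/control phantom cohort
#'
#' Draws whole-cord NSUVs for cases from Normal(0.82, 0.28) and for
#' controls from Normal(0.70, 0.14) (each truncated at 0.05), splits
#' each into cervical and dorsal segment NSUVs preserving the reported
#' cervical:dorsal ratio of each group (0.99:0.72 cases, 0.85:0.62
#' controls) with volume weights from the reported mean segment cord
#' volumes (13.99 and 32.60 mL), and returns one [phantom_truth()] per
#' subject plus a metadata table.  Volumes are not generated here; call
#' [generate_phantom()] on any returned truth to materialize a scan.
#'
#' @param n_cases,n_controls group sizes, `>= 1`.
#' @param seed RNG seed.
#' @param case_mean,case_sd,control_mean,control_sd group NSUV
#'   distributions.
#' @return List with `truths` (list of `phantom_truth`) and `subjects`
#'   (tibble: id, group, sc_nsuv, cervical_nsuv, dorsal_nsuv, sex,
#'   height_cm, weight_kg, injected_activity_mbq, seed).
#' @export
default_cohort <- function(n_cases, n_controls, seed = 1L,
                           case_mean = 0.82, case_sd = 0.28,
                           control_mean = 0.70, control_sd = 0.14) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  set.seed(seed)
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  sc <- c(rnorm_trunc(n_cases, case_mean, case_sd),
          rnorm_trunc(n_controls, control_mean, control_sd))
  ratio <- ifelse(group == "case", 0.99 / 0.72, 0.85 / 0.62)
  vc <- 13.99; vd <- 32.60
  dorsal <- sc * (vc + vd) / (ratio * vc + vd)
  cervical <- ratio * dorsal
  sex <- sample(c("male", "female"), n, replace = TRUE)
  height <- round(stats::rnorm(n, ifelse(sex == "male", 175, 162), 7), 1)
  weight <- round(stats::rnorm(n, ifelse(sex == "male", 78, 65), 10), 1)
  weight <- pmax(weight, 40)
  dose <- round(stats::runif(n, 4.8, 5.2) * weight, 1)
  subjects <- tibble::tibble(
    id = sprintf("%s%02d", ifelse(group == "case", "P", "C"),
                 c(seq_len(n_cases), seq_len(n_controls))),
    group = group, sc_nsuv = sc,
    cervical_nsuv = cervical, dorsal_nsuv = dorsal,
    sex = sex, height_cm = height, weight_kg = weight,
    injected_activity_mbq = dose,
    seed = seed + seq_len(n))
  truths <- lapply(seq_len(n), function(i)
    phantom_truth(cervical_nsuv = cervical[i], dorsal_nsuv = dorsal[i],
                  injected_activity_mbq = dose[i], weight_kg = weight[i],
                  seed = seed + i))
  list(truths = truths, subjects = subjects)
}
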