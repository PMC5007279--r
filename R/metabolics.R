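#' Subject information for SUV computation
#'
#' @param injected_activity_mbq injected FDG activity (MBq), `> 0`.
#' @param weight_kg body weight (kg), `> 0`.
#' @param height_cm height (cm), optional (needed for ideal body weight).
#' @param sex `"male"` or `"female"`, optional.
#' @param decay_corrected logical: `TRUE` (default) when voxel values are
#'   already decay-corrected to injection time by the scanner.
#' @param uptake_time_min minutes from injection to acquisition, used
#'   only when `decay_corrected = FALSE` to correct with the 18F
#'   half-life (109.77 min).
#' @return A `subject_info`.
#' @export
subject_info <- function(injected_activity_mbq, weight_kg,
                         height_cm = NA_real_, sex = NA_character_,
                         decay_corrected = TRUE, uptake_time_min = 0) {
  if (!is.finite(injected_activity_mbq) || injected_activity_mbq <= 0)
    stop("injected activity must be > 0", call. = FALSE)
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop("body weight must be > 0", call. = FALSE)
  structure(list(injected_activity_mbq = injected_activity_mbq,
                 weight_kg = weight_kg, height_cm = height_cm, sex = sex,
                 decay_corrected = decay_corrected,
                 uptake_time_min = uptake_time_min),
            class = "subject_info")
}

F18_HALF_LIFE_MIN <- 109.77

#' Standardized uptake value
#'
#' `SUV = concentration / (injected activity / body weight)` with units
#' reconciled (activity in kBq, weight in g, tissue density 1 g/mL), so
#' a uniform distribution of the dose over the body gives SUV 1.
#'
#' @param concentration activity concentration(s) in kBq/mL, `>= 0`.
#' @param subject a [subject_info()].
#' @return Dimensionless SUV, same length as `concentration`.
#' @export
compute_suv <- function(concentration, subject) {
  stopifnot(inherits(subject, "subject_info"))
  if (any(concentration < 0, na.rm = TRUE))
    stop("activity concentration must be >= 0", call. = FALSE)
  conc <- concentration
  if (!isTRUE(subject$decay_corrected))
    conc <- conc * 2^(subject$uptake_time_min / F18_HALF_LIFE_MIN)
  activity_kbq <- subject$injected_activity_mbq * 1000
  weight_g <- subject$weight_kg * 1000
  conc / (activity_kbq / weight_g)
}

#' Mean SUV of a PET volume under a mask stack
#'
#' The binary masks are multiplied against the coregistered PET slices
#' and the voxel-wise SUV is averaged over all mask-true voxels.
#'
#' @param pet a PET [image_volume()] (kBq/mL).
#' @param masks named list of 2D logical matrices keyed by slice index
#'   (as produced by [segment_volume_run()]), or a 3D logical array on
#'   the PET grid.
#' @param subject a [subject_info()].
#' @return Mean SUV (scalar).
#' @export
mean_suv_in_mask <- function(pet, masks, subject) {
  stopifnot(inherits(pet, "image_volume"), pet$modality == "PET")
  vals <- numeric(0)
  if (is.array(masks) && length(dim(masks)) == 3L) {
    if (!identical(dim(masks), dim(pet$data)))
      stop("mask array and PET volume are on different grids", call. = FALSE)
    vals <- pet$data[masks]
  } else {
    stopifnot(is.list(masks))
    for (s in names(masks)) {
      m <- masks[[s]]
      k <- as.integer(s)
      if (!identical(dim(m), dim(pet$data)[1:2]))
        stop("mask and PET slice are on different grids", call. = FALSE)
      vals <- c(vals, pet$data[, , k][m])
    }
  }
  if (length(vals) == 0L)
    stop("mask union is empty: no voxels to average", call. = FALSE)
  mean(compute_suv(vals, subject))
}

#' Liver reference SUV from a spherical ROI
#'
#' Mean SUV inside a sphere (default 3 cm diameter) centered at a
#' user-given voxel coordinate; used as the normalization reference.
#'
#' @param pet a PET [image_volume()].
#' @param center_vox numeric length-3 voxel coordinate of the ROI center.
#' @param subject a [subject_info()].
#' @param diameter_mm ROI diameter in mm.
#' @return Mean liver SUV.
#' @export
liver_suv_sphere <- function(pet, center_vox, subject, diameter_mm = 30) {
  stopifnot(inherits(pet, "image_volume"), length(center_vox) == 3L)
  d <- dim(pet$data)
  r <- diameter_mm / 2
  xs <- (seq_len(d[1]) - center_vox[1]) * pet$spacing[1]
  ys <- (seq_len(d[2]) - center_vox[2]) * pet$spacing[2]
  zs <- (seq_len(d[3]) - center_vox[3]) * pet$spacing[3]
  inside <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`) <= r^2
  if (!any(inside))
    stop("liver ROI contains no voxels", call. = FALSE)
  mean(compute_suv(pet$data[inside], subject))
}

#' Normalize a mean SUV to the liver reference
#'
#' @param mean_suv mean SUV of a region.
#' @param liver_suv mean liver SUV, `> 0`.
#' @return NSUV = `mean_suv / liver_suv`.
#' @export
normalize_to_liver <- function(mean_suv, liver_suv) {
  if (!is.finite(liver_suv) || liver_suv <= 0)
    stop("liver SUV must be > 0", call. = FALSE)
  mean_suv / liver_suv
}

#' Volume-weighted whole-cord NSUV
#'
#' Combines the cervical and dorsal cord NSUVs into the whole-cord value
#' \deqn{SC\_NSUV = \frac{C\_NSUV \cdot V_c + D\_NSUV \cdot V_d}{V_c + V_d},}
#' a convex combination that always lies between the two segment NSUVs.
#'
#' @param c_nsuv,d_nsuv cervical and dorsal cord NSUVs.
#' @param cervical_vol,dorsal_vol segment cord volumes (mL), `>= 0`, not
#'   both zero.
#' @return The whole-cord NSUV.
#' @export
whole_cord_nsuv <- function(c_nsuv, d_nsuv, cervical_vol, dorsal_vol) {
  if (cervical_vol < 0 || dorsal_vol < 0)
    stop("volumes must be >= 0", call. = FALSE)
  if (cervical_vol + dorsal_vol == 0)
    stop("both segment volumes are zero", call. = FALSE)
  (c_nsuv * cervical_vol + d_nsuv * dorsal_vol) / (cervical_vol + dorsal_vol)
}

#' Ideal body weight (Robinson formula)
#'
#' `male: 52 + 1.9 kg` and `female: 49 + 1.7 kg` per inch of height over
#' 60 inches; undefined below 60 in (152.4 cm).
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm height in cm, `>= 152.4`.
#' @return Ideal body weight in kg.
#' @export
ideal_body_weight <- function(sex = c("male", "female"), height_cm) {
  sex <- match.arg(sex)
  if (!is.finite(height_cm) || height_cm < 152.4)
    stop("height below 60 in (152.4 cm): ideal-body-weight formula undefined",
         call. = FALSE)
  over <- height_cm / 2.54 - 60
  if (sex == "male") 52 + 1.9 * over else 49 + 1.7 * over
}

#' Per-segment uptake report
#'
#' Extracts the PET activity under the canal and cord masks of a
#' segmentation result, normalizes to the liver reference, and computes
#' the volume-weighted whole-cord NSUV.
#'
#' @param seg a `segmentation_result` from [segment_volume_run()].
#' @param pet the coregistered PET [image_volume()].
#' @param subject a [subject_info()].
#' @param liver_suv precomputed liver reference SUV (e.g. from
#'   [liver_suv_sphere()] or a user-supplied liver mask mean).
#' @param subject_id optional identifier carried into the report.
#' @return An `uptake_report`: list with `table` (tibble: segment, canal
#'   and cord NSUV and volume), `liver_suv`, `sc_nsuv`, `subject_id`.
#' @export
uptake_report <- function(seg, pet, subject, liver_suv,
                          subject_id = NA_character_) {
  stopifnot(inherits(seg, "segmentation_result"))
  segs <- c("cervical", "dorsal")
  rows <- lapply(segs, function(sg) {
    ks <- which(seg$fits$segment == sg)
    canal_suv <- mean_suv_in_mask(pet, seg$canal_masks[ks], subject)
    cord_suv <- mean_suv_in_mask(pet, seg$cord_masks[ks], subject)
    v <- seg$volumes[seg$volumes$segment == sg, ]
    tibble::tibble(segment = sg,
                   canal_nsuv = normalize_to_liver(canal_suv, liver_suv),
                   cord_nsuv = normalize_to_liver(cord_suv, liver_suv),
                   canal_volume_ml = v$canal_volume_ml,
                   cord_volume_ml = v$cord_volume_ml)
  })
  tab <- do.call(rbind, rows)
  sc <- whole_cord_nsuv(tab$cord_nsuv[1], tab$cord_nsuv[2],
                        tab$cord_volume_ml[1], tab$cord_volume_ml[2])
  structure(list(table = tab, liver_suv = liver_suv, sc_nsuv = sc,
                 subject_id = subject_id),
            class = "uptake_report")
}

#' @export
print.uptake_report <- function(x, ...) {
  cat(sprintf("<uptake report>  liver SUV %.3f, whole-cord NSUV %.3f\n",
              x$liver_suv, x$sc_nsuv))
  print(x$table)
  invisible(x)
}

#' Write an uptake report as a delimited table
#'
#' One row per segment plus a `whole_cord` row, tab-separated with a
#' header: subject id, segment, canal NSUV, cord NSUV, volumes, liver
#' SUV, whole-cord NSUV.
#'
#' @param report an [uptake_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uptake_report <- function(report, path) {
  tab <- report$table
  out <- data.frame(subject_id = report$subject_id,
                    segment = c(tab$segment, "whole_cord"),
                    canal_nsuv = c(tab$canal_nsuv, NA),
                    cord_nsuv = c(tab$cord_nsuv, report$sc_nsuv),
                    canal_volume_ml = c(tab$canal_volume_ml,
                                        sum(tab$canal_volume_ml)),
                    cord_volume_ml = c(tab$cord_volume_ml,
                                       sum(tab$cord_volume_ml)),
                    liver_suv = report$liver_suv)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
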