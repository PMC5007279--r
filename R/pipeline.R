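#' Run configuration for the end-to-end pipeline
#'
#' All pipeline inputs in one validated object.  The only anatomical
#' input the operator supplies is the three plane indices; everything
#' else is automatic.
#'
#' @param ct_path,pet_path NIfTI volume paths.
#' @param occiput,c7,d12 axial plane indices (1-based).
#' @param liver_center_vox numeric length-3 voxel coordinate for the
#'   spherical liver reference ROI.
#' @param liver_roi_mm liver ROI diameter in mm.
#' @param injected_activity_mbq,weight_kg subject values for SUV.
#' @param height_cm,sex optional, for the ideal-body-weight covariate.
#' @param out_dir output directory (created if missing).
#' @param subject_id identifier carried into reports.
#' @param seg a [seg_config()] (or a list of overrides for it).
#' @return A `run_config`.
#' @export
run_config <- function(ct_path, pet_path, occiput, c7, d12,
                       liver_center_vox, liver_roi_mm = 30,
                       injected_activity_mbq, weight_kg,
                       height_cm = NA_real_, sex = NA_character_,
                       out_dir = ".", subject_id = "subject",
                       seg = seg_config()) {
  for (p in c(ct_path, pet_path))
    if (!file.exists(p))
      stop(sprintf("input path '%s' does not exist", p), call. = FALSE)
  if (!inherits(seg, "seg_config"))
    seg <- do.call(seg_config, as.list(seg))
  structure(list(ct_path = ct_path, pet_path = pet_path,
                 occiput = occiput, c7 = c7, d12 = d12,
                 liver_center_vox = liver_center_vox,
                 liver_roi_mm = liver_roi_mm,
                 injected_activity_mbq = injected_activity_mbq,
                 weight_kg = weight_kg, height_cm = height_cm, sex = sex,
                 out_dir = out_dir, subject_id = subject_id, seg = seg),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `seg:` block holds
#' [seg_config()] overrides.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(run_config, vals)
}

#' Execute the full segmentation + quantification pipeline
#'
#' Reads the coregistered CT and PET volumes, segments the cervical and
#' dorsal cord, extracts the PET uptake under the masks, normalizes to
#' the liver reference and writes all outputs to the configured
#' directory: `canal_mask.nii.gz` and `cord_mask.nii.gz` aligned to the
#' input grid, `slice_fits.tsv` (per-slice parameters and status),
#' `uptake_report.tsv`, and `run_log.txt`.  The chain contains no
#' randomness: reruns are byte-identical.
#'
#' @param config a [run_config()].
#' @return List with `seg` (the `segmentation_result`), `report` (the
#'   [uptake_report()]) and `files` (paths written), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("run_pipeline %s\n", config$subject_id), file = logf)

  ct <- read_volume(config$ct_path, "CT")
  pet <- read_volume(config$pet_path, "PET")
  if (!identical(dim(ct$data), dim(pet$data)))
    stop("CT and PET volumes are not on the same grid", call. = FALSE)
  segdef <- partition_segments(ct, config$occiput, config$c7, config$d12)
  seg <- segment_volume_run(ct, segdef, config$seg)
  for (i in seq_len(nrow(seg$fits)))
    logline("slice %d [%s]: %s", seg$fits$slice[i], seg$fits$segment[i],
            seg$fits$status[i])

  subject <- subject_info(config$injected_activity_mbq, config$weight_kg,
                          config$height_cm, config$sex)
  liver <- liver_suv_sphere(pet, config$liver_center_vox, subject,
                            config$liver_roi_mm)
  report <- uptake_report(seg, pet, subject, liver, config$subject_id)
  logline("liver SUV %.4f, whole-cord NSUV %.4f", liver, report$sc_nsuv)

  nslice <- dim(ct$data)[3]
  files <- c(
    canal_mask = file.path(config$out_dir, "canal_mask.nii.gz"),
    cord_mask = file.path(config$out_dir, "cord_mask.nii.gz"),
    slice_fits = file.path(config$out_dir, "slice_fits.tsv"),
    uptake_report = file.path(config$out_dir, "uptake_report.tsv"),
    log = logf)
  write_volume(mask_array(seg, "canal", nslice), files[["canal_mask"]],
               spacing = ct$spacing)
  write_volume(mask_array(seg, "cord", nslice), files[["cord_mask"]],
               spacing = ct$spacing)
  utils::write.table(seg$fits, files[["slice_fits"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_uptake_report(report, files[["uptake_report"]])
  invisible(list(seg = seg, report = report, files = files))
}

#' Write a ready-made demo phantom dataset
#'
#' Emits a coregistered CT/PET NIfTI pair for the default phantom plus a
#' YAML run configuration and the ground-truth record, so the full
#' pipeline can be exercised end to end without patient data.
#'
#' @param dir output directory.
#' @param truth a [phantom_truth()].
#' @param shape,spacing passed to [generate_phantom()].
#' @return The [run_config()] for the emitted dataset, invisibly.
#' @export
write_demo_phantom <- function(dir, truth = phantom_truth(),
                               shape = c(64, 64, 60), spacing = c(1, 1, 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(truth, shape, spacing)
  ct_path <- file.path(dir, "phantom_ct.nii.gz")
  pet_path <- file.path(dir, "phantom_pet.nii.gz")
  write_volume(ph$ct, ct_path)
  write_volume(ph$pet, pet_path)
  utils::write.table(ph$truth_record$fits, file.path(dir, "truth_fits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfgl <- list(ct_path = ct_path, pet_path = pet_path,
               occiput = truth$occiput, c7 = truth$c7, d12 = truth$d12,
               liver_center_vox = as.numeric(ph$truth_record$liver_center_vox),
               liver_roi_mm = 12,
               injected_activity_mbq = truth$injected_activity_mbq,
               weight_kg = truth$weight_kg,
               out_dir = file.path(dir, "out"), subject_id = "phantom")
  yaml::write_yaml(cfgl, file.path(dir, "run_config.yaml"))
  invisible(do.call(run_config, cfgl))
}
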