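#' 3D image volume with voxel spacing and modality
#'
#' Thin container for a coregistered CT or PET volume: a 3D numeric
#' array indexed `[x, y, slice]` with axial slices ordered cranial to
#' caudal (slice 1 most cranial), per-axis voxel spacing in mm, and a
#' modality tag (`"CT"` for Hounsfield units, `"PET"` for activity
#' concentration in kBq/mL).
#'
#' @param data 3D numeric array `[x, y, z]`.
#' @param spacing numeric length-3 voxel spacing in mm, all `> 0`.
#' @param modality `"CT"` or `"PET"`.
#' @return An `image_volume`.
#' @export
image_volume <- function(data, spacing, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(spacing), length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be > 0 on all axes",
                              call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing),
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image volume>  %s, %s voxels, spacing %s mm\n",
              x$modality, paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Read a volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` volume with its voxel spacing.  Slice order
#' is normalized to cranial-to-caudal using the NIfTI orientation (an
#' inferior-to-superior z axis is flipped).  DICOM series directories
#' are not supported by this build and raise an informative error.
#'
#' @param path path to a NIfTI file.
#' @param modality `"CT"` or `"PET"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  if (dir.exists(path))
    stop(sprintf("'%s' is a directory: DICOM series input is not supported; convert to NIfTI", path),
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("input volume '%s' does not exist", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  # normalize slice order: NIfTI +z points superior, so a stored
  # orientation with positive z step is feet-first; flip so that slice 1
  # is the most cranial.  Files without orientation info (code 0) are
  # taken as already head-first.
  xf <- RNifti::xform(img)
  code <- attr(xf, "code")
  if (is.matrix(xf) && !is.null(code) && code > 0 && xf[3, 3] > 0)
    arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
  image_volume(arr, spacing, modality)
}

#' Write a volume (or mask stack) to NIfTI
#'
#' Writes the array with its spacing; masks written this way align with
#' the input grid.  The array is stored head-first (slice 1 most
#' cranial) with a superior-pointing z axis flip applied symmetrically
#' to [read_volume()].
#'
#' @param vol an [image_volume()] or a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data; spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) stop("spacing required for a bare array", call. = FALSE)
  }
  img <- RNifti::asNifti(arr * 1)   # *1 coerces logical masks to numeric
  # head-first storage: z step negative (slice 1 most superior)
  img <- RNifti::`qform<-`(img, structure(diag(c(spacing[1:2], -spacing[3], 1)),
                                          code = 2L))
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volume of a binary mask stack
#'
#' @param masks list of 2D logical matrices (one per slice), all the same
#'   shape, or a 3D logical array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Volume in mL (voxel count x voxel volume in mm^3 / 1000).
#' @export
compute_volume <- function(masks, spacing) {
  stopifnot(is.numeric(spacing), length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  if (is.array(masks) && length(dim(masks)) == 3L)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  stopifnot(is.list(masks))
  if (length(masks)) {
    shp <- dim(masks[[1]])
    for (m in masks)
      if (!identical(dim(m), shp))
        stop("mask shapes differ across slices", call. = FALSE)
  }
  nvox <- sum(vapply(masks, function(m) sum(m != 0), numeric(1)))
  nvox * prod(spacing) / 1000
}
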