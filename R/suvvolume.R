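#' Construct a SuvVolume
#'
#' @param values 3D numeric array of SUVs.
#' @param spacing voxel spacing in mm, length 3 (or a scalar, recycled).
#' @param origin world coordinate (mm) of voxel (0, 0, 0); default zeros.
#' @return A [SuvVolume-class] object.
#' @examples
#' vol <- suvVolume(array(1, c(8, 8, 8)), spacing = 2)
#' suvSpacing(vol)
#' @export
suvVolume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("SuvVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn suvVolume the raw 3D SUV array.
#' @param x a `SuvVolume`.
#' @export
suvValues <- function(x) x@values

#' @describeIn suvVolume voxel spacing in mm (length 3).
#' @export
suvSpacing <- function(x) x@spacing

#' @describeIn suvVolume world origin in mm (length 3).
#' @export
suvOrigin <- function(x) x@origin

#' @describeIn suvVolume voxel volume in cm^3.
#' @export
voxelVolumeCm3 <- function(x) prod(suvSpacing(x)) / 1000

setMethod("show", "SuvVolume", function(object) {
  d <- dim(object@values)
  cat("SuvVolume:", paste(d, collapse = " x "), "voxels @",
      paste(format(object@spacing, digits = 4), collapse = " x "), "mm\n")
  cat("  SUV range: [", format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

#' Read / write SUV volumes and masks as NIfTI-1
#'
#' `writeSuvVolume()` stores the grid with its voxel spacing (pixdim) and
#' origin (sform translation); `readSuvVolume()` restores them. Only 3D
#' images are accepted: the pipeline operates on single static PET frames.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param vol a [SuvVolume-class].
#' @return `readSuvVolume()` returns a [SuvVolume-class]; `writeSuvVolume()`
#'   returns `path` invisibly.
#' @export
readSuvVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI image, got ", length(d), "D", call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header carries no usable voxel spacing", call. = FALSE)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  suvVolume(array(as.numeric(img), dim = d), spacing = abs(pd[1:3]),
            origin = as.numeric(origin))
}

#' @rdname readSuvVolume
#' @export
writeSuvVolume <- function(vol, path) {
  stopifnot(is(vol, "SuvVolume"))
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  aff <- diag(c(vol@spacing, 1))
  aff[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a LesionSet as a NIfTI-1 label map
#'
#' Lesion voxels carry their label (1..n); the liver reference VOI is coded
#' 255; background is 0. Per-lesion metrics go to a CSV alongside if
#' `metricsPath` is given.
#'
#' @param lesions a [LesionSet-class].
#' @param path output NIfTI path.
#' @param spacingOrigin optional [SuvVolume-class] supplying the origin.
#' @param metricsPath optional CSV path for `lesionStats(lesions)`.
#' @return `path`, invisibly.
#' @export
writeLesionLabels <- function(lesions, path, spacingOrigin = NULL,
                              metricsPath = NULL) {
  lab <- lesions@labelMap
  lab[lesions@liverMask] <- 255
  origin <- if (is.null(spacingOrigin)) c(0, 0, 0) else suvOrigin(spacingOrigin)
  writeSuvVolume(suvVolume(lab, lesions@spacing, origin), path)
  if (!is.null(metricsPath))
    write.csv(lesions@stats, metricsPath, row.names = FALSE)
  invisible(path)
}
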