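# Volume container and I/O: 16-bit Hounsfield CT volumes, NIfTI read/write,
# window/level display transform, isotropic resampling.
#
# Axis convention used throughout the package: arrays are indexed (z, y, x);
# an axial slice is a fixed z, a coronal slice a fixed y, a sagittal slice a
# fixed x. NIfTI stores (x, y, z), so I/O permutes axes.

#' @import methods
NULL

#' CTVolume: a CT volume in Hounsfield units
#'
#' Holds a 3D intensity grid indexed `(z, y, x)`, the voxel spacing in mm per
#' axis (same order), and a physical origin offset. CT intensities are
#' Hounsfield units and must be representable as signed 16-bit integers;
#' arithmetic is done in double precision, storage ([writeVolume()]) is
#' 16-bit.
#'
#' @slot voxels numeric 3D array `(z, y, x)` of HU values.
#' @slot spacing numeric length-3, mm per voxel along `(z, y, x)`; all > 0.
#' @slot origin numeric length-3, mm offset of voxel (1,1,1).
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
      return("spacing must be three strictly positive values")
    }
    if (length(object@origin) != 3L) return("origin must have length 3")
    rng <- range(v)
    if (rng[1] < -32768 || rng[2] > 32767) {
      return("intensities outside the signed 16-bit range")
    }
    TRUE
  }
)

#' Construct a CTVolume
#'
#' @param voxels numeric 3D array `(z, y, x)` of HU values.
#' @param spacing mm per voxel along `(z, y, x)`.
#' @param origin physical offset in mm (default zero).
#' @return a [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn CTVolume-class voxel array accessor.
#' @param x,object a `CTVolume`.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname CTVolume-class
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname CTVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname CTVolume-class
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @rdname CTVolume-class
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g mm, HU range [%d, %d]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], round(min(object@voxels)),
              round(max(object@voxels))))
})

#' Read a CT volume or mask from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` file and returns the data in the package's
#' canonical `(z, y, x)` orientation with spacing populated from the file
#' header. Only NIfTI input is supported; other formats raise an error.
#'
#' @param path path to a NIfTI file.
#' @return a [CTVolume-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unsupported volume format (expected .nii or .nii.gz): ", path)
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3L, 2L, 1L))
  storage.mode(arr) <- "double"
  CTVolume(arr, spacing = rev(pd[1:3]))
}

#' Write a CT volume to NIfTI as signed 16-bit
#'
#' Intensities are rounded to the nearest integer and stored as int16; the
#' `(z, y, x)` array is permuted back to NIfTI's `(x, y, z)` order with the
#' spacing in the header.
#'
#' @param vol a [CTVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  arr <- aperm(round(vol@voxels), c(3L, 2L, 1L))
  attr(arr, "pixdim") <- rev(vol@spacing)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a binary mask as NIfTI
#'
#' Masks are stored as unsigned 8-bit with the same axis convention as
#' volumes.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param path NIfTI file path.
#' @param spacing mm per voxel along `(z, y, x)`.
#' @return `writeMask` returns `path` invisibly; `readMask` returns a logical
#'   array with a `"spacing"` attribute.
#' @export
writeMask <- function(mask, path, spacing = c(1, 1, 1)) {
  arr <- aperm(array(as.integer(mask), dim = dim(mask)), c(3L, 2L, 1L))
  attr(arr, "pixdim") <- rev(spacing)
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3L, 2L, 1L)) > 0
  attr(arr, "spacing") <- rev(RNifti::pixdim(img)[1:3])
  arr
}

#' Apply the DICOM linear rescale
#'
#' Maps stored integer values to Hounsfield units, `hu = slope * stored +
#' intercept`.
#'
#' @param stored numeric array of stored values.
#' @param slope,intercept rescale parameters.
#' @return numeric array of HU values.
#' @examples
#' applyRescale(1024, 1, -1024)  # 0 HU
#' @export
applyRescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Window/level display transform
#'
#' Maps HU values to 8-bit display grey levels:
#' `clamp((hu - (level - width/2)) / width, 0, 1) * 255`, rounded to the
#' nearest integer (ties round to even, so `hu == level` maps to 128).
#' The map is monotone non-decreasing in HU. The default is a standard lung
#' window (width 1500 HU, level -600 HU).
#'
#' @param x a [CTVolume-class] or numeric array of HU values.
#' @param width window width in HU; must be > 0.
#' @param level window centre in HU.
#' @return integer array of display values in 0..255, same shape as the
#'   input.
#' @examples
#' applyWindow(c(-1350, -600, 150), width = 1500, level = -600)  # 0 128 255
#' @export
applyWindow <- function(x, width = 1500, level = -600) {
  if (width <= 0) stop("window width must be positive")
  hu <- if (is(x, "CTVolume")) x@voxels else x
  d <- pmin(pmax((hu - (level - width / 2)) / width, 0), 1)
  out <- round(d * 255)
  storage.mode(out) <- "integer"
  out
}

#' @noRd
windowNormalize <- function(hu, width = 1500, level = -600) {
  pmin(pmax((hu - (level - width / 2)) / width, 0), 1)
}

#' Resample a volume or mask to isotropic spacing
#'
#' Trilinear interpolation for intensities, nearest neighbour for masks.
#' Output grid sizes are `round(extent_mm / target)`, so the physical extent
#' is preserved to within one voxel.
#'
#' @param x a [CTVolume-class] or a logical mask array with a `spacing`
#'   argument.
#' @param target target isotropic spacing in mm (> 0).
#' @param spacing for plain mask arrays: current mm per axis `(z, y, x)`.
#' @return resampled object of the same kind.
#' @export
resampleIsotropic <- function(x, target = 1, spacing = NULL) {
  if (target <= 0) stop("target spacing must be positive")
  if (is(x, "CTVolume")) {
    d <- dim(x@voxels)
    od <- pmax(1L, as.integer(round(d * x@spacing / target)))
    if (all(od == d) && all(x@spacing == target)) return(x)
    arr <- .nf_resample3d(x@voxels, od[1], od[2], od[3], FALSE)
    arr <- pmin(pmax(arr, -32768), 32767)
    CTVolume(arr, spacing = rep(target, 3), origin = x@origin)
  } else {
    if (is.null(spacing)) spacing <- attr(x, "spacing")
    if (is.null(spacing)) stop("mask resampling needs `spacing`")
    d <- dim(x)
    od <- pmax(1L, as.integer(round(d * spacing / target)))
    arr <- .nf_resample3d(array(as.numeric(x), dim = d),
                          od[1], od[2], od[3], TRUE)
    out <- arr > 0.5
    attr(out, "spacing") <- rep(target, 3)
    out
  }
}

#' Export a windowed slice as PNG
#'
#' Convenience inspection output: applies [applyWindow()] to one slice and
#' writes an 8-bit greyscale PNG (requires the `png` package).
#'
#' @param vol a [CTVolume-class].
#' @param z axial slice index.
#' @param path output PNG path.
#' @param width,level window parameters passed to [applyWindow()].
#' @return `path`, invisibly.
#' @export
writeSlicePNG <- function(vol, z, path, width = 1500, level = -600) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required for PNG export")
  }
  sl <- applyWindow(vol@voxels[z, , ], width = width, level = level)
  png::writePNG(sl / 255, path)
  invisible(path)
}
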