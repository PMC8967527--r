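# Multiposition reslicing: a volume (z,y,x) is cut into three 2D stacks
# (axial = fixed z, coronal = fixed y, sagittal = fixed x), each slice is
# optionally size-normalized for the 2D networks, and per-position binary
# predictions are reassembled and fused voxel-wise.

#' PositionStack: one anatomical position's slice sequence
#'
#' @slot position `"axial"`, `"coronal"` or `"sagittal"`.
#' @slot slices list of 2D numeric matrices, one per plane coordinate.
#' @slot indexMap integer vector: slice i sits at plane coordinate
#'   `indexMap[i]` of the source volume (a bijection onto that axis).
#' @slot sourceDim integer dims `(z, y, x)` of the source volume.
#' @export
setClass("PositionStack",
  representation(position = "character", slices = "list",
                 indexMap = "integer", sourceDim = "integer"),
  validity = function(object) {
    if (!object@position %in% c("axial", "coronal", "sagittal")) {
      return("position must be axial, coronal or sagittal")
    }
    ax <- switch(object@position, axial = 1L, coronal = 2L, sagittal = 3L)
    n <- object@sourceDim[ax]
    if (length(object@slices) != n) {
      return("slice count must equal the source extent along the fixed axis")
    }
    if (!identical(sort(object@indexMap), seq_len(n))) {
      return("indexMap must be a bijection onto the fixed axis")
    }
    TRUE
  }
)

setMethod("show", "PositionStack", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("PositionStack (%s): %d slices of %d x %d\n", object@position,
              length(object@slices), d[1], d[2]))
})

#' @rdname PositionStack-class
#' @param x a `PositionStack`.
#' @export
setGeneric("position", function(x) standardGeneric("position"))

#' @rdname PositionStack-class
#' @export
setMethod("position", "PositionStack", function(x) x@position)

#' @rdname PositionStack-class
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname PositionStack-class
#' @export
setMethod("slices", "PositionStack", function(x) x@slices)

#' Reslice a volume into one anatomical position
#'
#' Slices are exact planar sections: voxel `(k, i, j)` of the volume appears
#' at axial slice `k` (as element `(i, j)`), coronal slice `i` (as `(k, j)`),
#' and sagittal slice `j` (as `(k, i)`). [stackPositions()] inverts the
#' operation exactly.
#'
#' @param x a [CTVolume-class], logical mask, or plain 3D array `(z, y, x)`.
#' @param pos `"axial"`, `"coronal"` or `"sagittal"`.
#' @return a [PositionStack-class].
#' @export
reslice <- function(x, pos = c("axial", "coronal", "sagittal")) {
  pos <- match.arg(pos)
  arr <- if (is(x, "CTVolume")) x@voxels else x
  stopifnot(length(dim(arr)) == 3L)
  d <- dim(arr)
  ax <- switch(pos, axial = 1L, coronal = 2L, sagittal = 3L)
  sl <- lapply(seq_len(d[ax]), function(i) {
    switch(pos,
      axial = arr[i, , , drop = TRUE],
      coronal = arr[, i, , drop = TRUE],
      sagittal = arr[, , i, drop = TRUE])
  })
  new("PositionStack", position = pos, slices = sl,
      indexMap = seq_len(d[ax]), sourceDim = as.integer(d))
}

#' Reassemble a position stack into a volume
#'
#' Exact inverse of [reslice()]: returns the original `(z, y, x)` array.
#'
#' @param stack a [PositionStack-class].
#' @return 3D array of the stack's source dimensions.
#' @export
stackPositions <- function(stack) {
  stopifnot(is(stack, "PositionStack"))
  d <- stack@sourceDim
  arr <- array(stack@slices[[1]][1] * 0, dim = d)
  for (i in seq_along(stack@slices)) {
    k <- stack@indexMap[i]
    switch(stack@position,
      axial = arr[k, , ] <- stack@slices[[i]],
      coronal = arr[, k, ] <- stack@slices[[i]],
      sagittal = arr[, , k] <- stack@slices[[i]])
  }
  arr
}

#' Normalize a slice to a target spatial size
#'
#' Bilinear resize (default 200 x 200, the size used by the nodule
#' networks). The original size is recorded in the `"originalSize"`
#' attribute so [denormalizeSlice()] can map predictions back.
#'
#' @param image 2D numeric matrix.
#' @param target integer length-2 target size.
#' @return resized matrix with attribute `"originalSize"`.
#' @export
normalizeSlice <- function(image, target = c(200L, 200L)) {
  stopifnot(is.matrix(image), all(target >= 1))
  out <- .nf_resize_bilinear(image, as.integer(target[1]),
                             as.integer(target[2]))
  attr(out, "originalSize") <- dim(image)
  out
}

#' @rdname normalizeSlice
#' @param prediction matrix produced on the normalized grid (e.g. a
#'   probability map).
#' @param originalSize size to map back to; defaults to the attribute
#'   recorded by [normalizeSlice()].
#' @export
denormalizeSlice <- function(prediction, originalSize =
                               attr(prediction, "originalSize")) {
  if (is.null(originalSize)) stop("originalSize not recorded on prediction")
  out <- .nf_resize_bilinear(prediction, as.integer(originalSize[1]),
                             as.integer(originalSize[2]))
  attr(out, "originalSize") <- NULL
  out
}

#' Fuse per-position 3D masks
#'
#' Combines the axial, coronal and sagittal predictions (each reassembled to
#' the full volume grid) voxel-wise. The default majority rule keeps a voxel
#' when at least two positions agree, which is what rejects elongated
#' vessel-like structures that look nodular in one position only.
#'
#' @param axial,coronal,sagittal logical 3D arrays of identical shape.
#' @param rule `"majority"` (>= 2 of 3), `"union"` or `"intersection"`.
#' @return logical 3D array.
#' @export
fusePositionMasks <- function(axial, coronal, sagittal,
                              rule = c("majority", "union", "intersection")) {
  rule <- match.arg(rule)
  if (!identical(dim(axial), dim(coronal)) ||
      !identical(dim(axial), dim(sagittal))) {
    stop("position masks must share one 3D shape")
  }
  votes <- (axial > 0) + (coronal > 0) + (sagittal > 0)
  switch(rule,
    majority = votes >= 2L,
    union = votes >= 1L,
    intersection = votes == 3L)
}
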