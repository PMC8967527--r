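# Nodule candidates: 26-connected components of the fused segmentation,
# scored by the circularity of their maximum-area slice in each of the three
# anatomical positions. Elongated vessel-like components look circular in at
# most one position and are rejected by requiring circularity in at least
# two positions; size is screened via the equivalent sphere diameter.

#' NoduleCandidate: one connected 3D component
#'
#' @slot id integer component label.
#' @slot voxelIndex integer matrix (n x 3) of `(z, y, x)` voxel coordinates.
#' @slot centroid numeric `(z, y, x)` voxel centroid.
#' @slot equivDiameterMm diameter of the equal-volume sphere, in mm.
#' @slot circularity named numeric: max-area-slice circularity in the
#'   `axial`, `coronal` and `sagittal` positions (each in `[0, 1]`).
#' @slot retained logical: passed the screening rule.
#' @slot features named numeric feature vector (filled by
#'   [extractFeatures()]).
#' @export
setClass("NoduleCandidate",
  representation(id = "integer", voxelIndex = "matrix", centroid = "numeric",
                 equivDiameterMm = "numeric", circularity = "numeric",
                 retained = "logical", features = "numeric"))

setMethod("show", "NoduleCandidate", function(object) {
  cat(sprintf(
    "NoduleCandidate %d: %d voxels, d_eq %.1f mm, circ a/c/s %.2f/%.2f/%.2f%s\n",
    object@id, nrow(object@voxelIndex), object@equivDiameterMm,
    object@circularity[1], object@circularity[2], object@circularity[3],
    if (object@retained) ", retained" else ", rejected"))
})

#' Circularity of a 2D binary region
#'
#' `4 * pi * Area / Perimeter^2`, where the perimeter is the polygonal arc
#' length of the Moore-traced outer contour (straight steps count 1,
#' diagonal steps sqrt(2)); a naive boundary-pixel count would bias discs
#' above 1. Values marginally above 1 from discretization are clamped to 1.
#'
#' @param region logical matrix, nonempty and connected (for a region with
#'   several blobs the largest is scored).
#' @return circularity score in `[0, 1]`; 1 for an ideal disc.
#' @examples
#' d <- outer((-25:25)^2, (-25:25)^2, "+") <= 20^2
#' circularity(d) > 0.85
#' @export
circularity <- function(region) {
  region <- region > 0
  area <- sum(region)
  if (area == 0) stop("cannot score an empty region")
  lab <- array(.nf_label3d(as.logical(region), 1L, nrow(region),
                           ncol(region)),
               dim = c(1L, dim(region)))
  tab <- tabulate(lab)
  main <- which.max(tab)
  m <- matrix(lab[1, , ] == main, nrow(region), ncol(region))
  area <- sum(m)
  per <- .nf_trace_perimeter(m)
  if (!is.finite(per) || per <= 0) return(1)
  min(4 * pi * area / per^2, 1)
}

#' @noRd
.maxAreaSlice <- function(vox, axis, dims) {
  cnt <- tabulate(vox[, axis], nbins = dims[axis])
  k <- which.max(cnt)
  keep <- vox[, axis] == k
  other <- setdiff(1:3, axis)
  m <- matrix(FALSE, dims[other[1]], dims[other[2]])
  m[vox[keep, other, drop = FALSE]] <- TRUE
  list(slice = m, at = k)
}

#' Screen 3D components into nodule candidates
#'
#' Labels `mask3d` into 26-connected components and scores each one. A
#' component is retained when its equivalent sphere diameter lies within
#' `diamRangeMm` and its max-area-slice circularity reaches `minCirc` in at
#' least two of the three positions. The lower diameter default (4 mm) is
#' deliberately below the 6 mm study focus so partial-volume-shrunk true
#' nodules are not discarded.
#'
#' @param mask3d logical array `(z, y, x)`.
#' @param spacing mm per axis `(z, y, x)`.
#' @param minCirc circularity threshold in `[0, 1]`.
#' @param diamRangeMm length-2 interval of admissible equivalent diameters.
#' @param returnAll if `TRUE`, also return rejected candidates (flagged via
#'   the `retained` slot).
#' @return list of [NoduleCandidate-class] (empty for an empty mask).
#' @export
screenCandidates <- function(mask3d, spacing = c(1, 1, 1), minCirc = 0.6,
                             diamRangeMm = c(4, 12), returnAll = FALSE) {
  d <- dim(mask3d)
  if (!any(mask3d)) return(list())
  lab <- array(.nf_label3d(as.logical(mask3d), d[1], d[2], d[3]), dim = d)
  ncomp <- max(lab)
  out <- list()
  for (k in seq_len(ncomp)) {
    vox <- which(lab == k, arr.ind = TRUE)
    nv <- nrow(vox)
    volMm3 <- nv * prod(spacing)
    dEq <- (6 * volMm3 / pi)^(1 / 3)
    circ <- vapply(1:3, function(ax)
      circularity(.maxAreaSlice(vox, ax, d)$slice), numeric(1))
    names(circ) <- c("axial", "coronal", "sagittal")
    keep <- dEq >= diamRangeMm[1] && dEq <= diamRangeMm[2] &&
      sum(circ >= minCirc) >= 2L
    cand <- new("NoduleCandidate", id = k, voxelIndex = vox,
                centroid = colMeans(vox), equivDiameterMm = dEq,
                circularity = circ, retained = keep,
                features = numeric(0))
    if (keep || returnAll) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Segment nodules from a volume with per-position networks
#'
#' Implements the 2.5D multiposition stage: the volume is masked to the
#' parenchyma, lung-window normalized, resliced into axial/coronal/sagittal
#' stacks, each slice is (optionally) size-normalized and passed through
#' that position's network, the probability maps are thresholded and
#' reassembled into three 3D masks, fused with [fusePositionMasks()], and
#' the fused mask is screened into candidates.
#'
#' @param volume a [CTVolume-class].
#' @param parenchyma logical parenchyma mask aligned with `volume`.
#' @param nets named list with trained networks for `axial`, `coronal` and
#'   `sagittal` (a missing position is an error).
#' @param threshold probability threshold applied before fusion.
#' @param fusionRule passed to [fusePositionMasks()].
#' @param sliceSize optional length-2 size to which slices are normalized
#'   before inference (`NULL` = native size).
#' @param minCirc,diamRangeMm screening parameters for
#'   [screenCandidates()].
#' @return list with `mask` (fused logical array), `positionMasks` (list of
#'   the three pre-fusion masks) and `candidates`.
#' @export
segmentNodules <- function(volume, parenchyma, nets, threshold = 0.5,
                           fusionRule = "majority", sliceSize = NULL,
                           minCirc = 0.6, diamRangeMm = c(4, 12)) {
  stopifnot(is(volume, "CTVolume"))
  if (!identical(dim(volume@voxels), dim(parenchyma))) {
    stop("parenchyma mask must be aligned with the volume")
  }
  for (pos in c("axial", "coronal", "sagittal")) {
    if (is.null(nets[[pos]])) stop("missing network for position: ", pos)
  }
  hu <- volume@voxels
  hu[!parenchyma] <- -1000
  norm <- windowNormalize(hu)
  posMask <- list()
  for (pos in c("axial", "coronal", "sagittal")) {
    stack <- reslice(norm, pos)
    pred <- lapply(stack@slices, function(sl) {
      if (!any(sl > 0)) return(sl * 0)
      if (!is.null(sliceSize)) {
        x <- normalizeSlice(sl, sliceSize)
        p <- netForward(nets[[pos]], x)
        attr(p, "originalSize") <- dim(sl)
        p <- denormalizeSlice(p)
      } else {
        p <- netForward(nets[[pos]], sl)
      }
      (p > threshold) * 1
    })
    bin <- new("PositionStack", position = pos, slices = pred,
               indexMap = stack@indexMap, sourceDim = stack@sourceDim)
    posMask[[pos]] <- stackPositions(bin) > 0
  }
  fused <- fusePositionMasks(posMask$axial, posMask$coronal,
                             posMask$sagittal, rule = fusionRule)
  fused <- fused & parenchyma
  cands <- screenCandidates(fused, spacing = volume@spacing,
                            minCirc = minCirc, diamRangeMm = diamRangeMm)
  list(mask = fused, positionMasks = posMask, candidates = cands)
}

#' Single-nodule phantom convenience generator
#'
#' One isolated (or wall-adherent) nodule auto-placed in a lung field of a
#' desk-scale phantom; the diameter is drawn uniformly from `diamRangeMm`
#' using the seed.
#'
#' @param seed integer seed.
#' @param shape phantom shape `(z, y, x)`.
#' @param diamRangeMm range the diameter is drawn from (6-8 mm focus).
#' @param spiculated render spiculation spikes.
#' @param attachment nodule attachment type.
#' @param noiseSigma noise SD in HU.
#' @return a [generatePhantom()] result.
#' @export
nodulePhantom <- function(seed, shape = c(48L, 64L, 64L),
                          diamRangeMm = c(6, 8), spiculated = FALSE,
                          attachment = "isolated", noiseSigma = 15) {
  dmm <- .withSeed(as.integer((as.numeric(seed) * 131 + 7) %% 2147483647),
                   stats::runif(1, diamRangeMm[1], diamRangeMm[2]))
  spec <- phantomSpec(shape = shape, noiseSigma = noiseSigma, seed = seed,
                      nodules = list(noduleSpec(diameterMm = dmm,
                                                spiculated = spiculated,
                                                attachment = attachment)))
  generatePhantom(spec)
}
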