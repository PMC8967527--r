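# Synthetic CT phantoms with exact ground truth: a soft-tissue body holding
# two darker lung fields (axis-aligned ellipsoids whose position and size are
# jittered by the seeded RNG, so anatomy varies across seeds), spherical
# nodules (smooth or spiculated), tubular vessel-like structures, and
# additive Gaussian noise. Every rendered structure is returned as a mask,
# so downstream stages can be tested without any external data.

#' NoduleSpec: one synthetic nodule
#'
#' @slot center voxel coordinates `(z, y, x)`; `NA` means auto-placement
#'   inside a lung field by the phantom's seeded RNG.
#' @slot diameterMm sphere diameter in mm (> 0).
#' @slot spiculated logical; add radial spikes to the boundary.
#' @slot spikeCount number of spikes (0 when not spiculated).
#' @slot spikeLengthMm spike length in mm.
#' @slot attachment one of `"isolated"`, `"wall"`, `"vessel"`.
#' @export
setClass("NoduleSpec",
  representation(center = "numeric", diameterMm = "numeric",
                 spiculated = "logical", spikeCount = "integer",
                 spikeLengthMm = "numeric", attachment = "character"),
  validity = function(object) {
    if (object@diameterMm <= 0) return("diameterMm must be > 0")
    if (object@spikeCount < 0 || object@spikeLengthMm < 0) {
      return("spike parameters must be >= 0")
    }
    if (!object@spiculated && object@spikeCount != 0L) {
      return("spikeCount must be 0 when spiculated is FALSE")
    }
    if (!object@attachment %in% c("isolated", "wall", "vessel")) {
      return("attachment must be isolated, wall or vessel")
    }
    TRUE
  }
)

#' @rdname NoduleSpec-class
#' @param center,diameterMm,spiculated,spikeCount,spikeLengthMm,attachment
#'   see slots.
#' @export
noduleSpec <- function(diameterMm = 8, center = c(NA_real_, NA, NA),
                       spiculated = FALSE,
                       spikeCount = if (spiculated) 8L else 0L,
                       spikeLengthMm = 3, attachment = "isolated") {
  new("NoduleSpec", center = as.numeric(center), diameterMm = diameterMm,
      spiculated = spiculated, spikeCount = as.integer(spikeCount),
      spikeLengthMm = spikeLengthMm, attachment = attachment)
}

#' VesselSpec: one vessel-like cylinder
#'
#' @slot axis one of `"z"`, `"y"`, `"x"`: the cylinder's long axis.
#' @slot from,to voxel coordinates `(z, y, x)` of the centre-line endpoints.
#' @slot radiusMm cylinder radius in mm (> 0).
#' @export
setClass("VesselSpec",
  representation(axis = "character", from = "numeric", to = "numeric",
                 radiusMm = "numeric"),
  validity = function(object) {
    if (!object@axis %in% c("z", "y", "x")) return("axis must be z, y or x")
    if (object@radiusMm <= 0) return("radiusMm must be > 0")
    TRUE
  }
)

#' @rdname VesselSpec-class
#' @param axis,from,to,radiusMm see slots.
#' @export
vesselSpec <- function(axis, from, to, radiusMm = 2) {
  new("VesselSpec", axis = axis, from = as.numeric(from),
      to = as.numeric(to), radiusMm = radiusMm)
}

#' PhantomSpec: full synthetic CT study description
#'
#' Intensity levels are Hounsfield units; the lung fields must be darker
#' than the body and all levels must fit in signed 16 bits.
#'
#' @slot shape voxels per axis `(z, y, x)`.
#' @slot spacing mm per axis `(z, y, x)`.
#' @slot bodyHu,lungHu,noduleHu,vesselHu intensity levels in HU.
#' @slot noiseSigma additive Gaussian noise SD in HU.
#' @slot nodules list of [NoduleSpec-class].
#' @slot vessels list of [VesselSpec-class].
#' @slot seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", bodyHu = "numeric",
                 lungHu = "numeric", noduleHu = "numeric",
                 vesselHu = "numeric", noiseSigma = "numeric",
                 nodules = "list", vessels = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape <= 0L)) {
      return("shape must be three positive integers")
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
      return("spacing must be three positive values")
    }
    if (object@lungHu >= object@bodyHu) {
      return("lung fields must be darker than the body (lungHu < bodyHu)")
    }
    hu <- c(object@bodyHu, object@lungHu, object@noduleHu, object@vesselHu)
    if (any(hu < -32768 | hu > 32767)) {
      return("HU levels outside the signed 16-bit range")
    }
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    TRUE
  }
)

#' @rdname PhantomSpec-class
#' @param shape,spacing,bodyHu,lungHu,noduleHu,vesselHu,noiseSigma,nodules,vessels,seed
#'   see slots. Defaults give a 96 x 128 x 128 voxel, 1 mm isotropic phantom
#'   with soft-tissue body (+40 HU), air-like lung fields (-800 HU),
#'   soft-tissue nodules (+20 HU) and 15 HU noise.
#' @export
phantomSpec <- function(shape = c(96L, 128L, 128L), spacing = c(1, 1, 1),
                        bodyHu = 40, lungHu = -800, noduleHu = 20,
                        vesselHu = 20, noiseSigma = 15, nodules = list(),
                        vessels = list(), seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      bodyHu = bodyHu, lungHu = lungHu, noduleHu = noduleHu,
      vesselHu = vesselHu, noiseSigma = noiseSigma, nodules = nodules,
      vessels = vessels, seed = as.integer(seed))
}

#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Coordinate index arrays for vectorized geometry.
#' @noRd
.gridIdx <- function(shape) {
  a <- array(0, dim = shape)
  list(z = slice.index(a, 1L), y = slice.index(a, 2L),
       x = slice.index(a, 3L))
}

#' @noRd
.ellipsoid <- function(gi, centre, semi) {
  ((gi$z - centre[1]) / semi[1])^2 + ((gi$y - centre[2]) / semi[2])^2 +
    ((gi$x - centre[3]) / semi[3])^2 <= 1
}

# Lung-field geometry for one phantom: two ellipsoids with ~5% seeded jitter.
#' @noRd
.lungGeometry <- function(shape) {
  j <- function(s) stats::runif(1, -0.05, 0.05) * s
  Z <- shape[1]; Y <- shape[2]; X <- shape[3]
  list(
    left = list(centre = c(Z / 2 + j(Z), Y / 2 + j(Y), 0.30 * X + j(X)),
                semi = c(0.36 * Z * (1 + j(1)), 0.30 * Y * (1 + j(1)),
                         0.15 * X * (1 + j(1)))),
    right = list(centre = c(Z / 2 + j(Z), Y / 2 + j(Y), 0.70 * X + j(X)),
                 semi = c(0.36 * Z * (1 + j(1)), 0.30 * Y * (1 + j(1)),
                          0.15 * X * (1 + j(1))))
  )
}

#' @noRd
.sphereMask <- function(shape, spacing, centre, radiusMm) {
  rv <- radiusMm / spacing          # radius in voxels per axis
  lo <- pmax(1L, floor(centre - rv - 1))
  hi <- pmin(shape, ceiling(centre + rv + 1))
  m <- array(FALSE, dim = shape)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz <- (zi - centre[1]) * spacing[1]
  dy <- (yi - centre[2]) * spacing[2]
  dx <- (xi - centre[3]) * spacing[3]
  sub <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`) <= radiusMm^2
  m[zi, yi, xi] <- sub
  m
}

#' Add spiculation spikes to a nodule mask
#'
#' Grows `spikeCount` thin conical protrusions of the stated length in
#' pseudorandom radial directions from the surface of a (roughly spherical)
#' mask. The output is always a superset of the input, and the max-area
#' slice becomes less circular, which is the ground-truth signature of the
#' spiculation sign.
#'
#' @param mask logical 3D array `(z, y, x)`, nonempty.
#' @param spikeCount number of spikes; 0 returns the input unchanged.
#' @param spikeLengthMm spike length in mm.
#' @param spacing mm per axis `(z, y, x)`.
#' @param seed integer seed for the spike directions.
#' @param baseRadiusVox cone base radius in voxels (1-2 gives thin spikes).
#' @return logical array: `mask` plus the spikes.
#' @export
spiculateBoundary <- function(mask, spikeCount, spikeLengthMm,
                              spacing = c(1, 1, 1), seed = 1L,
                              baseRadiusVox = 1.5) {
  if (!any(mask)) stop("cannot spiculate an empty mask")
  if (spikeCount == 0L) return(mask)
  shape <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  centre <- colMeans(idx)
  volMm3 <- nrow(idx) * prod(spacing)
  rMm <- (3 * volMm3 / (4 * pi))^(1 / 3)
  out <- mask
  .withSeed(seed, {
    for (s in seq_len(spikeCount)) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      steps <- seq(0, spikeLengthMm, by = min(spacing) / 2)
      for (t in steps) {
        posMm <- (rMm - 0.5 + t) * dir
        pos <- centre + posMm / spacing
        rad <- baseRadiusVox * (1 - t / spikeLengthMm) + 0.5
        lo <- pmax(1L, floor(pos - rad)); hi <- pmin(shape, ceiling(pos + rad))
        if (any(lo > hi)) next
        zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
        ball <- outer(outer((zi - pos[1])^2, (yi - pos[2])^2, `+`),
                      (xi - pos[3])^2, `+`) <= rad^2
        out[zi, yi, xi] <- out[zi, yi, xi] | ball
      }
    }
  })
  out
}

#' Generate a synthetic CT phantom with ground truth
#'
#' Renders the body and two lung fields, then every nodule and vessel, adds
#' Gaussian noise, and rounds to integer HU. All geometry and noise is drawn
#' from the spec's seed, so identical specs give bit-identical phantoms.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements `volume` (a [CTVolume-class]),
#'   `parenchyma` (logical lung-field mask), `noduleMask` (logical union of
#'   all nodule voxels), `noduleMasks` (per-nodule list), and `labels`
#'   (data frame: id, diameterMm, spiculated, attachment, centre
#'   coordinates).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(24, 32, 32), seed = 7,
#'                                   nodules = list(noduleSpec(6))))
#' sum(ph$noduleMask)      # ~ voxelized 6 mm sphere
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  shape <- spec@shape
  sp <- spec@spacing
  .withSeed(spec@seed, {
    gi <- .gridIdx(shape)
    geom <- .lungGeometry(shape)
    body <- .ellipsoid(gi, c(shape[1] / 2, shape[2] / 2, shape[3] / 2),
                       c(0.48 * shape[1], 0.42 * shape[2], 0.45 * shape[3]))
    lungs <- .ellipsoid(gi, geom$left$centre, geom$left$semi) |
      .ellipsoid(gi, geom$right$centre, geom$right$semi)
    lungs <- lungs & body
    vol <- array(-1000, dim = shape)
    vol[body] <- spec@bodyHu
    vol[lungs] <- spec@lungHu
    # vessels (clipped to the lung fields)
    for (vs in spec@vessels) {
      ax <- match(vs@axis, c("z", "y", "x"))
      perp <- setdiff(1:3, ax)
      lo <- pmin(vs@from[ax], vs@to[ax]); hi <- pmax(vs@from[ax], vs@to[ax])
      along <- gi[[c("z", "y", "x")[ax]]]
      d2 <- ((gi[[c("z", "y", "x")[perp[1]]]] - vs@from[perp[1]]) *
               sp[perp[1]])^2 +
            ((gi[[c("z", "y", "x")[perp[2]]]] - vs@from[perp[2]]) *
               sp[perp[2]])^2
      cyl <- d2 <= vs@radiusMm^2 & along >= lo & along <= hi & lungs
      vol[cyl] <- spec@vesselHu
    }
    # nodules
    noduleMasks <- list()
    labels <- NULL
    for (i in seq_along(spec@nodules)) {
      nd <- spec@nodules[[i]]
      centre <- nd@center
      if (anyNA(centre)) {
        lg <- if (i %% 2L == 1L) geom$left else geom$right
        if (nd@attachment == "wall") {
          # centre on the lateral lung-field boundary
          dirx <- if (i %% 2L == 1L) -1 else 1
          centre <- lg$centre + c(0, 0, dirx * lg$semi[3])
        } else {
          centre <- lg$centre + stats::runif(3, -0.3, 0.3) * lg$semi
        }
      }
      ci <- pmin(pmax(round(centre), 1L), shape)
      inLung <- lungs[ci[1], ci[2], ci[3]]
      if (nd@attachment == "wall") {
        near <- lungs[max(1, ci[1] - 2):min(shape[1], ci[1] + 2),
                      max(1, ci[2] - 2):min(shape[2], ci[2] + 2),
                      max(1, ci[3] - 2):min(shape[3], ci[3] + 2)]
        if (!any(near)) {
          stop(sprintf("nodule %d: centre not on a lung-field boundary", i))
        }
      } else if (!inLung) {
        stop(sprintf("nodule %d: centre (%d,%d,%d) outside the lung fields",
                     i, ci[1], ci[2], ci[3]))
      }
      m <- .sphereMask(shape, sp, centre, nd@diameterMm / 2)
      if (nd@spiculated && nd@spikeCount > 0L) {
        m <- spiculateBoundary(m, nd@spikeCount, nd@spikeLengthMm, sp,
                               seed = spec@seed + 1000L * i)
      }
      m <- m & body
      noduleMasks[[i]] <- m
      vol[m] <- spec@noduleHu
      labels <- rbind(labels, data.frame(
        id = i, diameterMm = nd@diameterMm, spiculated = nd@spiculated,
        attachment = nd@attachment, cz = centre[1], cy = centre[2],
        cx = centre[3]))
    }
    if (spec@noiseSigma > 0) {
      vol <- vol + stats::rnorm(length(vol), sd = spec@noiseSigma)
    }
    vol <- round(pmin(pmax(vol, -32768), 32767))
    noduleMask <- array(FALSE, dim = shape)
    for (m in noduleMasks) noduleMask <- noduleMask | m
    list(volume = CTVolume(vol, spacing = sp),
         parenchyma = lungs,
         noduleMask = noduleMask,
         noduleMasks = noduleMasks,
         labels = labels)
  })
}

#' Write a phantom to disk
#'
#' Writes the volume and both ground-truth masks as NIfTI plus a JSON
#' sidecar with the per-nodule labels.
#'
#' @param ph result of [generatePhantom()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(ph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- ph$volume@spacing
  writeVolume(ph$volume, file.path(dir, "volume.nii.gz"))
  writeMask(ph$parenchyma, file.path(dir, "parenchyma.nii.gz"), sp)
  writeMask(ph$noduleMask, file.path(dir, "nodules.nii.gz"), sp)
  jsonlite::write_json(ph$labels, file.path(dir, "labels.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Per-position training pairs for the nodule networks
#'
#' Builds `(slice, mask)` pairs for one anatomical position from a phantom:
#' the volume is masked to the (ground-truth) parenchyma and lung-window
#' normalized, every slice intersecting a nodule is included with its
#' nodule-mask slice, and `negatives` nodule-free lung slices are added so
#' the network also sees empty backgrounds.
#'
#' @param ph a [generatePhantom()] result.
#' @param pos `"axial"`, `"coronal"` or `"sagittal"`.
#' @param negatives number of nodule-free slices to include.
#' @param seed seed for picking the negative slices.
#' @return list of `list(x, y)` training pairs.
#' @export
noduleSliceSet <- function(ph, pos, negatives = 3L, seed = 1L) {
  hu <- ph$volume@voxels
  hu[!ph$parenchyma] <- -1000
  xs <- reslice(windowNormalize(hu), pos)
  ys <- reslice(ph$noduleMask * 1, pos)
  ps <- reslice(ph$parenchyma * 1, pos)
  hasN <- vapply(ys@slices, function(m) any(m > 0), logical(1))
  hasL <- vapply(ps@slices, function(m) any(m > 0), logical(1))
  pick <- which(hasN)
  negPool <- which(hasL & !hasN)
  neg <- .withSeed(seed, sample(negPool, min(negatives, length(negPool))))
  lapply(c(pick, neg), function(i) list(x = xs@slices[[i]],
                                        y = ys@slices[[i]]))
}

#' Training pairs of parenchyma slices from small phantoms
#'
#' Convenience generator for desk-scale experiments: renders a sequence of
#' small phantoms (anatomy jittered per seed) and returns axial slices
#' through the lung fields paired with their parenchyma masks. Intensities
#' are lung-window normalized to [0, 1].
#'
#' @param n number of slices.
#' @param size in-plane size in voxels (slices are `size x size`).
#' @param seed base RNG seed.
#' @param noiseSigma noise level passed to the phantom spec.
#' @return list of `list(x = <size x size intensity matrix>, y = <mask>)`.
#' @export
phantomSliceSet <- function(n, size = 64L, seed = 1L, noiseSigma = 15) {
  perPh <- 4L
  out <- vector("list", n)
  k <- 0L
  phi <- 0L
  while (k < n) {
    phi <- phi + 1L
    spec <- phantomSpec(shape = c(16L, size, size), noiseSigma = noiseSigma,
                        seed = seed + phi)
    ph <- generatePhantom(spec)
    zc <- round(dim(ph$parenchyma)[1] / 2)
    zs <- zc + seq(-perPh + 1L, perPh) # central slices hold both lungs
    zs <- zs[zs >= 1 & zs <= dim(ph$parenchyma)[1]]
    zs <- utils::head(zs, perPh)
    for (z in zs) {
      if (k >= n) break
      k <- k + 1L
      out[[k]] <- list(x = windowNormalize(ph$volume@voxels[z, , ]),
                       y = ph$parenchyma[z, , ] * 1)
    }
  }
  out
}
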