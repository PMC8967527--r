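# End-to-end orchestration: parenchyma segmentation -> multiposition nodule
# segmentation -> spiculation-sign recognition, with optional evaluation
# against ground truth and on-disk outputs.

#' @noRd
.resolveNet <- function(x, what) {
  if (inherits(x, "noduleflowNet")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing checkpoint for ", what, ": ", x)
    return(loadNet(x))
  }
  stop("no network supplied for ", what)
}

#' @noRd
.resolveMask <- function(x) {
  if (is.character(x)) readMask(x) else x
}

#' Segment the lung parenchyma of a whole volume
#'
#' Applies the attention-gated network to every axial slice (lung-window
#' normalized) and thresholds the probability maps into a 3D mask.
#'
#' @param volume a [CTVolume-class].
#' @param net a trained parenchyma network (or checkpoint path).
#' @param threshold probability threshold.
#' @return logical array aligned with the volume.
#' @export
segmentParenchyma <- function(volume, net, threshold = 0.5) {
  stopifnot(is(volume, "CTVolume"))
  net <- .resolveNet(net, "parenchyma")
  stack <- reslice(windowNormalize(volume@voxels), "axial")
  pred <- lapply(stack@slices, function(sl) (netForward(net, sl) > threshold) * 1)
  bin <- new("PositionStack", position = "axial", slices = pred,
             indexMap = stack@indexMap, sourceDim = stack@sourceDim)
  stackPositions(bin) > 0
}

#' Run the full nodule pipeline
#'
#' Executes the three stages in order on one volume: parenchyma
#' segmentation, multiposition nodule segmentation with circularity
#' screening, and (when a sign model is supplied) spiculation-sign
#' recognition on each retained candidate. When ground-truth masks are
#' supplied the report carries Md/Vd/Ud/CM for both segmentation stages.
#'
#' @param cfg configuration list, or path to a YAML file with the same
#'   keys: `volume` (path or [CTVolume-class]), `parenchymaNet`,
#'   `noduleNets` (named list `axial`/`coronal`/`sagittal`; networks or
#'   checkpoint paths), optional `signModel` (path to an RDS or a
#'   `SignModel`), `threshold` (default 0.5), `fusionRule`, `minCirc`,
#'   `diamRangeMm`, `sliceSize`, `seed`, `outDir`, and optional `truth`
#'   (list with `parenchyma` and/or `noduleMask`, paths or arrays).
#' @return a run report: list with `parenchymaMask`, `noduleMask`,
#'   `candidates`, `signs` (data frame, when a sign model is given),
#'   `scores` (when truth is given) and `log` (per-stage messages).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  volume <- if (is(cfg$volume, "CTVolume")) cfg$volume else readVolume(cfg$volume)
  threshold <- if (is.null(cfg$threshold)) 0.5 else cfg$threshold
  fusionRule <- if (is.null(cfg$fusionRule)) "majority" else cfg$fusionRule
  minCirc <- if (is.null(cfg$minCirc)) 0.6 else cfg$minCirc
  diamRangeMm <- if (is.null(cfg$diamRangeMm)) c(4, 12) else cfg$diamRangeMm
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  .withSeed(seed, {
    say("stage 1: parenchyma segmentation (threshold %.2f)", threshold)
    pnet <- .resolveNet(cfg$parenchymaNet, "parenchyma")
    parenchyma <- tryCatch(
      segmentParenchyma(volume, pnet, threshold),
      error = function(e) stop("parenchyma stage failed: ",
                               conditionMessage(e)))
    say("stage 1: %d parenchyma voxels", sum(parenchyma))
    say("stage 2: multiposition nodule segmentation (rule %s)", fusionRule)
    nets <- lapply(stats::setNames(nm = c("axial", "coronal", "sagittal")),
                   function(p) .resolveNet(cfg$noduleNets[[p]],
                                           paste("nodule", p)))
    seg <- tryCatch(
      segmentNodules(volume, parenchyma, nets, threshold = threshold,
                     fusionRule = fusionRule, sliceSize = cfg$sliceSize,
                     minCirc = minCirc, diamRangeMm = diamRangeMm),
      error = function(e) stop("nodule stage failed: ", conditionMessage(e)))
    say("stage 2: %d candidates retained", length(seg$candidates))
    signs <- NULL
    if (!is.null(cfg$signModel)) {
      say("stage 3: spiculation-sign recognition")
      sm <- cfg$signModel
      if (is.character(sm)) {
        if (!file.exists(sm)) stop("missing checkpoint for sign model: ", sm)
        sm <- readRDS(sm)
      }
      signs <- tryCatch({
        rows <- lapply(seg$candidates, function(cand) {
          fv <- extractFeatures(volume, cand)
          pr <- predict(sm, as.data.frame(t(fv)))
          data.frame(id = cand@id, probability = pr$probability,
                     spiculated = pr$spiculated)
        })
        do.call(rbind, rows)
      }, error = function(e) stop("sign stage failed: ",
                                  conditionMessage(e)))
    }
    scores <- NULL
    if (!is.null(cfg$truth)) {
      scores <- list()
      tp <- cfg$truth
      if (!is.null(tp$parenchyma)) {
        scores$parenchyma <- segScores(.resolveMask(tp$parenchyma),
                                       parenchyma)
      }
      if (!is.null(tp$noduleMask) && any(seg$mask)) {
        scores$nodule <- segScores(.resolveMask(tp$noduleMask), seg$mask)
      }
    }
    report <- list(parenchymaMask = parenchyma, noduleMask = seg$mask,
                   candidates = seg$candidates, signs = signs,
                   scores = scores, seed = seed, log = log)
    if (!is.null(cfg$outDir)) {
      dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
      sp <- volume@spacing
      writeMask(parenchyma, file.path(cfg$outDir, "parenchyma.nii.gz"), sp)
      writeMask(seg$mask, file.path(cfg$outDir, "nodules.nii.gz"), sp)
      cj <- lapply(seg$candidates, function(cand) list(
        id = cand@id, centroid = as.numeric(cand@centroid),
        equivDiameterMm = cand@equivDiameterMm,
        circularity = as.list(cand@circularity), retained = cand@retained))
      jsonlite::write_json(cj, file.path(cfg$outDir, "candidates.json"),
                           auto_unbox = TRUE, digits = NA)
      summ <- list(seed = seed, log = log,
                   scores = lapply(scores, as.list))
      if (!is.null(signs)) summ$signs <- signs
      jsonlite::write_json(summ, file.path(cfg$outDir, "report.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
    report
  })
}

#' Evaluate a directory of predictions against ground truth
#'
#' Matches mask files by name between the two directories and computes
#' per-case and aggregate Md/Vd/Ud/CM.
#'
#' @param predDir directory of predicted NIfTI masks.
#' @param truthDir directory of ground-truth NIfTI masks with matching file
#'   names.
#' @return list with `perCase` (data frame, one row per case) and
#'   `aggregate` (mean scores).
#' @export
evaluateRun <- function(predDir, truthDir) {
  pf <- list.files(predDir, pattern = "\\.nii(\\.gz)?$")
  tf <- list.files(truthDir, pattern = "\\.nii(\\.gz)?$")
  if (length(pf) == 0L) stop("no predictions found in ", predDir)
  common <- intersect(pf, tf)
  unmatched <- c(setdiff(pf, tf), setdiff(tf, pf))
  if (length(common) == 0L) {
    stop("no matching case names; unmatched: ",
         paste(unmatched, collapse = ", "))
  }
  rows <- lapply(common, function(f) {
    sc <- segScores(readMask(file.path(truthDir, f)),
                    readMask(file.path(predDir, f)))
    cbind(data.frame(case = f), as.data.frame(t(sc)))
  })
  perCase <- do.call(rbind, rows)
  agg <- colMeans(perCase[, c("Md", "Vd", "Ud", "CM")])
  list(perCase = perCase, aggregate = agg, unmatched = unmatched)
}
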