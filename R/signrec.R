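# Spiculation-sign recognition: radiomics + morphological features per
# candidate, univariate screening (t-test / chi-square), LASSO selection,
# two logistic submodels (radiomics: first-order + 3D shape; morphology: 2D
# shape) whose probabilities are averaged, evaluated by stratified k-fold
# cross-validation. Per-position sign decisions are fused with the OR rule.

#' Extract radiomics and morphological features for a candidate
#'
#' First-order intensity statistics over the candidate's voxels (mean,
#' variance, skewness, kurtosis, energy = mean squared HU, entropy of a
#' 25-HU-bin histogram), 2D shape of the max-area slice in each position
#' (circularity, elongation = sqrt of the principal-axis ratio,
#' perimeter-to-area in 1/mm, radial-length variance of the contour,
#' normalized by the mean radius), and 3D shape (sphericity, surface-to-
#' volume ratio, equivalent diameter, compactness = 36 pi V^2 / A^3). The
#' surface area is estimated from exposed voxel faces scaled by 2/3, which
#' removes the staircase overestimate exactly for spheres. All features are
#' deterministic and invariant to translating the candidate inside the
#' volume.
#'
#' @param volume a [CTVolume-class].
#' @param candidate a [NoduleCandidate-class] with at least 2 voxels (shape
#'   features are undefined for a single voxel, which is an error).
#' @return named numeric vector with no missing values.
#' @export
extractFeatures <- function(volume, candidate) {
  stopifnot(is(volume, "CTVolume"), is(candidate, "NoduleCandidate"))
  vox <- candidate@voxelIndex
  if (nrow(vox) < 2L) {
    stop("degenerate single-voxel candidate: shape features undefined")
  }
  sp <- volume@spacing
  d <- dim(volume@voxels)
  ints <- volume@voxels[vox]
  fo <- c(
    fo_mean = mean(ints),
    fo_var = stats::var(ints),
    fo_skew = if (stats::var(ints) > 0) e1071::skewness(ints) else 0,
    fo_kurt = if (stats::var(ints) > 0) e1071::kurtosis(ints) else 0,
    fo_energy = mean(ints^2),
    fo_entropy = {
      b <- table(floor(ints / 25))
      p <- b / sum(b)
      max(0, -sum(p * log2(p)))
    }
  )
  # 2D shape on the max-area slice per position
  s2 <- numeric(0)
  posNames <- c("axial", "coronal", "sagittal")
  for (ax in 1:3) {
    ms <- .maxAreaSlice(vox, ax, d)
    other <- setdiff(1:3, ax)
    spc <- sp[other]
    m <- ms$slice
    pix <- which(m, arr.ind = TRUE)
    pmm <- sweep(matrix(as.numeric(pix), ncol = 2), 2, spc, `*`)
    circ <- circularity(m)
    elong <- if (nrow(pmm) > 2) {
      ev <- eigen(stats::cov(pmm), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 1e-9)
      sqrt(ev[1] / ev[2])
    } else 1
    per <- .nf_trace_perimeter(m) * mean(spc)
    area <- sum(m) * prod(spc)
    bnd <- .boundaryPixels(m)
    radvar <- if (nrow(bnd) > 2) {
      bm <- sweep(matrix(as.numeric(bnd), ncol = 2), 2, spc, `*`)
      r <- sqrt(rowSums(sweep(bm, 2, colMeans(pmm), `-`)^2))
      stats::var(r / mean(r))
    } else 0
    v <- c(circ, elong, per / area, radvar)
    names(v) <- paste0(c("c2d_", "elong_", "pa_", "radvar_"), posNames[ax])
    s2 <- c(s2, v)
  }
  # 3D shape
  volMm3 <- nrow(vox) * prod(sp)
  A <- .surfaceAreaMm2(vox, d, sp)
  sph <- min((36 * pi * volMm3^2)^(1 / 3) / A, 1)
  s3 <- c(sphericity = sph,
          surf_to_vol = A / volMm3,
          equiv_diam_mm = (6 * volMm3 / pi)^(1 / 3),
          compactness = min(36 * pi * volMm3^2 / A^3, 1))
  out <- c(fo, s2, s3)
  if (anyNA(out)) stop("internal error: missing feature values")
  out
}

# Exposed-face surface area with the 2/3 staircase correction (the expected
# face-count area of a smooth convex surface is 3/2 its true area).
#' @noRd
.surfaceAreaMm2 <- function(vox, dims, sp) {
  m <- array(FALSE, dim = dims)
  m[vox] <- TRUE
  faceArea <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  tot <- 0
  for (ax in 1:3) {
    sh <- function(off) {
      idx <- vox
      idx[, ax] <- idx[, ax] + off
      ok <- idx[, ax] >= 1 & idx[, ax] <= dims[ax]
      exposed <- !ok
      exposed[ok] <- !m[idx[ok, , drop = FALSE]]
      sum(exposed)
    }
    tot <- tot + (sh(1L) + sh(-1L)) * faceArea[ax]
  }
  tot * 2 / 3
}

#' @noRd
.boundaryPixels <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  core <- pad[2:(H + 1), 2:(W + 1)]
  inner <- core & pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(core & !inner, arr.ind = TRUE)
}

#' Univariate feature screening
#'
#' Welch two-sample t-test per numeric feature and chi-square test per
#' factor feature; features with p < `alpha` are retained. Constant
#' features are excluded with a warning rather than an error.
#'
#' @param X data frame or matrix of features (rows = samples).
#' @param y binary labels.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained feature names (possibly empty).
#' @export
screenFeatures <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  y <- as.integer(y > 0)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  keep <- character(0)
  for (nm in names(X)) {
    v <- X[[nm]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2L) {
        warning("constant feature excluded: ", nm)
        next
      }
      p <- suppressWarnings(stats::chisq.test(table(v, y))$p.value)
    } else {
      if (stats::var(v) == 0 || stats::var(v[y == 1]) + stats::var(v[y == 0]) == 0) {
        warning("constant feature excluded: ", nm)
        next
      }
      p <- stats::t.test(v ~ y)$p.value
    }
    if (is.finite(p) && p < alpha) keep <- c(keep, nm)
  }
  keep
}

#' @noRd
.stratFolds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    id[ix] <- rep_len(seq_len(folds), length(ix))[sample.int(length(ix))]
  }
  id
}

# Fit one logistic submodel: standardize, LASSO-select (when >= 2 features),
# then an unpenalized logistic fit on the surviving features. Returns a
# predictor plus its description.
#' @noRd
.fitSubmodel <- function(X, y, nlambda = 50L) {
  feats <- colnames(X)
  if (length(feats) == 0L) {
    prev <- mean(y)
    return(list(features = character(0), center = NULL, scale = NULL,
                coef = c(`(Intercept)` = stats::qlogis(min(max(prev, 1e-6),
                                                           1 - 1e-6))),
                predict = function(newX) rep(prev, nrow(newX))))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  sel <- feats
  if (length(feats) >= 2L) {
    nf <- max(3L, min(10L, floor(min(table(y)))))
    cvfit <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                               nlambda = nlambda, nfolds = nf,
                               standardize = FALSE)
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
    if (any(cf != 0)) sel <- feats[cf != 0]
  }
  df <- data.frame(Xs[, sel, drop = FALSE])
  names(df) <- sel
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  list(features = sel, center = ctr[sel], scale = scl[sel], coef = co,
       predict = function(newX) {
         Z <- scale(newX[, sel, drop = FALSE], center = ctr[sel],
                    scale = scl[sel])
         eta <- co[1] + as.numeric(Z %*% co[-1])
         stats::plogis(eta)
       })
}

#' Fit the spiculation-sign model with stratified cross-validation
#'
#' Features are split by name into the radiomics set (first-order `fo_*`
#' plus 3D shape) and the morphology set (2D shape `c2d_*`, `elong_*`,
#' `pa_*`, `radvar_*`). Each set is screened with [screenFeatures()],
#' LASSO-selected, and fit as a logistic model; the combined score is the
#' unweighted mean of the two model probabilities, thresholded at 0.5.
#' Stratified `folds`-fold cross-validation reports per-fold and pooled
#' SEN/SPE; the returned model is refit on all data.
#'
#' @param X feature matrix or data frame (columns named as produced by
#'   [extractFeatures()]).
#' @param y binary labels (1 = spiculated).
#' @param folds number of CV folds (default 10, stratified).
#' @param seed RNG seed for the fold assignment.
#' @param alpha screening significance level.
#' @param threshold decision threshold on the combined probability.
#' @return object of class `"SignModel"`: submodels, selected features,
#'   `cv` (per-fold SEN/SPE), `cvPooled` (SEN/SPE/FPF over pooled held-out
#'   predictions), `cvScores` and `cvLabels` for ROC analysis.
#' @export
fitSignModel <- function(X, y, folds = 10L, seed = 1L, alpha = 0.05,
                         threshold = 0.5) {
  X <- as.data.frame(X)
  y <- as.integer(y > 0)
  stopifnot(folds >= 2L, nrow(X) == length(y))
  morphNames <- grep("^(c2d|elong|pa|radvar)_", names(X), value = TRUE)
  radNames <- setdiff(names(X), morphNames)
  selRad <- screenFeatures(X[radNames], y, alpha)
  selMor <- if (length(morphNames)) screenFeatures(X[morphNames], y, alpha)
            else character(0)
  if (length(selRad) + length(selMor) == 0L) {
    stop("no features survive screening at alpha = ", alpha,
         "; relax alpha")
  }
  Xr <- as.matrix(X[selRad]); Xm <- as.matrix(X[selMor])
  predCombined <- function(mr, mm, idx) {
    (mr$predict(Xr[idx, , drop = FALSE]) +
       mm$predict(Xm[idx, , drop = FALSE])) / 2
  }
  # everything stochastic (fold assignment, internal LASSO CV) runs under
  # the caller's seed so a fit is exactly reproducible
  fitted <- .withSeed(seed, {
    foldId <- .stratFolds(y, folds)
    cv <- NULL
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- foldId != f; te <- !tr
      if (length(unique(y[tr])) < 2L || !any(te)) next
      mr <- .fitSubmodel(Xr[tr, , drop = FALSE], y[tr])
      mm <- .fitSubmodel(Xm[tr, , drop = FALSE], y[tr])
      pr <- predCombined(mr, mm, which(te))
      scores[te] <- pr
      pred <- as.integer(pr >= threshold)
      cv <- rbind(cv, data.frame(
        fold = f,
        SEN = if (any(y[te] == 1)) mean(pred[y[te] == 1] == 1) * 100 else NA,
        SPE = if (any(y[te] == 0)) mean(pred[y[te] == 0] == 0) * 100 else NA))
    }
    list(cv = cv, scores = scores,
         mrFull = .fitSubmodel(Xr, y), mmFull = .fitSubmodel(Xm, y))
  })
  cv <- fitted$cv; scores <- fitted$scores
  mrFull <- fitted$mrFull; mmFull <- fitted$mmFull
  predAll <- as.integer(scores >= threshold)
  pooled <- recognitionScores(TP = sum(predAll == 1 & y == 1),
                              FP = sum(predAll == 1 & y == 0),
                              TN = sum(predAll == 0 & y == 0),
                              FN = sum(predAll == 0 & y == 1))
  out <- list(radiomics = mrFull, morphology = mmFull,
              selected = list(radiomics = selRad, morphology = selMor),
              threshold = threshold, folds = folds, seed = seed,
              cv = cv, cvPooled = pooled, cvScores = scores, cvLabels = y)
  class(out) <- "SignModel"
  out
}

#' @exportS3Method base::print
print.SignModel <- function(x, ...) {
  cat(sprintf(
    "SignModel: %d radiomics + %d morphology features, %d-fold CV SEN %.1f%% SPE %.1f%%\n",
    length(x$radiomics$features), length(x$morphology$features), x$folds,
    x$cvPooled["SEN"], x$cvPooled["SPE"]))
  invisible(x)
}

#' Predict the spiculation sign for new feature rows
#'
#' @param object a `"SignModel"`.
#' @param newdata data frame / matrix with the model's feature columns.
#' @param ... unused.
#' @return data frame with the combined probability and the binary decision.
#' @export
predict.SignModel <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  pr <- (object$radiomics$predict(as.matrix(newdata)) +
           object$morphology$predict(as.matrix(newdata))) / 2
  data.frame(probability = pr, spiculated = pr >= object$threshold)
}

#' Fuse per-position sign decisions (OR rule)
#'
#' A nodule carries the spiculation sign when at least one of the three
#' position-wise decisions is positive.
#'
#' @param perPosition logical vector of exactly three decisions
#'   (axial, coronal, sagittal).
#' @return single logical.
#' @examples
#' fuseSignDecisions(c(FALSE, TRUE, FALSE))  # TRUE
#' @export
fuseSignDecisions <- function(perPosition) {
  if (length(perPosition) != 3L) stop("exactly three position decisions")
  any(as.logical(perPosition))
}
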