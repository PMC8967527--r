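# Minimal trainable layer toolkit used by both segmentation networks.
# Feature maps are H x W x C arrays; all layers carry their own parameters,
# gradients and forward cache in an environment so a network is just an
# ordered composition with hand-written adjoints.

.actFun <- function(z, act) {
  switch(act,
    linear  = z,
    relu    = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    mish    = mish(z),
    stop("unknown activation: ", act)
  )
}

.actGrad <- function(z, act) {
  switch(act,
    linear  = array(1, dim = dim(z)),
    relu    = (z > 0) * 1,
    sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
    mish    = mishGrad(z),
    stop("unknown activation: ", act)
  )
}

.as3d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' @noRd
newConv <- function(cin, cout, k = 3L, dil = 1L, stride = 1L,
                    pad = NULL, act = "relu", bias = TRUE) {
  if (is.null(pad)) pad <- ((k - 1L) * dil) %/% 2L
  L <- new.env(parent = emptyenv())
  L$kind <- "conv"
  L$cin <- cin; L$cout <- cout; L$k <- k; L$dil <- dil
  L$stride <- stride; L$pad <- pad; L$act <- act; L$bias <- bias
  sd <- sqrt(2 / (k * k * cin))
  L$w <- matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout)
  L$b <- if (bias) numeric(cout) else numeric(cout) # zero, frozen when !bias
  L$gw <- 0 * L$w; L$gb <- 0 * L$b
  L
}

#' @noRd
convFwd <- function(L, x) {
  x <- .as3d(x)
  if (dim(x)[3] != L$cin) {
    stop("channel mismatch: layer expects ", L$cin, " channels, got ",
         dim(x)[3])
  }
  z <- .nf_conv_fwd(x, L$w, L$b, L$k, L$dil, L$stride, L$pad)
  L$x <- x; L$z <- z
  .actFun(z, L$act)
}

#' @noRd
convBwd <- function(L, gy) {
  gz <- gy * .actGrad(L$z, L$act)
  gr <- .nf_conv_bwd(L$x, L$w, gz, L$k, L$dil, L$stride, L$pad)
  L$gw <- L$gw + gr$gw
  if (L$bias) L$gb <- L$gb + as.numeric(gr$gb)
  gr$gx
}

#' @noRd
newTConv <- function(cin, cout, k = 2L, stride = 2L, pad = 0L,
                     act = "linear") {
  L <- new.env(parent = emptyenv())
  L$kind <- "tconv"
  L$cin <- cin; L$cout <- cout; L$k <- k; L$stride <- stride; L$pad <- pad
  L$act <- act; L$bias <- TRUE
  sd <- sqrt(2 / (k * k * cin))
  L$w <- matrix(stats::rnorm(k * k * cout * cin, sd = sd), k * k * cout, cin)
  L$b <- numeric(cout)
  L$gw <- 0 * L$w; L$gb <- 0 * L$b
  L
}

#' @noRd
tconvFwd <- function(L, x) {
  x <- .as3d(x)
  if (dim(x)[3] != L$cin) {
    stop("channel mismatch: layer expects ", L$cin, " channels, got ",
         dim(x)[3])
  }
  outH <- L$stride * (dim(x)[1] - 1L) + L$k - 2L * L$pad
  outW <- L$stride * (dim(x)[2] - 1L) + L$k - 2L * L$pad
  z <- .nf_tconv_fwd(x, L$w, L$b, L$k, L$stride, L$pad, outH, outW)
  L$x <- x; L$z <- z
  .actFun(z, L$act)
}

#' @noRd
tconvBwd <- function(L, gy) {
  gz <- gy * .actGrad(L$z, L$act)
  gr <- .nf_tconv_bwd(L$x, L$w, gz, L$k, L$stride, L$pad)
  L$gw <- L$gw + gr$gw
  L$gb <- L$gb + as.numeric(gr$gb)
  gr$gx
}

#' @noRd
newFuse <- function(n, eps = 1e-4) {
  L <- new.env(parent = emptyenv())
  L$kind <- "fuse"
  L$n <- n; L$eps <- eps
  L$u <- rep(1, n)
  L$gu <- numeric(n)
  L
}

# Fast normalized fusion: w_i = relu(u_i) / (sum relu(u_j) + eps).
#' @noRd
fuseFwd <- function(L, xs) {
  stopifnot(length(xs) == L$n)
  r <- pmax(L$u, 0)
  S <- sum(r) + L$eps
  wgt <- r / S
  y <- wgt[1] * xs[[1]]
  if (L$n > 1) for (i in 2:L$n) y <- y + wgt[i] * xs[[i]]
  L$xs <- xs; L$wgt <- wgt; L$S <- S
  y
}

#' @noRd
fuseBwd <- function(L, gy) {
  dots <- vapply(L$xs, function(x) sum(gy * x), numeric(1))
  gr <- (dots - sum(L$wgt * dots)) / L$S
  L$gu <- L$gu + gr * (L$u > 0)
  lapply(seq_len(L$n), function(i) L$wgt[i] * gy)
}

#' @noRd
fuseWeights <- function(L) {
  r <- pmax(L$u, 0)
  r / (sum(r) + L$eps)
}

#' @noRd
poolFwd <- function(L, x) {
  x <- .as3d(x)
  res <- .nf_maxpool2_fwd(x)
  L$idx <- res$idx; L$H <- dim(x)[1]; L$W <- dim(x)[2]
  res$y
}

#' @noRd
newPool <- function() {
  L <- new.env(parent = emptyenv())
  L$kind <- "pool"
  L
}

#' @noRd
poolBwd <- function(L, gy) {
  .nf_maxpool2_bwd(gy, L$idx, L$H, L$W)
}

# Collect every parameterised layer environment reachable from a nested list.
#' @noRd
collectLayers <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o)) {
      if (!is.null(o$kind) && o$kind %in% c("conv", "tconv", "fuse")) {
        out[[length(out) + 1L]] <<- o
      }
    } else if (is.list(o)) {
      lapply(o, walk)
    }
    invisible(NULL)
  }
  walk(obj)
  out
}

#' @noRd
zeroGrads <- function(layers) {
  for (L in layers) {
    if (L$kind == "fuse") L$gu <- 0 * L$gu
    else { L$gw <- 0 * L$gw; L$gb <- 0 * L$gb }
  }
  invisible(NULL)
}

#' @noRd
adamInit <- function(layers) {
  lapply(layers, function(L) {
    if (L$kind == "fuse") list(mu = 0 * L$u, vu = 0 * L$u)
    else list(mw = 0 * L$w, vw = 0 * L$w, mb = 0 * L$b, vb = 0 * L$b)
  })
}

#' @noRd
adamStep <- function(layers, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  upd <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v, step = lr * (m / c1) / (sqrt(v / c2) + eps))
  }
  for (i in seq_along(layers)) {
    L <- layers[[i]]; s <- state[[i]]
    if (L$kind == "fuse") {
      r <- upd(s$mu, s$vu, L$gu)
      L$u <- L$u - r$step
      state[[i]] <- list(mu = r$m, vu = r$v)
    } else {
      rw <- upd(s$mw, s$vw, L$gw)
      L$w <- L$w - rw$step
      rb <- upd(s$mb, s$vb, L$gb)
      if (L$bias) L$b <- L$b - rb$step
      state[[i]] <- list(mw = rw$m, vw = rw$v, mb = rb$m, vb = rb$v)
    }
  }
  state
}

# Replicate-pad a slice (or H x W x C map) on the bottom/right to a multiple
# of `mult`; the adjoint of the matching crop is zero-padding, and the input
# itself carries no gradient, so training only needs the crop adjoint.
#' @noRd
padToMultiple <- function(x, mult) {
  x <- .as3d(x)
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1] / mult) * mult)
  W2 <- as.integer(ceiling(d[2] / mult) * mult)
  if (H2 == d[1] && W2 == d[2]) return(x)
  y <- array(0, dim = c(H2, W2, d[3]))
  ri <- pmin(seq_len(H2), d[1])
  ci <- pmin(seq_len(W2), d[2])
  for (c in seq_len(d[3])) y[, , c] <- x[ri, ci, c]
  y
}

#' @noRd
cropTo <- function(x, H, W) {
  if (length(dim(x)) == 3L) x[seq_len(H), seq_len(W), , drop = FALSE]
  else x[seq_len(H), seq_len(W), drop = FALSE]
}

#' @noRd
zeroPadTo <- function(g, H2, W2) {
  d <- dim(g)
  if (length(d) == 2L) g <- array(g, dim = c(d, 1L))
  d <- dim(g)
  if (d[1] == H2 && d[2] == W2) return(g)
  y <- array(0, dim = c(H2, W2, d[3]))
  y[seq_len(d[1]), seq_len(d[2]), ] <- g
  y
}
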