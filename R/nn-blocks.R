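# Composite network blocks: additive attention gate, dense atrous
# convolution (DAC) bottleneck, and multiscale parallel sampling blocks.

# ---- attention gate ---------------------------------------------------------

#' Create an additive attention gate
#'
#' The gate weights a skip-connection ("coding") feature map `x` by attention
#' coefficients computed from `x` and a gating ("upsampling") feature map `g`:
#' \deqn{\alpha = \sigma_2(\varphi^T \sigma_1(W_x^T x + W_g^T g + b_g)),}
#' with \eqn{\sigma_1} the rectifier and \eqn{\sigma_2} the logistic sigmoid,
#' all projections 1x1 convolutions. The output is \eqn{\alpha \odot x}, so
#' coefficients lie strictly in (0,1) and the gate can only attenuate.
#'
#' @param cinX channels of the gated feature map `x`.
#' @param cinG channels of the gating signal `g`.
#' @param inter channels of the additive projection.
#' @return an opaque gate object usable with [attentionGate()].
#' @seealso [attentionGate()]
#' @export
newAttentionGate <- function(cinX, cinG, inter = max(cinX %/% 2L, 1L)) {
  list(
    kind = "ag",
    wx  = newConv(cinX, inter, k = 1L, act = "linear", bias = FALSE),
    wg  = newConv(cinG, inter, k = 1L, act = "linear", bias = TRUE),
    psi = newConv(inter, 1L, k = 1L, act = "linear", bias = TRUE)
  )
}

#' Apply an attention gate
#'
#' @param gate a gate from [newAttentionGate()].
#' @param x coding feature map (H x W x Cx array) to be gated.
#' @param g gating feature map (H x W x Cg array), same spatial size as `x`.
#' @return the gated map \eqn{\alpha \odot x}; the coefficients are available
#'   as attribute `"alpha"` (an H x W matrix with values in (0,1)).
#' @examples
#' g <- newAttentionGate(1, 1, inter = 1)
#' # scalar hand-check: W_x = W_g = phi = 1, biases 0, x = g = 1
#' g$wx$w[] <- 1; g$wg$w[] <- 1; g$wg$b[] <- 0; g$psi$w[] <- 1; g$psi$b[] <- 0
#' y <- attentionGate(g, array(1, c(1, 1, 1)), array(1, c(1, 1, 1)))
#' stopifnot(abs(attr(y, "alpha") - plogis(2)) < 1e-12)
#' @export
attentionGate <- function(gate, x, g) {
  x <- .as3d(x); g <- .as3d(g)
  if (!all(dim(x)[1:2] == dim(g)[1:2])) {
    stop("attention gate inputs must share spatial size")
  }
  a1 <- convFwd(gate$wx, x)
  a2 <- convFwd(gate$wg, g)
  s <- a1 + a2
  z <- pmax(s, 0)
  gate$wx$sMask <- (s > 0) * 1
  gate$wx$zCache <- z
  alpha <- 1 / (1 + exp(-convFwd(gate$psi, z)))
  gate$psi$alpha <- alpha
  cx <- dim(x)[3]
  out <- x * array(alpha, dim = c(dim(alpha)[1:2], cx))
  attr(out, "alpha") <- alpha[, , 1]
  out
}

#' @noRd
attentionGateBwd <- function(gate, gy) {
  x <- gate$wx$x
  alpha <- gate$psi$alpha
  cx <- dim(x)[3]
  aB <- array(alpha, dim = c(dim(alpha)[1:2], cx))
  gxDirect <- gy * aB
  gAlpha <- array(rowSums(gy * x, dims = 2), dim = dim(alpha))
  gPsiOut <- gAlpha * alpha * (1 - alpha)
  gz <- convBwd(gate$psi, gPsiOut)
  gs <- gz * gate$wx$sMask
  gxAtt <- convBwd(gate$wx, gs)
  gg <- convBwd(gate$wg, gs)
  list(gx = gxDirect + gxAtt, gg = gg)
}

# ---- dense atrous convolution block ----------------------------------------

#' Cascade branch compositions of the dense atrous convolution block
#'
#' Four branches of stacked stride-1 convolutions given as (kernel, dilation)
#' pairs. Their effective receptive fields are 3, 7, 9 and 19 pixels
#' (see [receptiveField()]).
#'
#' @return a list of four branches; each branch is a list of `c(kernel,
#'   dilation)` integer pairs.
#' @export
dacBranches <- function() {
  list(
    list(c(3L, 1L)),
    list(c(3L, 3L), c(1L, 1L)),
    list(c(3L, 1L), c(3L, 3L), c(1L, 1L)),
    list(c(3L, 1L), c(3L, 3L), c(3L, 5L), c(1L, 1L))
  )
}

#' Effective receptive field of a stacked convolution branch
#'
#' For stride-1 convolutions with odd kernels \eqn{k_i} and dilations
#' \eqn{d_i}, the receptive field is \eqn{1 + \sum_i d_i (k_i - 1)}.
#'
#' @param branch a list of `c(kernel, dilation)` pairs; an empty branch has
#'   receptive field 1.
#' @return integer receptive field in pixels.
#' @examples
#' receptiveField(list(c(3, 1)))                           # 3
#' receptiveField(list(c(3, 1), c(3, 3), c(3, 5), c(1, 1))) # 19
#' @export
receptiveField <- function(branch) {
  if (length(branch) == 0L) return(1L)
  ks <- vapply(branch, function(p) as.integer(p[1]), integer(1))
  ds <- vapply(branch, function(p) as.integer(p[2]), integer(1))
  if (any(ks %% 2L == 0L)) stop("kernels must be odd")
  if (any(ds < 1L)) stop("dilations must be >= 1")
  1L + sum(ds * (ks - 1L))
}

#' Create a dense atrous convolution (DAC) block
#'
#' Four parallel cascade branches of dilated convolutions (receptive fields
#' 3/7/9/19) whose outputs are summed together with the residual input, so the
#' block enlarges the receptive field at unchanged spatial size and channel
#' count. Convolutions inside a branch use the rectifier except the final one.
#'
#' @param channels channel count preserved by the block.
#' @return an opaque block object usable with [dacBlock()].
#' @export
newDacBlock <- function(channels) {
  branches <- lapply(dacBranches(), function(br) {
    n <- length(br)
    lapply(seq_len(n), function(i) {
      k <- br[[i]][1]; d <- br[[i]][2]
      newConv(channels, channels, k = k, dil = d,
              act = if (i < n) "relu" else "linear")
    })
  })
  list(kind = "dac", channels = channels, branches = branches)
}

#' Apply a dense atrous convolution block
#'
#' @param block a block from [newDacBlock()].
#' @param f feature map (H x W x C array) with `C == block$channels`.
#' @return feature map of identical shape: residual input plus the sum of the
#'   four branch outputs.
#' @export
dacBlock <- function(block, f) {
  f <- .as3d(f)
  out <- f
  for (br in block$branches) {
    h <- f
    for (L in br) h <- convFwd(L, h)
    out <- out + h
  }
  out
}

#' @noRd
dacBlockBwd <- function(block, gy) {
  gx <- gy
  for (br in block$branches) {
    g <- gy
    for (L in rev(br)) g <- convBwd(L, g)
    gx <- gx + g
  }
  gx
}

# ---- multiscale parallel sampling blocks -----------------------------------

# Downsampling: parallel stride-2 convolutions (kernels 3 and 5) fused by
# addition, halving the spatial size exactly.
#' @noRd
newDownBlock <- function(cin, cout) {
  list(kind = "down",
       a = newConv(cin, cout, k = 3L, stride = 2L, pad = 1L, act = "linear"),
       b = newConv(cin, cout, k = 5L, stride = 2L, pad = 2L, act = "linear"))
}

#' @noRd
downBlockFwd <- function(blk, x) {
  z <- convFwd(blk$a, x) + convFwd(blk$b, x)
  blk$a$sumZ <- z
  pmax(z, 0)
}

#' @noRd
downBlockBwd <- function(blk, gy) {
  gz <- gy * (blk$a$sumZ > 0)
  convBwd(blk$a, gz) + convBwd(blk$b, gz)
}

# Upsampling: parallel transposed convolutions (kernels 2 and 4) fused by
# addition, doubling the spatial size exactly.
#' @noRd
newUpBlock <- function(cin, cout) {
  list(kind = "up",
       a = newTConv(cin, cout, k = 2L, stride = 2L, pad = 0L, act = "linear"),
       b = newTConv(cin, cout, k = 4L, stride = 2L, pad = 1L, act = "linear"))
}

#' @noRd
upBlockFwd <- function(blk, x) {
  z <- tconvFwd(blk$a, x) + tconvFwd(blk$b, x)
  blk$a$sumZ <- z
  pmax(z, 0)
}

#' @noRd
upBlockBwd <- function(blk, gy) {
  gz <- gy * (blk$a$sumZ > 0)
  tconvBwd(blk$a, gz) + tconvBwd(blk$b, gz)
}
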