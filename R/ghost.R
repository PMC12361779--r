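# Ghost convolution: a thin "primary" convolution produces the intrinsic
# feature maps; cheap linear operations on those maps generate the
# remaining "ghost" maps, and the two sets are concatenated to the target
# width. A ghost bottleneck chains two ghost modules (expand / linear
# project) around an optional stride-2 depthwise convolution and a
# channel-attention stage, with an identity residual when shapes permit.
#
# The calibrated package defaults use ratio s = 2, a 1x1 primary
# convolution (BN + Swish) and a per-map pointwise linear cheap branch
# (depthwise 1x1, no BN or activation). With these defaults, substituting
# MBConv stages 4 and 7 of the printed table reproduces the published
# 2.82M parameter count; see the methods vignette for the calibration.

#' Ghost module configuration
#'
#' @param ratio intrinsic:total split s >= 1; the primary convolution
#'   produces `ceiling(out/s)` intrinsic maps.
#' @param primary_kernel odd kernel of the primary convolution.
#' @param cheap_kernel odd kernel of the depthwise cheap branch; 1 gives a
#'   per-map scalar linear map.
#' @param cheap_bn,cheap_act apply BN / Swish on the cheap branch
#'   (off by default: the cheap branch is a pure linear operation).
#' @return a `ghost_config` list.
#' @export
ghost_config <- function(ratio = 2L, primary_kernel = 1L, cheap_kernel = 1L,
                         cheap_bn = FALSE, cheap_act = FALSE) {
  stopifnot(ratio >= 1, primary_kernel %% 2 == 1, cheap_kernel %% 2 == 1)
  structure(list(ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 cheap_bn = cheap_bn, cheap_act = cheap_act),
            class = "ghost_config")
}

#' Build a ghost module
#'
#' Primary convolution `in_ch -> m` (`m = ceiling(out_ch/ratio)`, BN +
#' optional activation), then a depthwise cheap branch producing
#' `(ratio-1)*m` ghost maps; the concatenation is truncated to `out_ch`.
#' With `ratio = 1` the module degenerates to a plain convolution.
#'
#' @param in_ch,out_ch channel counts.
#' @param cfg a [ghost_config()].
#' @param act apply Swish after the primary BN.
#' @param name layer name.
#' @return a composite layer.
#' @export
build_ghost_module <- function(in_ch, out_ch, cfg = ghost_config(),
                               act = TRUE, name = "ghost") {
  stopifnot(out_ch >= 1)
  m <- as.integer(ceiling(out_ch / cfg$ratio))
  if (cfg$ratio * m > 16L * out_ch)
    stop("ghost split exceeds sanity bound")
  primary <- list(conv_layer(in_ch, m, cfg$primary_kernel, name = "primary"),
                  bn_layer(m, act = act, name = "primary_bn"))
  cheap <- if (cfg$ratio > 1L) {
    cl <- list(dwconv_layer(m, cfg$cheap_kernel, name = "cheap"))
    if (cfg$cheap_bn) {
      cl <- c(cl, list(bn_layer(m, act = cfg$cheap_act, name = "cheap_bn")))
    } else if (cfg$cheap_act) {
      cl <- c(cl, list(swish_layer("cheap_act")))
    }
    cl
  } else list()
  ly <- new_layer("ghost_module", list(
    name = name, in_ch = in_ch, out_ch = as.integer(out_ch), m = m,
    ratio = cfg$ratio))
  ly$children <- c(primary, cheap)
  ly$primary <- primary
  ly$cheap <- cheap
  ly
}

#' @export
layer_fwd.cg_ghost_module <- function(ly, fm, training = FALSE) {
  for (ch in ly$primary) fm <- layer_fwd(ch, fm, training)
  p <- fm
  if (length(ly$cheap) == 0L) {
    out <- p
  } else {
    g <- p
    for (ch in ly$cheap) g <- layer_fwd(ch, g, training)
    n_ghost <- ly$out_ch - ly$m
    reps <- cbind(p$x, g$x)[, seq_len(ly$out_ch), drop = FALSE]
    ly$.n_ghost <- n_ghost
    out <- fm_new(reps, p$n, p$h, p$w)
  }
  out
}

#' @export
layer_bwd.cg_ghost_module <- function(ly, dfm) {
  if (length(ly$cheap) == 0L) {
    dp <- dfm
  } else {
    m <- ly$m
    n_ghost <- ly$.n_ghost
    dpx <- dfm$x[, seq_len(m), drop = FALSE]
    dgx <- matrix(0, nrow(dfm$x), m)
    if (n_ghost > 0)
      dgx[, seq_len(n_ghost)] <- dfm$x[, m + seq_len(n_ghost), drop = FALSE]
    dg <- fm_new(dgx, dfm$n, dfm$h, dfm$w)
    for (ch in rev(ly$cheap)) dg <- layer_bwd(ch, dg)
    dp <- fm_new(dpx + dg$x, dfm$n, dfm$h, dfm$w)
  }
  for (ch in rev(ly$primary)) dp <- layer_bwd(ch, dp)
  dp
}

#' @export
layer_count.cg_ghost_module <- function(ly, h, w) {
  params <- 0
  macs <- 0
  for (ch in ly$primary) {
    ct <- layer_count(ch, h, w)
    params <- params + ct$params
    macs <- macs + ct$macs
    h <- ct$h
    w <- ct$w
  }
  for (ch in ly$cheap) {
    ct <- layer_count(ch, h, w)
    params <- params + ct$params
    macs <- macs + ct$macs
  }
  list(params = params, macs = macs, h = h, w = w)
}

#' Build a ghost bottleneck
#'
#' Ghost-module expansion `in -> in*expansion`, an optional depthwise
#' k x k stride-2 convolution, a channel-attention stage on the expanded
#' features, and a linear ghost-module projection to `out_ch`; identity
#' residual iff stride 1 and `in_ch == out_ch`.
#'
#' @param in_ch,out_ch channel counts.
#' @param expansion expansion factor (1 or 6 in the host table).
#' @param kernel odd depthwise kernel for the stride-2 convolution.
#' @param stride 1 or 2.
#' @param attention `"ECA"` (default), `"SE"` (ratio 0.25 of `in_ch`) or
#'   `"none"`.
#' @param cfg a [ghost_config()].
#' @param eca_cfg an [eca_config()] used when `attention = "ECA"`.
#' @return a block layer.
#' @export
build_ghost_bottleneck <- function(in_ch, out_ch, expansion, kernel, stride,
                                   attention = c("ECA", "SE", "none"),
                                   cfg = ghost_config(),
                                   eca_cfg = eca_config()) {
  attention <- match.arg(attention)
  stopifnot(stride %in% c(1L, 2L))
  if (kernel %% 2 == 0) stop("kernel must be odd")
  mid <- in_ch * expansion
  layers <- list(build_ghost_module(in_ch, mid, cfg, act = TRUE,
                                    name = "ghost_expand"))
  if (stride == 2L) {
    layers <- c(layers, list(dwconv_layer(mid, kernel, 2L, name = "dw"),
                             bn_layer(mid, name = "dw_bn")))
  }
  if (attention == "ECA") {
    layers <- c(layers, list(eca_layer(mid, cfg = eca_cfg)))
  } else if (attention == "SE") {
    red <- max(1L, as.integer(round(in_ch * 0.25)))
    layers <- c(layers, list(se_layer(mid, red)))
  }
  layers <- c(layers, list(build_ghost_module(mid, out_ch, cfg, act = FALSE,
                                              name = "ghost_project")))
  kind <- switch(attention, ECA = "ghost_eca", SE = "ghost_se",
                 none = "ghost")
  block_layer(layers, residual = (stride == 1L && in_ch == out_ch),
              kind = kind)
}
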