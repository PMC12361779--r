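#' @useDynLib cgenet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Layer framework.
#
# A layer is a mutable environment with class c("cg_<kind>", "cg_layer").
# Batched activations travel as "fm" lists: list(x = (N*H*W) x C matrix,
# n, h, w); rows are ordered image-major, then row, then column, so that
# every 1x1 convolution is a single GEMM. Three S3 generics drive the
# network: layer_fwd() (caches what backward needs), layer_bwd() (returns
# the input gradient and accumulates weight gradients into ly$g), and
# layer_count() (shape-propagating parameter/MAC accounting, no tensors).
# ---------------------------------------------------------------------------

new_layer <- function(kind, fields = list()) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- kind
  ly$name <- kind
  ly$children <- list()
  ly$w <- list()
  ly$g <- list()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  class(ly) <- c(paste0("cg_", kind), "cg_layer")
  ly
}

fm_new <- function(x, n, h, w) list(x = x, n = n, h = h, w = w)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Swish activation
#'
#' The smooth, non-monotone activation `x * sigmoid(x)` used throughout the
#' EfficientNet backbone and the ghost modules.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape as `x`.
#' @examples
#' swish(0)      # 0
#' swish(1)      # 0.7310586
#' @export
swish <- function(x) x * sigmoid(x)

swish_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# The generics carry light-weight tap hooks used by Grad-CAM: a layer
# flagged .tap_in records its input activation on the way forward, one
# flagged .tap_dy records the gradient arriving at its output on the way
# back.
layer_fwd <- function(ly, fm, training = FALSE) {
  if (isTRUE(ly$.tap_in)) ly$.tap_x <- fm
  UseMethod("layer_fwd")
}

#' @export
layer_count.default <- function(ly, h, w)
  stop("unsupported layer kind for complexity accounting: ", ly$kind)
layer_bwd <- function(ly, dfm) {
  if (isTRUE(ly$.tap_dy)) ly$.tap_grad <- dfm
  UseMethod("layer_bwd")
}
layer_count <- function(ly, h, w) UseMethod("layer_count")

# ---- dense convolution ----------------------------------------------------

conv_layer <- function(in_ch, out_ch, k = 1, stride = 1, bias = FALSE,
                       name = "conv") {
  ly <- new_layer("conv", list(
    in_ch = in_ch, out_ch = out_ch, k = k, stride = stride,
    pad = (k - 1) %/% 2, bias = bias, name = name))
  sd <- sqrt(2 / (k * k * in_ch))
  ly$w$W <- matrix(stats::rnorm(in_ch * k * k * out_ch, 0, sd),
                   in_ch * k * k, out_ch)
  if (bias) ly$w$b <- numeric(out_ch)
  ly
}

#' @export
layer_fwd.cg_conv <- function(ly, fm, training = FALSE) {
  plain <- ly$k == 1L && ly$stride == 1L
  col <- if (plain) fm$x else
    nn_im2col(fm$x, fm$n, fm$h, fm$w, ly$k, ly$stride, ly$pad)
  y <- col %*% ly$w$W
  if (ly$bias) y <- y + rowrep(ly$w$b, nrow(y))
  ly$.col <- col
  ly$.in <- fm[c("n", "h", "w")]
  ho <- if (plain) fm$h else (fm$h + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  wo <- if (plain) fm$w else (fm$w + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  fm_new(y, fm$n, ho, wo)
}

#' @export
layer_bwd.cg_conv <- function(ly, dfm) {
  dy <- dfm$x
  ly$g$W <- crossprod(ly$.col, dy)
  if (ly$bias) ly$g$b <- colSums(dy)
  dcol <- dy %*% t(ly$w$W)
  s <- ly$.in
  dx <- if (ly$k == 1L && ly$stride == 1L) dcol else
    nn_col2im(dcol, s$n, s$h, s$w, ly$in_ch, ly$k, ly$stride, ly$pad)
  fm_new(dx, s$n, s$h, s$w)
}

#' @export
layer_count.cg_conv <- function(ly, h, w) {
  ho <- (h + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  wo <- (w + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  list(params = length(ly$w$W) + if (ly$bias) ly$out_ch else 0L,
       macs = as.double(ly$k)^2 * ly$in_ch * ly$out_ch * ho * wo,
       h = ho, w = wo)
}

# ---- depthwise convolution ------------------------------------------------

dwconv_layer <- function(ch, k, stride = 1, name = "dwconv") {
  ly <- new_layer("dwconv", list(ch = ch, k = k, stride = stride,
                                 pad = (k - 1) %/% 2, name = name))
  ly$w$W <- matrix(stats::rnorm(k * k * ch, 0, sqrt(2 / (k * k))), k * k, ch)
  ly
}

#' @export
layer_fwd.cg_dwconv <- function(ly, fm, training = FALSE) {
  y <- nn_dwconv_fwd(fm$x, ly$w$W, fm$n, fm$h, fm$w, ly$k, ly$stride, ly$pad)
  ly$.x <- fm$x
  ly$.in <- fm[c("n", "h", "w")]
  ho <- (fm$h + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  wo <- (fm$w + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  fm_new(y, fm$n, ho, wo)
}

#' @export
layer_bwd.cg_dwconv <- function(ly, dfm) {
  s <- ly$.in
  ly$g$W <- nn_dwconv_bwd_w(ly$.x, dfm$x, s$n, s$h, s$w, ly$k, ly$stride, ly$pad)
  dx <- nn_dwconv_bwd_x(dfm$x, ly$w$W, s$n, s$h, s$w, ly$k, ly$stride, ly$pad)
  fm_new(dx, s$n, s$h, s$w)
}

#' @export
layer_count.cg_dwconv <- function(ly, h, w) {
  ho <- (h + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  wo <- (w + 2 * ly$pad - ly$k) %/% ly$stride + 1L
  list(params = length(ly$w$W),
       macs = as.double(ly$k)^2 * ly$ch * ho * wo, h = ho, w = wo)
}

# ---- batch normalization --------------------------------------------------

# Batch normalization with an optionally fused Swish activation
# (`act = TRUE`); fusing keeps the hot path to one allocation per layer
# and per direction. Running statistics use the conventional momentum
# 0.1 so that evaluation-mode statistics track training within the short
# desk-scale runs this package targets.
bn_layer <- function(ch, eps = 1e-3, momentum = 0.1, act = FALSE,
                     name = "bn") {
  ly <- new_layer("bn", list(ch = ch, eps = eps, momentum = momentum,
                             act = act, name = name))
  ly$w$gamma <- rep(1, ch)
  ly$w$beta <- numeric(ch)
  ly$run_mean <- numeric(ch)
  ly$run_var <- rep(1, ch)
  ly
}

#' @export
layer_fwd.cg_bn <- function(ly, fm, training = FALSE) {
  if (training) {
    mv <- nn_col_meanvar(fm$x)
    mu <- mv$mean
    v <- mv$var
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
  } else {
    mu <- ly$run_mean
    v <- ly$run_var
  }
  invstd <- 1 / sqrt(v + ly$eps)
  y <- nn_bn_act_fwd(fm$x, mu, invstd, ly$w$gamma, ly$w$beta, ly$act)
  ly$.x <- fm$x
  ly$.mu <- mu
  ly$.invstd <- invstd
  ly$.training <- training
  fm_new(y, fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_bn <- function(ly, dfm) {
  r <- nn_bn_act_bwd(dfm$x, ly$.x, ly$.mu, ly$.invstd, ly$w$gamma,
                     ly$w$beta, ly$act, isTRUE(ly$.training))
  ly$g$gamma <- r$dgamma
  ly$g$beta <- r$dbeta
  fm_new(r$dx, dfm$n, dfm$h, dfm$w)
}

#' @export
layer_count.cg_bn <- function(ly, h, w)
  list(params = 2L * ly$ch, macs = 0, h = h, w = w)

# ---- activations ----------------------------------------------------------

swish_layer <- function(name = "swish") new_layer("swish", list(name = name))

#' @export
layer_fwd.cg_swish <- function(ly, fm, training = FALSE) {
  ly$.x <- fm$x
  fm_new(nn_swish_fwd(fm$x), fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_swish <- function(ly, dfm)
  fm_new(nn_swish_bwd(ly$.x, dfm$x), dfm$n, dfm$h, dfm$w)

#' @export
layer_count.cg_swish <- function(ly, h, w)
  list(params = 0L, macs = 0, h = h, w = w)

# ---- global average pooling ----------------------------------------------

gap_layer <- function(name = "gap") new_layer("gap", list(name = name))

#' @export
layer_fwd.cg_gap <- function(ly, fm, training = FALSE) {
  y <- nn_gap(fm$x, fm$n, fm$h * fm$w)
  ly$.in <- fm[c("n", "h", "w")]
  fm_new(y, fm$n, 1L, 1L)
}

#' @export
layer_bwd.cg_gap <- function(ly, dfm) {
  s <- ly$.in
  hw <- s$h * s$w
  dx <- dfm$x[rep(seq_len(s$n), each = hw), , drop = FALSE] / hw
  fm_new(dx, s$n, s$h, s$w)
}

#' @export
layer_count.cg_gap <- function(ly, h, w)
  list(params = 0L, macs = 0, h = 1L, w = 1L)

# ---- fully connected ------------------------------------------------------

fc_layer <- function(in_ch, out_ch, bias = TRUE, name = "fc") {
  ly <- new_layer("fc", list(in_ch = in_ch, out_ch = out_ch, bias = bias,
                             name = name))
  sd <- sqrt(1 / in_ch)
  ly$w$W <- matrix(stats::rnorm(in_ch * out_ch, 0, sd), in_ch, out_ch)
  if (bias) ly$w$b <- numeric(out_ch)
  ly
}

#' @export
layer_fwd.cg_fc <- function(ly, fm, training = FALSE) {
  y <- fm$x %*% ly$w$W
  if (ly$bias) y <- y + rowrep(ly$w$b, nrow(y))
  ly$.x <- fm$x
  fm_new(y, fm$n, 1L, 1L)
}

#' @export
layer_bwd.cg_fc <- function(ly, dfm) {
  ly$g$W <- crossprod(ly$.x, dfm$x)
  if (ly$bias) ly$g$b <- colSums(dfm$x)
  fm_new(dfm$x %*% t(ly$w$W), dfm$n, 1L, 1L)
}

#' @export
layer_count.cg_fc <- function(ly, h, w)
  list(params = length(ly$w$W) + if (ly$bias) ly$out_ch else 0L,
       macs = as.double(ly$in_ch) * ly$out_ch, h = 1L, w = 1L)

# ---- dropout --------------------------------------------------------------

dropout_layer <- function(p = 0.2, name = "dropout")
  new_layer("dropout", list(p = p, name = name))

#' @export
layer_fwd.cg_dropout <- function(ly, fm, training = FALSE) {
  if (!training || ly$p <= 0) {
    ly$.mask <- NULL
    return(fm)
  }
  mask <- (stats::runif(length(fm$x)) >= ly$p) / (1 - ly$p)
  dim(mask) <- dim(fm$x)
  ly$.mask <- mask
  fm_new(fm$x * mask, fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_dropout <- function(ly, dfm) {
  if (is.null(ly$.mask)) return(dfm)
  fm_new(dfm$x * ly$.mask, dfm$n, dfm$h, dfm$w)
}

#' @export
layer_count.cg_dropout <- function(ly, h, w)
  list(params = 0L, macs = 0, h = h, w = w)

# ---- composites -----------------------------------------------------------

seq_layer <- function(children, name = "seq", kind = "seq") {
  ly <- new_layer(kind, list(name = name))
  class(ly) <- c(paste0("cg_", kind), "cg_seq", "cg_layer")
  ly$children <- children
  ly
}

#' @export
layer_fwd.cg_seq <- function(ly, fm, training = FALSE) {
  for (ch in ly$children) fm <- layer_fwd(ch, fm, training)
  fm
}

#' @export
layer_bwd.cg_seq <- function(ly, dfm) {
  for (ch in rev(ly$children)) dfm <- layer_bwd(ch, dfm)
  dfm
}

#' @export
layer_count.cg_seq <- function(ly, h, w) {
  params <- 0
  macs <- 0
  for (ch in ly$children) {
    ct <- layer_count(ch, h, w)
    params <- params + ct$params
    macs <- macs + ct$macs
    h <- ct$h
    w <- ct$w
  }
  list(params = params, macs = macs, h = h, w = w)
}

# A block is a sequential body with an optional identity residual; `kind`
# labels the block type for structural audits ("mbconv", "ghost_eca", ...).
block_layer <- function(children, residual = FALSE, kind = "block",
                        name = kind) {
  ly <- seq_layer(children, name = name, kind = kind)
  class(ly) <- c(paste0("cg_", kind), "cg_block", "cg_seq", "cg_layer")
  ly$residual <- residual
  ly
}

#' @export
layer_fwd.cg_block <- function(ly, fm, training = FALSE) {
  xin <- fm$x
  for (ch in ly$children) fm <- layer_fwd(ch, fm, training)
  if (isTRUE(ly$residual)) fm$x <- fm$x + xin
  fm
}

#' @export
layer_bwd.cg_block <- function(ly, dfm) {
  dtop <- dfm
  for (ch in rev(ly$children)) dfm <- layer_bwd(ch, dfm)
  if (isTRUE(ly$residual)) dfm$x <- dfm$x + dtop$x
  dfm
}

# ---- traversal ------------------------------------------------------------

layer_leaves <- function(ly) {
  if (length(ly$children) == 0L) return(list(ly))
  out <- list()
  for (ch in ly$children) out <- c(out, layer_leaves(ch))
  out
}

assign_ids <- function(ly, prefix = NULL) {
  id <- if (is.null(prefix)) ly$name else paste(prefix, ly$name, sep = ".")
  ly$id <- id
  if (length(ly$children)) {
    nms <- vapply(ly$children, function(ch) ch$name, character(1))
    dup <- ave(seq_along(nms), nms, FUN = seq_along)
    for (i in seq_along(ly$children)) {
      ch <- ly$children[[i]]
      nm <- if (sum(nms == nms[i]) > 1) paste0(nms[i], dup[i]) else nms[i]
      ch$name <- nm
      assign_ids(ch, id)
    }
  }
  invisible(ly)
}

find_layer <- function(ly, id) {
  if (identical(ly$id, id)) return(ly)
  for (ch in ly$children) {
    hit <- find_layer(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}
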