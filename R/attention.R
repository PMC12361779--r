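# Channel attention: squeeze-and-excitation (SE) and efficient channel
# attention (ECA). Both gate channels with factors in (0,1) computed from
# the globally average-pooled channel vector; SE uses a bottleneck MLP,
# ECA a single 1-D convolution across the channel axis whose parameter
# count equals its kernel size.

se_layer <- function(ch, reduced, name = "se") {
  stopifnot(reduced >= 1)
  ly <- new_layer("se", list(ch = ch, reduced = reduced, name = name))
  sd1 <- sqrt(2 / ch)
  sd2 <- sqrt(2 / reduced)
  ly$w$W1 <- matrix(stats::rnorm(ch * reduced, 0, sd1), ch, reduced)
  ly$w$b1 <- numeric(reduced)
  ly$w$W2 <- matrix(stats::rnorm(reduced * ch, 0, sd2), reduced, ch)
  ly$w$b2 <- numeric(ch)
  ly
}

#' @export
layer_fwd.cg_se <- function(ly, fm, training = FALSE) {
  hw <- fm$h * fm$w
  z <- nn_gap(fm$x, fm$n, hw)
  a1 <- z %*% ly$w$W1 + rowrep(ly$w$b1, fm$n)
  h1 <- swish(a1)
  a2 <- h1 %*% ly$w$W2 + rowrep(ly$w$b2, fm$n)
  s <- sigmoid(a2)
  ly$.x <- fm$x
  ly$.z <- z
  ly$.a1 <- a1
  ly$.h1 <- h1
  ly$.s <- s
  ly$.hw <- hw
  fm_new(nn_scale_ch(fm$x, s, hw), fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_se <- function(ly, dfm) {
  dy <- dfm$x
  s <- ly$.s
  ds <- nn_scale_sum(ly$.x, dy, dfm$n, ly$.hw)
  da2 <- ds * s * (1 - s)
  ly$g$b2 <- colSums(da2)
  ly$g$W2 <- crossprod(ly$.h1, da2)
  dh1 <- da2 %*% t(ly$w$W2)
  da1 <- dh1 * swish_grad(ly$.a1)
  ly$g$b1 <- colSums(da1)
  ly$g$W1 <- crossprod(ly$.z, da1)
  dz <- da1 %*% t(ly$w$W1)
  fm_new(nn_scale_ch_bwd(dy, s, dz, ly$.hw), dfm$n, dfm$h, dfm$w)
}

#' @export
layer_count.cg_se <- function(ly, h, w) {
  C <- ly$ch
  r <- ly$reduced
  list(params = C * r + r + r * C + C, macs = as.double(C) * r * 2, h = h, w = w)
}

#' Adaptive ECA kernel size
#'
#' Resolves the 1-D convolution kernel size of efficient channel attention
#' from the channel count. The default `sqrt_odd` rule takes the nearest odd
#' integer to \eqn{\sqrt{C}} (ties resolved upward, minimum 1); `log2_odd`
#' is the conventional alternative \eqn{|log2(C)/2 + 1/2|_{odd}}.
#'
#' @param C number of channels (positive integer).
#' @param rule `"sqrt_odd"` (default) or `"log2_odd"`.
#' @return odd integer kernel size.
#' @examples
#' eca_kernel_size(9)   # 3
#' eca_kernel_size(64)  # 9 (sqrt = 8, equidistant odd neighbours, tie up)
#' @export
eca_kernel_size <- function(C, rule = c("sqrt_odd", "log2_odd")) {
  rule <- match.arg(rule)
  if (!is.numeric(C) || length(C) != 1L || C < 1)
    stop("C must be a positive integer channel count")
  r <- switch(rule, sqrt_odd = sqrt(C), log2_odd = log2(C) / 2 + 0.5)
  lo <- 2 * floor((r - 1) / 2) + 1
  hi <- lo + 2
  k <- if ((r - lo) < (hi - r)) lo else hi
  as.integer(max(1, k))
}

#' ECA configuration
#'
#' @param kernel_rule rule mapping channel count to the 1-D kernel size;
#'   see [eca_kernel_size()].
#' @param fixed_k optional odd integer overriding the rule.
#' @return an `eca_config` list.
#' @export
eca_config <- function(kernel_rule = c("sqrt_odd", "log2_odd"),
                       fixed_k = NULL) {
  kernel_rule <- match.arg(kernel_rule)
  if (!is.null(fixed_k)) {
    stopifnot(fixed_k >= 1, fixed_k %% 2 == 1)
    fixed_k <- as.integer(fixed_k)
  }
  structure(list(kernel_rule = kernel_rule, fixed_k = fixed_k),
            class = "eca_config")
}

eca_resolve_k <- function(C, cfg = eca_config()) {
  if (!is.null(cfg$fixed_k)) cfg$fixed_k else eca_kernel_size(C, cfg$kernel_rule)
}

eca_layer <- function(ch, k = NULL, cfg = eca_config(), name = "eca") {
  if (is.null(k)) k <- eca_resolve_k(ch, cfg)
  stopifnot(k %% 2 == 1, k >= 1)
  ly <- new_layer("eca", list(ch = ch, k = as.integer(k), name = name))
  ly$w$W <- numeric(k)  # zero init: gates start at 1/2, no bias by design
  ly
}

eca_conv1d <- function(z, w) {
  C <- ncol(z)
  k <- length(w)
  p <- (k - 1) %/% 2
  zp <- cbind(matrix(0, nrow(z), p), z, matrix(0, nrow(z), p))
  a <- matrix(0, nrow(z), C)
  for (j in seq_len(k)) a <- a + w[j] * zp[, j:(j + C - 1), drop = FALSE]
  a
}

#' @export
layer_fwd.cg_eca <- function(ly, fm, training = FALSE) {
  hw <- fm$h * fm$w
  z <- nn_gap(fm$x, fm$n, hw)
  a <- eca_conv1d(z, ly$w$W)
  s <- sigmoid(a)
  ly$.x <- fm$x
  ly$.z <- z
  ly$.s <- s
  ly$.hw <- hw
  fm_new(nn_scale_ch(fm$x, s, hw), fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_eca <- function(ly, dfm) {
  dy <- dfm$x
  s <- ly$.s
  z <- ly$.z
  k <- length(ly$w$W)
  C <- ncol(z)
  p <- (k - 1) %/% 2
  ds <- nn_scale_sum(ly$.x, dy, dfm$n, ly$.hw)
  da <- ds * s * (1 - s)
  zp <- cbind(matrix(0, nrow(z), p), z, matrix(0, nrow(z), p))
  dw <- numeric(k)
  for (j in seq_len(k)) dw[j] <- sum(da * zp[, j:(j + C - 1), drop = FALSE])
  ly$g$W <- dw
  dz <- eca_conv1d(da, rev(ly$w$W))  # correlation adjoint = flipped kernel
  fm_new(nn_scale_ch_bwd(dy, s, dz, ly$.hw), dfm$n, dfm$h, dfm$w)
}

#' @export
layer_count.cg_eca <- function(ly, h, w)
  list(params = length(ly$w$W), macs = as.double(length(ly$w$W)) * ly$ch,
       h = h, w = w)

# ---- functional forms on single feature maps ------------------------------

#' Feature map container
#'
#' A single C x H x W activation tensor, the object the attention and
#' Grad-CAM operations act on.
#'
#' @param values numeric array with dim `c(C, H, W)` and finite values.
#' @return a `feature_map` object.
#' @export
feature_map <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L)
    stop("values must be a C x H x W array")
  if (!all(is.finite(values))) stop("feature map values must be finite")
  structure(list(values = values, c = d[1], h = d[2], w = d[3]),
            class = "feature_map")
}

# (H*W, C) matrix view used by the batched layers; rows ordered y-major.
fmap_to_mat <- function(map) {
  v <- aperm(map$values, c(3, 2, 1))        # W x H x C
  matrix(v, map$h * map$w, map$c)
}

mat_to_fmap <- function(x, h, w) {
  v <- array(x, dim = c(w, h, ncol(x)))
  feature_map(aperm(v, c(3, 2, 1)))
}

#' Squeeze-and-excitation gating of a feature map
#'
#' Applies the standard SE construction (global average pool, bottleneck
#' MLP with Swish, sigmoid gates) to one feature map. With `weights = NULL`
#' all MLP weights and biases are zero, so every gate is `sigmoid(0) = 0.5`.
#'
#' @param map a [feature_map()].
#' @param reduce_ratio bottleneck ratio in (0, 1]; the reduced width is
#'   `max(1, round(C * reduce_ratio))`.
#' @param weights optional list with entries `W1` (C x r), `b1`, `W2`
#'   (r x C), `b2`.
#' @return a [feature_map()] of the same shape.
#' @export
squeeze_excite <- function(map, reduce_ratio = 0.25, weights = NULL) {
  stopifnot(inherits(map, "feature_map"))
  if (!is.numeric(reduce_ratio) || reduce_ratio <= 0 || reduce_ratio > 1)
    stop("reduce_ratio must be in (0, 1]")
  r <- max(1L, as.integer(round(map$c * reduce_ratio)))
  ly <- se_layer(map$c, r)
  if (is.null(weights)) {
    ly$w$W1[] <- 0
    ly$w$W2[] <- 0
  } else {
    for (nm in names(weights)) ly$w[[nm]] <- weights[[nm]]
  }
  out <- layer_fwd(ly, fm_new(fmap_to_mat(map), 1L, map$h, map$w))
  mat_to_fmap(out$x, map$h, map$w)
}

#' Efficient channel attention on a feature map
#'
#' @param map a [feature_map()].
#' @param cfg an [eca_config()].
#' @param weights optional numeric kernel (length = resolved kernel size);
#'   zero by default, giving gates of 0.5.
#' @return a [feature_map()] of the same shape.
#' @export
eca_apply <- function(map, cfg = eca_config(), weights = NULL) {
  stopifnot(inherits(map, "feature_map"))
  ly <- eca_layer(map$c, cfg = cfg)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(ly$w$W))
    ly$w$W <- as.numeric(weights)
  }
  out <- layer_fwd(ly, fm_new(fmap_to_mat(map), 1L, map$h, map$w))
  mat_to_fmap(out$x, map$h, map$w)
}
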