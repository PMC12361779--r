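# EfficientNet-B0 backbone: the tabulated nine-stage architecture with
# mobile inverted-bottleneck (MBConv) blocks, squeeze-and-excitation and
# Swish activation. Strides are derived from the printed resolution
# column (stem 2; MBConv stages 1,2,2,1,2,2,1), giving the per-stage
# input resolutions 224, 112, 112, 56, 28, 28, 14, 7, 7.

#' Stage description
#'
#' One row of the backbone architecture table.
#'
#' @param operator `"conv3x3"`, `"mbconv"` or `"head"`.
#' @param out_channels output channel count.
#' @param repeats number of blocks in the stage (stride applies to the
#'   first block only).
#' @param kernel odd depthwise kernel size.
#' @param expansion MBConv expansion factor, 1 or 6.
#' @param stride stride of the first block, 1 or 2.
#' @param input_resolution input resolution in pixels at the tabulated
#'   224 input (informational).
#' @return a `stage_spec` list.
#' @export
stage_spec <- function(operator, out_channels, repeats = 1L, kernel = 3L,
                       expansion = 1L, stride = 1L,
                       input_resolution = NA_integer_) {
  operator <- match.arg(operator, c("conv3x3", "mbconv", "head"))
  stopifnot(repeats >= 1, kernel %% 2 == 1, out_channels > 0,
            stride %in% c(1L, 2L))
  if (operator == "mbconv") stopifnot(expansion %in% c(1L, 6L))
  structure(list(operator = operator, out_channels = as.integer(out_channels),
                 repeats = as.integer(repeats), kernel = as.integer(kernel),
                 expansion = as.integer(expansion), stride = as.integer(stride),
                 input_resolution = as.integer(input_resolution)),
            class = "stage_spec")
}

#' Default B0 architecture
#'
#' Reproduces the printed nine-stage table: channels
#' (32,16,24,40,80,112,192,320,1280), repeats (1,1,2,2,3,3,4,1,1) and
#' kernels (3,3,3,5,3,5,5,3,1).
#'
#' @param num_classes classifier width (positive integer).
#' @param head_channels channels of the final 1x1 convolution.
#' @return an `architecture_spec`: list of [stage_spec()] rows plus the
#'   classifier settings.
#' @export
b0_architecture <- function(num_classes, head_channels = 1280L) {
  stopifnot(num_classes >= 2)
  stages <- list(
    stage_spec("conv3x3", 32, 1, 3, stride = 2, input_resolution = 224),
    stage_spec("mbconv", 16, 1, 3, expansion = 1, stride = 1,
               input_resolution = 112),
    stage_spec("mbconv", 24, 2, 3, expansion = 6, stride = 2,
               input_resolution = 112),
    stage_spec("mbconv", 40, 2, 5, expansion = 6, stride = 2,
               input_resolution = 56),
    stage_spec("mbconv", 80, 3, 3, expansion = 6, stride = 1,
               input_resolution = 28),
    stage_spec("mbconv", 112, 3, 5, expansion = 6, stride = 2,
               input_resolution = 28),
    stage_spec("mbconv", 192, 4, 5, expansion = 6, stride = 2,
               input_resolution = 14),
    stage_spec("mbconv", 320, 1, 3, expansion = 6, stride = 1,
               input_resolution = 7),
    stage_spec("head", head_channels, 1, 1, input_resolution = 7))
  structure(list(stages = stages, num_classes = as.integer(num_classes),
                 head_channels = as.integer(head_channels)),
            class = "architecture_spec")
}

# MBConv block: [1x1 expand (omitted when expansion = 1)] -> depthwise
# k x k (stride) -> SE -> 1x1 linear project; BN after each convolution,
# Swish after expand/depthwise; identity residual iff stride 1 and
# in == out. SE reduced width = round(0.25 * input channels), the
# original EfficientNet convention.

#' Build one MBConv block
#'
#' @param in_ch,out_ch input/output channels.
#' @param expansion 1 or 6.
#' @param kernel odd depthwise kernel size.
#' @param stride 1 or 2.
#' @param se_ratio SE bottleneck ratio relative to `in_ch` (0 disables SE).
#' @return a block layer usable inside a network.
#' @export
build_mbconv <- function(in_ch, out_ch, expansion, kernel, stride,
                         se_ratio = 0.25) {
  stopifnot(stride %in% c(1L, 2L), expansion %in% c(1L, 6L))
  if (kernel %% 2 == 0) stop("kernel must be odd")
  mid <- in_ch * expansion
  layers <- list()
  if (expansion > 1) {
    layers <- c(layers, list(
      conv_layer(in_ch, mid, 1, name = "expand"),
      bn_layer(mid, act = TRUE, name = "expand_bn")))
  }
  layers <- c(layers, list(
    dwconv_layer(mid, kernel, stride, name = "dw"),
    bn_layer(mid, act = TRUE, name = "dw_bn")))
  if (se_ratio > 0) {
    red <- max(1L, as.integer(round(in_ch * se_ratio)))
    layers <- c(layers, list(se_layer(mid, red)))
  }
  layers <- c(layers, list(
    conv_layer(mid, out_ch, 1, name = "project"),
    bn_layer(out_ch, name = "project_bn")))
  block_layer(layers, residual = (stride == 1L && in_ch == out_ch),
              kind = "mbconv")
}

block_builder_registry <- function(attention = "SE") {
  function(kind, in_ch, out_ch, expansion, kernel, stride) {
    switch(kind,
      mbconv = build_mbconv(in_ch, out_ch, expansion, kernel, stride),
      ghost = build_ghost_bottleneck(in_ch, out_ch, expansion, kernel,
                                     stride, attention = attention),
      stop("unknown block kind: ", kind))
  }
}

build_backbone <- function(spec, block_kinds = NULL, cpca_cfg = NULL,
                           attention = "ECA", dropout = 0.2,
                           ghost_cfg = ghost_config()) {
  stages <- spec$stages
  n_mb <- sum(vapply(stages, function(s) s$operator == "mbconv", logical(1)))
  if (is.null(block_kinds)) block_kinds <- rep("mbconv", n_mb)
  stopifnot(length(block_kinds) == n_mb)
  placement <- if (is.null(cpca_cfg)) character(0) else cpca_cfg$placement
  top <- list()
  in_ch <- 3L
  mb_i <- 0L
  for (s in stages) {
    if (s$operator == "conv3x3") {
      top <- c(top, list(seq_layer(list(
        conv_layer(in_ch, s$out_channels, s$kernel, s$stride, name = "conv"),
        bn_layer(s$out_channels, act = TRUE)), name = "stem")))
      in_ch <- s$out_channels
      if ("stem" %in% placement)
        top <- c(top, list(cpca_layer(cpca_cfg, ch = in_ch)))
    } else if (s$operator == "mbconv") {
      mb_i <- mb_i + 1L
      kind <- block_kinds[mb_i]
      blocks <- list()
      for (b in seq_len(s$repeats)) {
        bl <- if (kind == "mbconv") {
          build_mbconv(in_ch, s$out_channels, s$expansion, s$kernel,
                       if (b == 1L) s$stride else 1L)
        } else {
          build_ghost_bottleneck(in_ch, s$out_channels, s$expansion, s$kernel,
                                 if (b == 1L) s$stride else 1L,
                                 attention = attention, cfg = ghost_cfg)
        }
        blocks <- c(blocks, list(bl))
        in_ch <- s$out_channels
      }
      top <- c(top, list(seq_layer(blocks, name = paste0("stage", mb_i))))
      if (paste0("stage", mb_i) %in% placement)
        top <- c(top, list(cpca_layer(cpca_cfg, ch = in_ch)))
    } else {  # head
      if ("head" %in% placement)
        top <- c(top, list(cpca_layer(cpca_cfg, ch = in_ch)))
      top <- c(top, list(seq_layer(list(
        conv_layer(in_ch, s$out_channels, 1, name = "conv"),
        bn_layer(s$out_channels, act = TRUE)), name = "head")))
      in_ch <- s$out_channels
    }
  }
  top <- c(top, list(gap_layer(),
                     dropout_layer(dropout),
                     fc_layer(in_ch, spec$num_classes, name = "classifier")))
  model <- block_layer(top, residual = FALSE, kind = "model", name = "net")
  model$arch <- spec
  model$block_kinds <- block_kinds
  model$num_classes <- spec$num_classes
  model$cpca_cfg <- cpca_cfg
  assign_ids(model)
  model
}

#' Build the baseline EfficientNet-B0 classifier
#'
#' Stem (3x3 stride 2, 32 channels), seven MBConv stages, 1x1 head
#' convolution to 1280 channels, global average pooling, dropout and a
#' fully connected classifier.
#'
#' @param spec an [b0_architecture()] spec (or one with `num_classes` set).
#' @param num_classes convenience override; either `spec` or this must be
#'   given.
#' @param dropout dropout rate before the classifier.
#' @return a model object; pass to [forward_classify()], [count_params()],
#'   [fit()].
#' @examples
#' \donttest{
#' m <- build_efficientnet(num_classes = 60)
#' count_params(m)$params_M  # 4.08
#' }
#' @export
build_efficientnet <- function(spec = NULL, num_classes = NULL,
                               dropout = 0.2) {
  if (is.null(spec)) {
    stopifnot(!is.null(num_classes))
    spec <- b0_architecture(num_classes)
  }
  build_backbone(spec, dropout = dropout)
}

images_to_mat <- function(images) {
  # images: N x H x W x 3 array (or H x W x 3 for a single image)
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, c(1L, d))
    d <- dim(images)
  }
  if (d[4] != 3L) stop("images must have 3 channels, got ", d[4])
  n <- d[1]; h <- d[2]; w <- d[3]
  x <- matrix(aperm(images, c(3, 2, 1, 4)), n * h * w, 3L)
  fm_new(x, n, h, w)
}

#' Classify a batch of images
#'
#' Runs the network in evaluation mode and returns logits and softmax
#' probabilities (rows sum to 1).
#'
#' @param model a built model.
#' @param images N x H x W x 3 array of standardized inputs (a single
#'   H x W x 3 array is promoted to a batch of one).
#' @return list with `logits` (N x K), `probs` (N x K), `pred`
#'   (0-based predicted class ids).
#' @export
forward_classify <- function(model, images) {
  fm <- if (inherits(images, "feature_map")) {
    fm_new(fmap_to_mat(images), 1L, images$h, images$w)
  } else if (is.list(images)) {
    images
  } else {
    images_to_mat(images)
  }
  if (ncol(fm$x) != 3L)
    stop("input must be 3-channel, got ", ncol(fm$x), " channels")
  if (!all(is.finite(fm$x))) stop("input values must be finite")
  out <- layer_fwd(model, fm, training = FALSE)
  logits <- out$x
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, pred = max.col(probs) - 1L)
}
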