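# Grad-CAM: gradient-weighted class activation maps. Channel weights are
# the spatial means of the target-logit gradient at a convolutional
# feature map; the map is the ReLU of the weighted channel sum, bilinearly
# upsampled to the input and min-max normalized. Backpropagating the raw
# logit (not the softmax) makes the normalized heatmap invariant both to
# positive scaling of the target logit and to adding a constant to all
# logits.

spatial_leaf_ids <- function(model, input_hw) {
  leaves <- layer_leaves(model)
  h <- input_hw; w <- input_hw
  ids <- character(0)
  for (lf in leaves) {
    ct <- layer_count(lf, h, w)
    h <- ct$h; w <- ct$w
    if (ct$h > 1 || ct$w > 1) ids <- c(ids, lf$id)
  }
  ids
}

#' Grad-CAM heatmap
#'
#' @param model a built model.
#' @param image standardized input: a [feature_map()] with C = 3 or an
#'   H x W x 3 array (e.g. from [resize_and_normalize()]).
#' @param target_class 0-based class whose logit is explained.
#' @param layer id of the tapped layer (its output feature map is used);
#'   default is the activation of the final 1x1 head convolution, the
#'   last convolutional layer before pooling.
#' @return a `heatmap` list: `values` (H x W in `[0,1]` at input
#'   resolution), `raw` (low-resolution map before upsampling),
#'   `target_class`, `layer`, `all_zero` flag (raised when every channel
#'   weight kills the map under ReLU).
#' @export
gradcam_heatmap <- function(model, image, target_class, layer = NULL) {
  if (is.null(layer)) layer <- "net.head.bn"
  fm <- if (inherits(image, "feature_map")) {
    if (image$c != 3L) stop("expected a 3-channel input image")
    fm_new(fmap_to_mat(image), 1L, image$h, image$w)
  } else {
    images_to_mat(image)
  }
  tap <- find_layer(model, layer)
  if (is.null(tap))
    stop("no such layer: ", layer)
  leaves <- layer_leaves(model)
  ids <- vapply(leaves, function(l) l$id, character(1))
  pos <- match(layer, ids)
  if (is.na(pos))
    stop("layer must be a leaf layer; spatial candidates: ",
         paste(utils::tail(spatial_leaf_ids(model, fm$h), 8), collapse = ", "))
  nxt <- if (pos < length(leaves)) leaves[[pos + 1L]] else NULL
  if (is.null(nxt)) stop("cannot tap the final layer")
  nxt$.tap_in <- TRUE
  tap$.tap_dy <- TRUE
  on.exit({ nxt$.tap_in <- NULL; tap$.tap_dy <- NULL
            nxt$.tap_x <- NULL; tap$.tap_grad <- NULL })
  out <- layer_fwd(model, fm, training = FALSE)
  K <- ncol(out$x)
  if (target_class < 0 || target_class >= K)
    stop("target_class must lie in 0..", K - 1L)
  act <- nxt$.tap_x
  if (is.null(act) || (act$h == 1L && act$w == 1L))
    stop("layer has no spatial feature map; spatial candidates: ",
         paste(utils::tail(spatial_leaf_ids(model, fm$h), 8), collapse = ", "))
  dlog <- matrix(0, 1, K)
  dlog[1, target_class + 1L] <- 1
  layer_bwd(model, fm_new(dlog, 1L, 1L, 1L))
  grad <- tap$.tap_grad
  cam_from_parts(act$x, grad$x, act$h, act$w, fm$h, fm$w, target_class, layer)
}

cam_from_parts <- function(A, dA, h, w, out_h, out_w, target_class, layer) {
  wts <- colMeans(dA)
  v <- as.numeric(A %*% wts)
  v[v < 0] <- 0
  raw <- t(matrix(v, w, h))  # rows were y-major, x fastest
  up <- nn_resize_bilinear(array(raw, c(h, w, 1L)), h, w, 1L, out_h, out_w)
  up <- up[, , 1]
  rng <- range(up)
  all_zero <- rng[2] <= 0
  values <- if (all_zero) up * 0 else (up - rng[1]) / (rng[2] - rng[1])
  structure(list(values = values, raw = raw, channel_weights = wts,
                 target_class = as.integer(target_class), layer = layer,
                 all_zero = all_zero),
            class = "heatmap")
}

#' Grad-CAM from explicit maps and gradients
#'
#' The core arithmetic of Grad-CAM exposed for direct use: given a stack
#' of feature maps and the matching logit gradients, compute the
#' (optionally upsampled) normalized heatmap.
#'
#' @param maps feature maps as a C x H x W array.
#' @param grads gradients of the target logit w.r.t. `maps`, same shape.
#' @param out_hw optional output resolution for bilinear upsampling.
#' @return a `heatmap` (see [gradcam_heatmap()]).
#' @export
gradcam_from_maps <- function(maps, grads, out_hw = NULL) {
  stopifnot(identical(dim(maps), dim(grads)))
  d <- dim(maps)
  A <- matrix(aperm(maps, c(3, 2, 1)), d[2] * d[3], d[1])
  dA <- matrix(aperm(grads, c(3, 2, 1)), d[2] * d[3], d[1])
  oh <- if (is.null(out_hw)) d[2] else out_hw
  ow <- if (is.null(out_hw)) d[3] else out_hw
  cam_from_parts(A, dA, d[2], d[3], oh, ow, NA_integer_, NA_character_)
}

#' Write a Grad-CAM overlay image
#'
#' Renders the original image and a colormapped heatmap overlay
#' side-by-side as one PNG.
#'
#' @param heatmap a `heatmap` from [gradcam_heatmap()].
#' @param image the raw H x W x 3 image in `[0,1]`.
#' @param path output PNG path.
#' @param alpha overlay opacity.
#' @return `path`, invisibly.
#' @export
gradcam_overlay <- function(heatmap, image, path, alpha = 0.5) {
  d <- dim(image)
  hm <- heatmap$values
  stopifnot(all(dim(hm) == d[1:2]))
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255)
  idx <- pmin(255L, pmax(0L, as.integer(round(hm * 255)))) + 1L
  overlay <- image
  for (c in 1:3) {
    colc <- matrix(pal[idx, c], d[1], d[2])
    overlay[, , c] <- (1 - alpha) * image[, , c] + alpha * colc
  }
  side <- array(0, c(d[1], 2L * d[2], 3L))
  side[, seq_len(d[2]), ] <- image
  side[, d[2] + seq_len(d[2]), ] <- overlay
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(side, path)
  invisible(path)
}
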