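# Image-folder ingestion, resizing/standardization, the affine
# augmentation set (rotation, shifts, counterclockwise shear, scaling,
# flips) and stratified dataset splitting.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 2L) a else aperm(a, c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3), c(dim(img)[1:2], 3L))
  img
}

#' Index an image-folder dataset
#'
#' Expects one subdirectory per class, each holding at least one
#' JPEG/PNG image. Class ids are dense 0..K-1 in deterministic
#' alphabetical order of the directory names.
#'
#' @param root dataset root directory.
#' @param validate decode every file; unreadable files abort the load
#'   with their paths listed (nothing is silently dropped).
#' @return a `dataset_index` data.frame (path, class_id, class_name) with
#'   attributes `class_names` and `counts`.
#' @export
load_image_folder <- function(root, validate = TRUE) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(classes) == 0L) stop("no class subdirectories in ", root)
  recs <- list()
  for (i in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("class directory has no images: ", classes[i])
    recs[[i]] <- data.frame(path = files, class_id = i - 1L,
                            class_name = classes[i], stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, recs)
  if (validate) {
    bad <- character(0)
    for (p in idx$path) {
      ok <- tryCatch({ read_image_file(p); TRUE }, error = function(e) FALSE)
      if (!ok) bad <- c(bad, p)
    }
    if (length(bad))
      stop("unreadable image file(s): ", paste(bad, collapse = ", "))
  }
  structure(idx, class_names = classes,
            counts = as.integer(table(factor(idx$class_id,
                                             levels = seq_along(classes) - 1L))),
            class = c("dataset_index", "data.frame"))
}

#' Resize and standardize an image
#'
#' Bilinear resize to `size` x `size`, then channel standardization
#' `(x - mean)/sd` on the `[0,1]` intensities. Grayscale inputs are
#' promoted to 3 channels and alpha channels dropped at read time.
#'
#' @param image a file path or an H x W x 3 array in `[0,1]`.
#' @param size output resolution (default 224).
#' @param mean,sd per-channel standardization statistics (ImageNet
#'   defaults, matching transfer-learning practice).
#' @param normalize set FALSE to return the resized `[0,1]` image.
#' @return a [feature_map()] with C = 3, H = W = `size`.
#' @export
resize_and_normalize <- function(image, size = 224,
                                 mean = IMAGENET_MEAN, sd = IMAGENET_SD,
                                 normalize = TRUE) {
  img <- if (is.character(image)) read_image_file(image) else image
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 image")
  if (d[1] != size || d[2] != size)
    img <- nn_resize_bilinear(img, d[1], d[2], 3L, size, size)
  if (normalize)
    for (c in 1:3) img[, , c] <- (img[, , c] - mean[c]) / sd[c]
  feature_map(aperm(img, c(3, 1, 2)))
}

#' Augmentation configuration
#'
#' The augmentation set applied online during training: random rotation,
#' horizontal/vertical shifts, counterclockwise shear, random scaling and
#' random flips, composed into a single affine warp with nearest-edge
#' fill. Coordinate convention: image-centre origin, y-down axis,
#' counterclockwise angles positive.
#'
#' @param rotation_deg rotation sampled from `[-rotation_deg, rotation_deg]`.
#' @param shift_frac shifts sampled from `[-shift_frac, shift_frac]` of the
#'   image size, per axis; must lie in `[0, 1)`.
#' @param shear_deg shear angle range (counterclockwise positive).
#' @param zoom_range scaling factor bounds (positive pair).
#' @param hflip,vflip enable random horizontal/vertical flips.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_deg = 30, shift_frac = 0.1,
                                shear_deg = 10, zoom_range = c(0.9, 1.1),
                                hflip = TRUE, vflip = TRUE) {
  stopifnot(shift_frac >= 0, shift_frac < 1, all(zoom_range > 0),
            length(zoom_range) == 2L)
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 shear_deg = shear_deg, zoom_range = zoom_range,
                 hflip = hflip, vflip = vflip),
            class = "augmentation_config")
}

#' @rdname augment_image
#' @export
augment_draw <- function(cfg) {
  list(angle = stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg),
       shift = stats::runif(2, -cfg$shift_frac, cfg$shift_frac),
       shear = stats::runif(1, -cfg$shear_deg, cfg$shear_deg),
       zoom = stats::runif(1, cfg$zoom_range[1], cfg$zoom_range[2]),
       hflip = cfg$hflip && stats::runif(1) < 0.5,
       vflip = cfg$vflip && stats::runif(1) < 0.5)
}

#' Randomly augment an image
#'
#' Samples rotation/shift/shear/zoom/flip parameters (or takes a fixed
#' `draw`) and applies them as one composed affine transform with
#' bilinear interpolation and nearest-edge fill. Draws come from the R
#' RNG, so runs are reproducible under a seed.
#'
#' @param img H x W x 3 array in `[0,1]`.
#' @param cfg an [augmentation_config()].
#' @param draw optional fixed parameter draw from [augment_draw()].
#' @return augmented image, same shape.
#' @export
augment_image <- function(img, cfg = augmentation_config(), draw = NULL) {
  if (is.null(draw)) draw <- augment_draw(cfg)
  d <- dim(img)
  th <- draw$angle * pi / 180
  ph <- draw$shear * pi / 180
  # forward content maps in (y, x), y-down, counterclockwise positive
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, -tan(ph), 1), 2, 2)
  Z <- diag(c(draw$zoom, draw$zoom))
  Fl <- diag(c(if (draw$vflip) -1 else 1, if (draw$hflip) -1 else 1))
  M <- Fl %*% R %*% Sh %*% Z
  A <- solve(M)
  shift <- c(draw$shift[1] * d[1], draw$shift[2] * d[2])
  t_in <- as.numeric(-A %*% shift)
  nn_affine_warp(img, d[1], d[2], d[3], A, t_in)
}

#' Split specification
#'
#' @param train,val,test fractions summing to 1 (each > 0).
#' @param stratified preserve per-class proportions (within one item).
#' @param seed shuffle seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train = 0.6, val = 0.2, test = 0.2,
                       stratified = TRUE, seed = 1L) {
  f <- c(train = train, val = val, test = test)
  if (abs(sum(f) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (any(f <= 0)) stop("all split fractions must be positive")
  structure(list(fractions = f, stratified = stratified,
                 seed = as.integer(seed)), class = "split_spec")
}

largest_remainder <- function(n, fractions) {
  tgt <- n * fractions
  base <- floor(tgt)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(tgt - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Produces a disjoint, exhaustive partition; under stratification each
#' class's proportions deviate from the target fractions by at most one
#' item per split.
#'
#' @param index a `dataset_index` from [load_image_folder()] or
#'   [synth_generate()].
#' @param spec a [split_spec()].
#' @return named list of three `dataset_index` objects (train, val, test).
#' @export
split_dataset <- function(index, spec = split_spec()) {
  set.seed(spec$seed)
  groups <- if (spec$stratified) split(seq_len(nrow(index)), index$class_id)
            else list(seq_len(nrow(index)))
  take <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in groups) {
    if (spec$stratified && length(g) < 3L)
      stop("class too small to stratify (needs >= 3): ",
           index$class_name[g[1]])
    g <- sample(g)
    sizes <- largest_remainder(length(g), spec$fractions)
    ends <- cumsum(sizes)
    take$train <- c(take$train, g[seq_len(sizes[1])])
    if (sizes[2] > 0) take$val <- c(take$val, g[(ends[1] + 1):ends[2]])
    if (sizes[3] > 0) take$test <- c(take$test, g[(ends[2] + 1):ends[3]])
  }
  lapply(take, function(ix) {
    out <- index[sort(ix), , drop = FALSE]
    attributes(out)[c("class_names")] <- attributes(index)[c("class_names")]
    class(out) <- class(index)
    out
  })
}

#' Split an in-memory dataset tensor
#'
#' Stratified train/validation/test partition of a dataset tensor (see
#' [load_dataset_tensor()] / [synth_tensor()]), delegating to
#' [split_dataset()] on a synthetic index over the sample labels.
#'
#' @param tensor a dataset tensor.
#' @param spec a [split_spec()].
#' @return named list of three dataset tensors.
#' @export
split_tensor <- function(tensor, spec = split_spec()) {
  n <- length(tensor$labels)
  idx <- data.frame(path = sprintf("sample_%05d", seq_len(n)),
                    class_id = tensor$labels,
                    class_name = tensor$class_names[tensor$labels + 1L],
                    stringsAsFactors = FALSE)
  attr(idx, "class_names") <- tensor$class_names
  class(idx) <- c("dataset_index", "data.frame")
  sp <- split_dataset(idx, spec)
  lapply(sp, function(s) {
    rows <- as.integer(sub("sample_", "", s$path))
    list(images = tensor$images[rows, , , , drop = FALSE],
         labels = tensor$labels[rows], class_names = tensor$class_names)
  })
}

#' Resample a dataset tensor to a new resolution
#'
#' Bilinear per-image resize of a dataset tensor, used to run the same
#' image set at a reduced resolution.
#'
#' @param tensor a dataset tensor.
#' @param size target square resolution.
#' @return a dataset tensor at the new resolution.
#' @export
resize_tensor <- function(tensor, size) {
  d <- dim(tensor$images)
  if (d[2] == size && d[3] == size) return(tensor)
  out <- array(0, c(d[1], size, size, 3L))
  for (i in seq_len(d[1]))
    out[i, , , ] <- nn_resize_bilinear(array(tensor$images[i, , , ],
                                             d[2:4]),
                                       d[2], d[3], 3L, size, size)
  list(images = out, labels = tensor$labels,
       class_names = tensor$class_names)
}

#' Load a dataset into memory
#'
#' Reads every indexed image, optionally resizes, and returns the raw
#' `[0,1]` tensor used by [fit()] (standardization happens at batch
#' time so augmentation can act on intensities).
#'
#' @param index a `dataset_index`.
#' @param image_size optional target resolution.
#' @return list with `images` (N x H x W x 3), `labels` (0-based integer),
#'   `class_names`.
#' @export
load_dataset_tensor <- function(index, image_size = NULL) {
  n <- nrow(index)
  first <- read_image_file(index$path[1])
  size <- if (is.null(image_size)) dim(first)[1] else image_size
  images <- array(0, c(n, size, size, 3L))
  for (i in seq_len(n)) {
    img <- if (i == 1L) first else read_image_file(index$path[i])
    d <- dim(img)
    if (d[1] != size || d[2] != size)
      img <- nn_resize_bilinear(img, d[1], d[2], 3L, size, size)
    images[i, , , ] <- img
  }
  list(images = images, labels = as.integer(index$class_id),
       class_names = attr(index, "class_names"))
}
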