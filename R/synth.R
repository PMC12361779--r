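# Synthetic class-separable image generator. Each class is an oriented
# sinusoidal grating with a class-specific (orientation, spatial
# frequency, hue) triple; images differ within a class by a random
# grating phase and pixel noise. The class signal is deliberately strong
# and low-level — a stand-in fixture for offline testing, not a model of
# insect photographs (see the methods vignette for what this does and
# does not exercise).

#' Synthetic dataset specification
#'
#' @param n_classes number of classes; classes receive pairwise-distinct
#'   (orientation, frequency, hue) triples.
#' @param per_class images per class.
#' @param image_size square image resolution in pixels.
#' @param noise_sd Gaussian pixel-noise standard deviation on `[0,1]`
#'   intensities.
#' @param seed generation seed; regeneration under the same spec is
#'   byte-identical.
#' @return a `synth_spec` list including the per-class texture table.
#' @export
synth_spec <- function(n_classes = 8L, per_class = 200L, image_size = 96L,
                       noise_sd = 0.08, seed = 1L) {
  stopifnot(n_classes >= 2, per_class >= 1, image_size >= 16, noise_sd >= 0)
  i <- seq_len(n_classes) - 1L
  tex <- data.frame(
    class = i,
    orientation_deg = i * 180 / n_classes,
    frequency = c(4, 7, 10)[i %% 3L + 1L],
    hue = i / n_classes)
  structure(list(n_classes = as.integer(n_classes),
                 per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 textures = tex),
            class = "synth_spec")
}

synth_image <- function(tex, size, noise_sd) {
  th <- tex$orientation_deg * pi / 180
  phase <- stats::runif(1, 0, 2 * pi)
  u <- (seq_len(size) - 1) / size
  proj <- outer(u * sin(th), u * cos(th), `+`)        # y*sin + x*cos
  g <- 0.55 + 0.35 * sin(2 * pi * tex$frequency * proj + phase)
  base <- grDevices::col2rgb(grDevices::hsv(tex$hue, 0.8, 1))[, 1] / 255
  img <- array(0, c(size, size, 3L))
  for (c in 1:3) img[, , c] <- base[c] * g
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic image-folder dataset
#'
#' Writes one PNG folder per class and returns the dataset index.
#' Deterministic under `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @param outdir output directory (one subdirectory per class).
#' @param overwrite allow writing into an existing non-empty `outdir`.
#' @return a `dataset_index` over the generated files.
#' @export
synth_generate <- function(spec = synth_spec(), outdir,
                           overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", outdir,
         " (use overwrite = TRUE)")
  set.seed(spec$seed)
  for (i in seq_len(spec$n_classes)) {
    cls <- sprintf("class_%02d", i - 1L)
    dir.create(file.path(outdir, cls), recursive = TRUE,
               showWarnings = FALSE)
    tex <- spec$textures[i, ]
    for (j in seq_len(spec$per_class)) {
      img <- synth_image(tex, spec$image_size, spec$noise_sd)
      png::writePNG(img, file.path(outdir, cls, sprintf("img_%04d.png", j)))
    }
  }
  load_image_folder(outdir, validate = FALSE)
}

#' In-memory synthetic dataset
#'
#' Generates the same images as [synth_generate()] without touching disk
#' (modulo PNG 8-bit quantization), as a dataset tensor for [fit()].
#'
#' @param spec a [synth_spec()].
#' @return list with `images`, `labels`, `class_names` (see
#'   [load_dataset_tensor()]).
#' @export
synth_tensor <- function(spec = synth_spec()) {
  set.seed(spec$seed)
  n <- spec$n_classes * spec$per_class
  images <- array(0, c(n, spec$image_size, spec$image_size, 3L))
  labels <- integer(n)
  r <- 0L
  for (i in seq_len(spec$n_classes)) {
    tex <- spec$textures[i, ]
    for (j in seq_len(spec$per_class)) {
      r <- r + 1L
      images[r, , , ] <- synth_image(tex, spec$image_size, spec$noise_sd)
      labels[r] <- i - 1L
    }
  }
  list(images = images, labels = labels,
       class_names = sprintf("class_%02d", seq_len(spec$n_classes) - 1L))
}

#' Fourier-energy class margin of a synthetic dataset
#'
#' Diagnostic for the separability guarantee: projects every image onto
#' its class's generating grating direction/frequency (a Fourier-energy
#' feature) and returns the margin between within-class and
#' cross-class energies; positive margins mean the classes are linearly
#' separable in these features.
#'
#' @param tensor a dataset tensor from [synth_tensor()].
#' @param spec the generating [synth_spec()].
#' @return minimum over images of (own-class energy - best other-class
#'   energy), after per-feature standardization.
#' @export
synth_margin <- function(tensor, spec) {
  size <- spec$image_size
  u <- (seq_len(size) - 1) / size
  K <- spec$n_classes
  n <- dim(tensor$images)[1]
  feats <- matrix(0, n, K)
  base <- vapply(seq_len(K), function(i)
    grDevices::col2rgb(grDevices::hsv(spec$textures$hue[i], 0.8, 1))[, 1] / 255,
    numeric(3))
  for (kk in seq_len(K)) {
    th <- spec$textures$orientation_deg[kk] * pi / 180
    f <- spec$textures$frequency[kk]
    proj <- outer(u * sin(th), u * cos(th), `+`)
    cw <- cos(2 * pi * f * proj)
    sw <- sin(2 * pi * f * proj)
    for (i in seq_len(n)) {
      lum <- tensor$images[i, , , 1] * base[1, kk] +
             tensor$images[i, , , 2] * base[2, kk] +
             tensor$images[i, , , 3] * base[3, kk]
      feats[i, kk] <- sqrt(sum(lum * cw)^2 + sum(lum * sw)^2) / length(lum)
    }
  }
  feats <- scale(feats)
  own <- feats[cbind(seq_len(n), tensor$labels + 1L)]
  other <- vapply(seq_len(n), function(i)
    max(feats[i, -(tensor$labels[i] + 1L)]), numeric(1))
  min(own - other)
}
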