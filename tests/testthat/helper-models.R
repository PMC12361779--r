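# Shared fixtures: tiny models and tensors built in code.

tiny_model <- function(num_classes = 3L, in_ch = 3L, width = 8L) {
  net <- cgenet:::block_layer(list(
    cgenet:::seq_layer(list(
      cgenet:::conv_layer(in_ch, width, 3, 2, name = "conv"),
      cgenet:::bn_layer(width, act = TRUE)), name = "stem"),
    cgenet:::gap_layer(),
    cgenet:::fc_layer(width, num_classes, name = "classifier")),
    kind = "model", name = "net")
  net$num_classes <- num_classes
  net$block_kinds <- character(0)
  cgenet:::assign_ids(net)
  net
}

random_fm <- function(n, h, w, c = 3L) {
  cgenet:::fm_new(matrix(stats::rnorm(n * h * w * c), n * h * w, c),
                  as.integer(n), as.integer(h), as.integer(w))
}

random_map <- function(C, H, W) feature_map(array(stats::rnorm(C * H * W),
                                                  c(C, H, W)))

# numeric loss + gradient used by gradient-check tests
ce_loss <- function(model, fm, y, training = TRUE) {
  out <- layer_fwd(model, fm, training)
  sc <- cgenet:::softmax_ce(out$x, y)
  list(loss = sc$loss, dlogits = sc$grad)
}

# 2-class linearly separable mini image set: left-bright vs right-bright
two_class_tensor <- function(n_per = 20L, size = 16L, seed = 5L) {
  set.seed(seed)
  n <- 2L * n_per
  images <- array(stats::runif(n * size * size * 3, 0, 0.2),
                  c(n, size, size, 3L))
  labels <- rep(0:1, each = n_per)
  half <- seq_len(size %/% 2)
  for (i in seq_len(n)) {
    cols <- if (labels[i] == 0) half else size %/% 2 + half
    images[i, , cols, ] <- images[i, , cols, ] + 0.7
  }
  list(images = images, labels = labels, class_names = c("left", "right"))
}
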