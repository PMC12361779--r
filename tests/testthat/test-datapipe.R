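make_folder_fixture <- function(root, classes = 3L, per = 2L, size = 8L) {
  set.seed(61)
  for (i in seq_len(classes)) {
    d <- file.path(root, sprintf("genus_%02d", i))
    dir.create(d, recursive = TRUE)
    for (j in seq_len(per))
      png::writePNG(array(stats::runif(size * size * 3), c(size, size, 3)),
                    file.path(d, sprintf("im%d.png", j)))
  }
}

test_that("image-folder indexing is deterministic and validated", {
  root <- withr::local_tempdir()
  make_folder_fixture(root)
  idx <- load_image_folder(root)
  expect_identical(nrow(idx), 6L)
  expect_identical(attr(idx, "class_names"),
                   sprintf("genus_%02d", 1:3))
  expect_identical(sort(unique(idx$class_id)), 0:2)
  # empty class directory is an error naming the class
  dir.create(file.path(root, "aaa_empty"))
  expect_error(load_image_folder(root), "aaa_empty")
  unlink(file.path(root, "aaa_empty"), recursive = TRUE)
  # unreadable file fails the load with its path
  bad <- file.path(root, "genus_01", "broken.png")
  writeLines("not a png", bad)
  expect_error(load_image_folder(root), "broken.png")
})

test_that("resize-and-normalize follows the documented arithmetic", {
  img <- array(0.5, c(20, 20, 3))
  out <- resize_and_normalize(img, size = 10)
  expect_identical(c(out$c, out$h, out$w), c(3L, 10L, 10L))
  for (c in 1:3)
    expect_equal(unique(as.vector(out$values[c, , ])),
                 (0.5 - cgenet:::IMAGENET_MEAN[c]) / cgenet:::IMAGENET_SD[c],
                 tolerance = 1e-12)
  # resizing at the native size is a shape no-op and value-preserving
  same <- resize_and_normalize(img, size = 20, normalize = FALSE)
  expect_equal(same$values[1, , ], img[, , 1])
  # halving a 448-type input
  big <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(resize_and_normalize(big, 8)$h, 8L)
})

test_that("identity augmentation changes nothing beyond interpolation", {
  set.seed(62)
  img <- array(stats::runif(12 * 12 * 3), c(12, 12, 3))
  cfg <- augmentation_config(rotation_deg = 0, shift_frac = 0,
                             shear_deg = 0, zoom_range = c(1, 1),
                             hflip = FALSE, vflip = FALSE)
  out <- augment_image(img, cfg)
  expect_equal(out, img, tolerance = 1e-6)
})

test_that("a pure 90-degree rotation lands the hot pixel where expected", {
  # one-hot pixel, odd size so the centre is a pixel; CCW positive angles,
  # y-down, centre origin: forward map (y,x) -> (y cos - x sin, y sin + x cos)
  size <- 9L
  img <- array(0, c(size, size, 3))
  img[3, 7, ] <- 1            # offset (dy, dx) = (-2, +2) from centre (5,5)
  draw <- list(angle = 90, shift = c(0, 0), shear = 0, zoom = 1,
               hflip = FALSE, vflip = FALSE)
  out <- augment_image(img, draw = draw)
  # (dy,dx) = (-2, 2) rotated CCW 90: (y' , x') = (-x, y) = (-2, -2)
  expect_equal(out[3, 3, 1], 1, tolerance = 1e-6)
  expect_lt(out[3, 7, 1], 0.5)
})

test_that("augmentation draws are reproducible under a seed", {
  img <- array(stats::runif(10 * 10 * 3), c(10, 10, 3))
  set.seed(63); a <- augment_image(img)
  set.seed(63); b <- augment_image(img)
  expect_identical(a, b)
})

test_that("splits partition the data with stratification within one item", {
  set.seed(64)
  idx <- data.frame(path = sprintf("p%03d", 1:100),
                    class_id = rep(0:1, each = 50),
                    class_name = rep(c("a", "b"), each = 50))
  attr(idx, "class_names") <- c("a", "b")
  class(idx) <- c("dataset_index", "data.frame")
  sp <- split_dataset(idx, split_spec(0.6, 0.2, 0.2, seed = 2))
  expect_identical(vapply(sp, nrow, integer(1)),
                   c(train = 60L, val = 20L, test = 20L))
  for (s in sp)
    expect_true(all(abs(table(s$class_id) - nrow(s) / 2) <= 1))
  all_paths <- sort(c(sp$train$path, sp$val$path, sp$test$path))
  expect_identical(all_paths, sort(idx$path))
  expect_length(intersect(sp$train$path, sp$val$path), 0)
  expect_length(intersect(sp$train$path, sp$test$path), 0)
  # class too small to stratify is a named error
  small <- idx[c(1:2, 51:99), ]
  attr(small, "class_names") <- c("a", "b")
  class(small) <- class(idx)
  expect_error(split_dataset(small, split_spec()), "a")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("split proportions hold across uneven class sizes", {
  set.seed(65)
  sizes <- c(7, 13, 29)
  idx <- data.frame(path = sprintf("q%03d", seq_len(sum(sizes))),
                    class_id = rep(0:2, times = sizes),
                    class_name = rep(c("a", "b", "c"), times = sizes))
  attr(idx, "class_names") <- c("a", "b", "c")
  class(idx) <- c("dataset_index", "data.frame")
  sp <- split_dataset(idx, split_spec(0.7, 0.2, 0.1, seed = 3))
  expect_equal(sum(vapply(sp, nrow, integer(1))), sum(sizes))
  for (ci in 0:2) {
    n_c <- sizes[ci + 1]
    got <- vapply(sp, function(s) sum(s$class_id == ci), integer(1))
    expect_true(all(abs(got - n_c * c(0.7, 0.2, 0.1)) <= 1))
  }
})
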