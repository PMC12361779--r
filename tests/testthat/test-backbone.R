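test_that("swish matches its closed form and asymptotes", {
  expect_identical(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(swish(100), 100, tolerance = 1e-6)
  x <- seq(-6, 6, by = 0.37)
  expect_equal(swish(x), x * (1 / (1 + exp(-x))), tolerance = 1e-12)
  # non-monotone below zero
  expect_true(swish(-1) < swish(-0.1) && swish(-5) > swish(-1.278))
})

test_that("squeeze-excite obeys its gating contract", {
  set.seed(1)
  map <- random_map(4, 3, 3)
  # zero-initialized SE gates every channel by sigmoid(0) = 0.5
  out <- squeeze_excite(map)
  expect_equal(out$values, map$values * 0.5, tolerance = 1e-12)
  # all-zero map stays zero for any weights
  z <- feature_map(array(0, c(4, 3, 3)))
  wts <- list(W1 = matrix(rnorm(4), 4, 1), b1 = 0.3,
              W2 = matrix(rnorm(4), 1, 4), b2 = rnorm(4))
  expect_equal(squeeze_excite(z, weights = wts)$values, z$values)
  expect_error(squeeze_excite(map, reduce_ratio = 0), "reduce_ratio")
})

test_that("squeeze-excite matches a hand-computed scalar chain", {
  # 2-channel 1x1 map, 1-unit bottleneck, hand-set weights
  map <- feature_map(array(c(2, -1), c(2, 1, 1)))
  wts <- list(W1 = matrix(c(0.5, -0.25), 2, 1), b1 = 0.1,
              W2 = matrix(c(1, -2), 1, 2), b2 = c(0, 0.2))
  z <- c(2, -1)                       # GAP of 1x1 map
  a1 <- sum(z * wts$W1) + wts$b1      # 1.35
  h1 <- a1 * plogis(a1)
  a2 <- h1 * wts$W2[1, ] + wts$b2
  s <- plogis(a2)
  out <- squeeze_excite(map, reduce_ratio = 0.5, weights = wts)
  expect_equal(as.numeric(out$values), z * s, tolerance = 1e-12)
})

test_that("MBConv blocks follow the bottleneck contract", {
  set.seed(2)
  # expansion 1: no expand convolution in the layer list
  b1 <- build_mbconv(32, 16, 1, 3, 1)
  kinds <- vapply(b1$children, function(l) l$name, character(1))
  expect_false(any(grepl("expand", kinds)))
  expect_false(b1$residual)  # 32 != 16
  # residual active iff stride 1 and in == out: output - inner(x) = x
  b2 <- build_mbconv(40, 40, 6, 3, 1)
  expect_true(b2$residual)
  fm <- random_fm(2, 6, 6, 40)
  out <- layer_fwd(b2, fm, training = FALSE)
  b2$residual <- FALSE
  inner <- layer_fwd(b2, fm, training = FALSE)
  expect_equal(out$x - inner$x, fm$x, tolerance = 1e-12)
  expect_error(build_mbconv(16, 24, 6, 4, 1), "odd")
})

test_that("MBConv parameter count matches per-layer arithmetic", {
  set.seed(3)
  b <- build_mbconv(16, 24, 6, 3, 2, se_ratio = 0.25)
  # expand 16*96, dw 96*9, SE 96*4+4 + 4*96+96, project 96*24,
  # BN affine 2*(96+96+24) = 432 -> 6004
  total <- sum(vapply(cgenet:::layer_leaves(b), function(l)
    sum(lengths(l$w)), numeric(1)))
  expect_identical(as.integer(total), 6004L)
})

test_that("the default architecture reproduces the printed stage table", {
  spec <- b0_architecture(60)
  ch <- vapply(spec$stages, function(s) s$out_channels, integer(1))
  expect_identical(ch, c(32L, 16L, 24L, 40L, 80L, 112L, 192L, 320L, 1280L))
  reps <- vapply(spec$stages, function(s) s$repeats, integer(1))
  expect_identical(reps, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 1L, 1L))
  ker <- vapply(spec$stages, function(s) s$kernel, integer(1))
  expect_identical(ker, c(3L, 3L, 3L, 5L, 3L, 5L, 5L, 3L, 1L))
  res <- vapply(spec$stages, function(s) s$input_resolution, integer(1))
  expect_identical(res, c(224L, 112L, 112L, 56L, 28L, 28L, 14L, 7L, 7L))
})

test_that("spatial resolutions chain through the stages as tabulated", {
  set.seed(4)
  m <- build_efficientnet(num_classes = 5)
  prof <- model_profile(m, 224)
  sections <- prof$section
  outs <- prof$out_h
  # after stem and each MBConv stage: 112,112,56,28,28,14,7,7, head 7
  expect_identical(outs[sections == "stem"], 112L)
  stage_out <- outs[grepl("^stage", sections)]
  expect_identical(stage_out, c(112L, 56L, 28L, 28L, 14L, 7L, 7L))
  expect_identical(outs[sections == "head"], 7L)
})

test_that("baseline forward produces calibrated class probabilities", {
  set.seed(5)
  m <- tiny_model(num_classes = 4)
  imgs <- array(stats::runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  # duplicate image in the batch -> identical rows in eval mode
  imgs[2, , , ] <- imgs[1, , , ]
  out <- forward_classify(m, imgs)
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
  expect_equal(out$probs[1, ], out$probs[2, ], tolerance = 1e-12)
  expect_error(forward_classify(m, array(1, c(2, 8, 8, 4))), "3 channels")
  # all-equal logits give the uniform distribution
  probs <- exp(rep(0, 4)) / sum(exp(rep(0, 4)))
  expect_equal(probs, rep(1 / 4, 4))
})

test_that("parameter count is invariant to input content and repetition", {
  set.seed(6)
  m <- tiny_model()
  p1 <- count_params(m)
  invisible(layer_fwd(m, random_fm(2, 16, 16), training = TRUE))
  p2 <- count_params(m)
  expect_identical(p1$params_exact, p2$params_exact)
})
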