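# Independent oracle: explicit loops over the four one-vs-rest counts.
brute_macro <- function(M) {
  K <- nrow(M)
  N <- sum(M)
  acc <- prec <- rec <- f1 <- numeric(K)
  for (i in seq_len(K)) {
    tp <- M[i, i]
    fp <- sum(M[, i]) - tp
    fn <- sum(M[i, ]) - tp
    tn <- N - tp - fp - fn
    acc[i] <- (tp + tn) / N
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(acc = mean(acc), prec = mean(prec), rec = mean(rec), f1 = mean(f1))
}

test_that("confusion matrices count labels exactly", {
  # perfect predictions give a diagonal matrix
  y <- c(0, 1, 2, 1, 0)
  expect_identical(confusion_matrix(y, y, 3), diag(c(2L, 2L, 1L)))
  # the worked example
  M <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_identical(M, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 2), "out of range")
})

test_that("the worked confusion matrix yields the hand-derived macros", {
  M <- matrix(c(1L, 0L, 1L, 2L), 2, 2)  # rows true: [[1,1],[0,2]]
  mm <- macro_metrics(M)
  expect_equal(mm$per_class$prec, c(1, 2 / 3))
  expect_equal(mm$per_class$rec, c(1 / 2, 1))
  expect_equal(mm$per_class$acc, c(3 / 4, 3 / 4))
  expect_equal(mm$per_class$f1, c(2 / 3, 4 / 5))
  expect_equal(mm$macro$acc, 3 / 4)
  expect_equal(mm$macro$prec, 5 / 6)
  expect_equal(mm$macro$rec, 3 / 4)
  expect_equal(mm$macro$f1, 11 / 15)
})

test_that("macro metrics equal the explicit-loop oracle on random matrices", {
  set.seed(81)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    M <- matrix(rpois(K * K, 3), K, K)
    mm <- macro_metrics(M)
    bb <- brute_macro(M)
    expect_identical(mm$macro$acc, bb$acc)
    expect_identical(mm$macro$prec, bb$prec)
    expect_identical(mm$macro$rec, bb$rec)
    expect_identical(mm$macro$f1, bb$f1)
  }
})

test_that("diagonal matrices score 1 and silent classes flag zero division", {
  mm <- macro_metrics(diag(c(5L, 3L, 2L)))
  expect_equal(unlist(mm$macro), c(acc = 1, prec = 1, rec = 1, f1 = 1))
  # a class never predicted and never true contributes 0 with a flag
  M <- matrix(0L, 3, 3)
  M[1, 1] <- 4L; M[2, 2] <- 4L   # class 2 silent
  mm2 <- macro_metrics(M)
  expect_true(mm2$zero_division[3])
  expect_equal(mm2$per_class$prec[3], 0)
})

test_that("permuting class order permutes per-class but fixes macros", {
  set.seed(82)
  M <- matrix(rpois(16, 4), 4, 4)
  p <- sample(4)
  mm <- macro_metrics(M)
  mp <- macro_metrics(M[p, p])
  expect_equal(mp$macro, mm$macro)
  expect_equal(mp$per_class$prec, mm$per_class$prec[p])
})

test_that("accuracy can sit far above precision on many-class errors", {
  # 60-class fixture with ~10% scattered errors: one-vs-rest accuracy
  # stays above 99% while macro precision drops below 95%
  set.seed(83)
  K <- 60L
  n_per <- 20L
  true <- rep(0:(K - 1L), each = n_per)
  pred <- true
  flip <- sample(length(true), round(0.1 * length(true)))
  pred[flip] <- (true[flip] + sample(1:(K - 1L), length(flip),
                                     replace = TRUE)) %% K
  mm <- macro_metrics(confusion_matrix(true, pred, K))
  expect_gt(mm$macro$acc, 0.99)
  expect_lt(mm$macro$prec, 0.95)
})

test_that("confusion heatmaps render row-normalized PNG cells", {
  dir <- withr::local_tempdir()
  M <- matrix(c(8L, 2L, 0L, 10L), 2, 2, byrow = TRUE)
  p <- confusion_heatmap(M, file.path(dir, "cm.png"), cell = 4L)
  img <- png::readPNG(p)
  expect_identical(dim(img)[1:2], c(8L, 8L))
  # the saturated diagonal cell and the empty cell map to palette extremes
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255)
  expect_equal(as.numeric(img[6, 2, ]), unname(pal[1, ]), tolerance = 1 / 255)
  expect_equal(as.numeric(img[6, 6, ]), unname(pal[256, ]), tolerance = 1 / 255)
})

test_that("the paired t helper matches hand arithmetic", {
  d <- c(0.12, 0.13, 0.12, 0.14, 0.12)
  pt <- cgenet:::paired_diff_test(d)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pt$t, t_hand, tolerance = 1e-9)
  expect_equal(pt$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-9)
  expect_identical(pt$df, 4L)
  # zero-variance branches
  expect_equal(cgenet:::paired_diff_test(rep(0, 5))$p_value, 1)
  z <- cgenet:::paired_diff_test(rep(0.1, 5))
  expect_true(z$degenerate && z$p_value < 1e-12)
})

test_that("k-fold comparison is paired, partitioned and self-consistent", {
  set.seed(84)
  n <- 60
  y <- rep(0:2, each = 20)
  x <- matrix(rnorm(n * 4), n, 4) + 2 * y  # class-shifted features
  # deterministic centroid classifier builder
  centroid_builder <- function(x_tr, y_tr, fold_seed) {
    mus <- lapply(sort(unique(y_tr)), function(k)
      colMeans(x_tr[y_tr == k, , drop = FALSE]))
    function(x_new) {
      d <- vapply(mus, function(mu)
        rowSums((x_new - matrix(mu, nrow(x_new), 4, byrow = TRUE))^2),
        numeric(nrow(x_new)))
      max.col(-d) - 1L
    }
  }
  res <- kfold_compare(centroid_builder, centroid_builder, x, y, k = 5,
                       seed = 2)
  # identical builders: all-zero differences and p = 1
  expect_true(all(res$diffs == 0))
  expect_equal(res$p_value, 1)
  # folds partition the data
  expect_identical(sort(unique(res$folds)), 1:5)
  expect_equal(length(res$folds), n)
  # against a majority-class builder the centroid model wins
  majority_builder <- function(x_tr, y_tr, fold_seed) {
    mode <- as.integer(names(which.max(table(y_tr))))
    function(x_new) rep(mode, nrow(x_new))
  }
  res2 <- kfold_compare(centroid_builder, majority_builder, x, y, k = 5,
                        seed = 2)
  expect_gt(res2$mean_diff, 0)
  # the reported t/p match the helper on its own differences
  pt <- cgenet:::paired_diff_test(res2$diffs)
  expect_equal(res2$t, pt$t)
  expect_equal(res2$p_value, pt$p_value)
})
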