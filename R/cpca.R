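# Channel-wise principal-component attention (CPCA).
#
# Each channel of a C x H x W feature map is flattened to a row of a
# C x (H*W) matrix X. The C x C channel covariance
#   S = (X - means)(X - means)' / (H*W - 1)
# is eigendecomposed and the channels are projected onto the top-k
# principal channel directions. In the default shape-preserving mode the
# map is reconstructed from the rank-k projection, so the stage is a
# parameter-free, drop-in attention refinement; the compressing mode
# returns the k score maps themselves. As printed, the covariance formula
# has shape (H*W) x (H*W); the stated C x C output dimensionality is taken
# as authoritative, so the C x C centred form is implemented.

#' CPCA configuration
#'
#' @param k_mode `"variance_fraction"` (default) resolves k as the smallest
#'   number of components whose cumulative eigenvalue fraction reaches
#'   `k_value`; `"fixed"` uses `k_value` directly.
#' @param k_value fraction in (0, 1] or a fixed positive integer.
#' @param output_mode `"reconstruct_C"` (default, shape-preserving rank-k
#'   reconstruction) or `"compress_k"` (returns the k score maps).
#' @param placement character vector of insertion points in a host network:
#'   `"stem"` (after the stem, default), `"stage<i>"` (after MBConv stage i)
#'   or `"head"` (before the head convolution); empty vector for none.
#' @return a `cpca_config` list.
#' @export
cpca_config <- function(k_mode = c("variance_fraction", "fixed"),
                        k_value = 0.95,
                        output_mode = c("reconstruct_C", "compress_k"),
                        placement = "stem") {
  k_mode <- match.arg(k_mode)
  output_mode <- match.arg(output_mode)
  if (k_mode == "variance_fraction") {
    if (!(k_value > 0 && k_value <= 1))
      stop("k_value must be a fraction in (0, 1] for variance_fraction mode")
  } else {
    if (k_value < 1 || k_value != round(k_value))
      stop("k_value must be a positive integer for fixed mode")
    k_value <- as.integer(k_value)
  }
  ok <- placement %in% c("stem", "head", paste0("stage", 1:7))
  if (!all(ok)) stop("unknown placement: ", paste(placement[!ok], collapse = ", "))
  structure(list(k_mode = k_mode, k_value = k_value,
                 output_mode = output_mode, placement = placement),
            class = "cpca_config")
}

#' Flatten a feature map into its channel matrix
#'
#' Row i of the result is channel i of the map flattened row-major; the
#' per-channel means are recorded and the operation is lossless (see
#' [unflatten_channels()]).
#'
#' @param map a [feature_map()].
#' @return a `channel_matrix`: list with `X` (C x H*W), `means` (length C),
#'   `h`, `w`, and `zero_var` flagging constant rows.
#' @export
flatten_channels <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  X <- matrix(aperm(map$values, c(1, 3, 2)), map$c, map$h * map$w)
  means <- rowMeans(X)
  v <- rowMeans(X * X) - means^2
  structure(list(X = X, means = means, h = map$h, w = map$w,
                 zero_var = v <= 1e-12 * max(1, max(abs(X)))^2),
            class = "channel_matrix")
}

#' Reassemble a feature map from a channel matrix
#'
#' @param cm a `channel_matrix` from [flatten_channels()], optionally with a
#'   replaced `X`.
#' @param X optional C x (H*W) matrix overriding `cm$X`.
#' @return a [feature_map()].
#' @export
unflatten_channels <- function(cm, X = NULL) {
  if (is.null(X)) X <- cm$X
  a <- array(X, dim = c(nrow(X), cm$w, cm$h))
  feature_map(aperm(a, c(1, 3, 2)))
}

#' Channel covariance of a flattened feature map
#'
#' Computes the C x C covariance `(X - means)(X - means)' / (H*W - 1)`
#' describing the correlation structure between channels.
#'
#' @param cm a `channel_matrix` from [flatten_channels()].
#' @return symmetric positive semi-definite C x C matrix.
#' @export
channel_covariance <- function(cm) {
  stopifnot(inherits(cm, "channel_matrix"))
  m <- ncol(cm$X)
  if (m < 2) stop("channel covariance undefined for H*W = 1")
  Xc <- cm$X - cm$means
  S <- tcrossprod(Xc) / (m - 1)
  (S + t(S)) / 2
}

#' Principal subspace of a channel covariance
#'
#' Eigendecomposes a symmetric PSD channel covariance, orders the
#' eigensystem by descending eigenvalue, applies a deterministic sign
#' convention (the largest-magnitude component of each eigenvector is
#' positive) and resolves the retained dimension k.
#'
#' @param S symmetric C x C covariance matrix.
#' @param cfg a [cpca_config()].
#' @return list with `values` (descending eigenvalues), `vectors`
#'   (orthonormal C x C), `k`, and `Vk` (C x k).
#' @export
principal_subspace <- function(S, cfg = cpca_config()) {
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8 * max(1, max(abs(S))))
    stop(sprintf("covariance must be symmetric (max asymmetry %.3g)", asym))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  C <- nrow(S)
  k <- if (cfg$k_mode == "fixed") {
    min(as.integer(cfg$k_value), C)
  } else {
    tot <- sum(vals)
    if (tot <= 0) 1L
    else as.integer(which(cumsum(vals) / tot >= cfg$k_value - 1e-12)[1])
  }
  list(values = vals, vectors = V, k = k, Vk = V[, seq_len(k), drop = FALSE])
}

#' Apply CPCA to a feature map
#'
#' Projects the centred channels onto the top-k principal channel
#' directions. In `reconstruct_C` mode the map is rebuilt from the rank-k
#' projection (same shape as the input, zero learned parameters); in
#' `compress_k` mode the k score maps are returned.
#'
#' @param map a [feature_map()].
#' @param cfg a [cpca_config()].
#' @return a [feature_map()] with attributes `k` (resolved k) and
#'   `degenerate` (TRUE when an all-constant map was returned unchanged).
#' @export
cpca_apply <- function(map, cfg = cpca_config()) {
  cm <- flatten_channels(map)
  if (all(cm$zero_var)) {
    if (cfg$output_mode == "compress_k") {
      warning("all-constant feature map: returning first channel as scores")
      out <- unflatten_channels(cm, cm$X[1, , drop = FALSE] * 0)
    } else {
      warning("all-constant feature map: CPCA returned it unchanged")
      out <- map
    }
    attr(out, "k") <- 1L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  S <- channel_covariance(cm)
  ps <- principal_subspace(S, cfg)
  Xc <- cm$X - cm$means
  scores <- crossprod(ps$Vk, Xc)                    # k x (H*W)
  out <- if (cfg$output_mode == "compress_k") {
    unflatten_channels(cm, scores)
  } else {
    unflatten_channels(cm, ps$Vk %*% scores + cm$means)
  }
  attr(out, "k") <- ps$k
  attr(out, "degenerate") <- FALSE
  out
}

# ---- network layer --------------------------------------------------------
# Per-image rank-k channel projector, recomputed every forward pass.
# The eigendecomposition is treated as data-dependent but non-learned:
# gradients flow through the symmetric projector as a constant matrix.

cpca_layer <- function(cfg = cpca_config(), ch = NA_integer_, name = "cpca") {
  stopifnot(cfg$output_mode == "reconstruct_C")
  new_layer("cpca", list(cfg = cfg, ch = ch, name = name))
}

#' @export
layer_fwd.cg_cpca <- function(ly, fm, training = FALSE) {
  hw <- fm$h * fm$w
  C <- ncol(fm$x)
  y <- fm$x
  P <- vector("list", fm$n)
  for (i in seq_len(fm$n)) {
    rows <- ((i - 1) * hw + 1):(i * hw)
    Xi <- fm$x[rows, , drop = FALSE]
    mu <- colMeans(Xi)
    Xc <- Xi - rowrep(mu, hw)
    S <- crossprod(Xc) / (hw - 1)
    tot <- sum(diag(S))
    if (tot <= 1e-12) {
      P[[i]] <- diag(C)
      next
    }
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    k <- if (ly$cfg$k_mode == "fixed") min(ly$cfg$k_value, C) else
      as.integer(which(cumsum(vals) / sum(vals) >= ly$cfg$k_value - 1e-12)[1])
    Vk <- e$vectors[, seq_len(k), drop = FALSE]
    Pi <- tcrossprod(Vk)
    P[[i]] <- Pi
    y[rows, ] <- Xc %*% Pi + rowrep(mu, hw)
  }
  ly$.P <- P
  ly$.hw <- hw
  fm_new(y, fm$n, fm$h, fm$w)
}

#' @export
layer_bwd.cg_cpca <- function(ly, dfm) {
  hw <- ly$.hw
  dx <- dfm$x
  for (i in seq_len(dfm$n)) {
    rows <- ((i - 1) * hw + 1):(i * hw)
    dx[rows, ] <- dx[rows, , drop = FALSE] %*% ly$.P[[i]]
  }
  fm_new(dx, dfm$n, dfm$h, dfm$w)
}

# Analytic MAC surrogate: covariance (C^2 HW) + eigendecomposition (C^3)
# + projection (2 k C HW), with k = C unless fixed.
#' @export
layer_count.cg_cpca <- function(ly, h, w) {
  C <- as.double(ly$ch)
  hw <- as.double(h) * w
  k <- if (ly$cfg$k_mode == "fixed") min(ly$cfg$k_value, C) else C
  list(params = 0L, macs = C^2 * hw + C^3 + 2 * k * C * hw, h = h, w = w)
}
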