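# Model complexity accounting: exact trainable-parameter counts and
# analytic multiply-accumulate (MAC) tallies per layer. "FLOPs (G)" in
# lightweight-CNN tables conventionally reports giga-MACs; a x2
# multiplier flag is available for the fused multiply-add convention.
# Pooling, BN and activations are excluded from the MAC tally; CPCA is
# accounted analytically (covariance + eigendecomposition + projection).

per_layer_table <- function(ly, h, w) {
  if (length(ly$children) == 0L && !inherits(ly, "cg_ghost_module")) {
    ct <- layer_count(ly, h, w)
    return(list(rows = data.frame(id = ly$id, kind = ly$kind,
                                  params = ct$params, macs = ct$macs,
                                  stringsAsFactors = FALSE),
                h = ct$h, w = ct$w))
  }
  rows <- list()
  if (inherits(ly, "cg_ghost_module")) {
    for (ch in ly$primary) {
      r <- per_layer_table(ch, h, w)
      rows <- c(rows, list(r$rows)); h <- r$h; w <- r$w
    }
    for (ch in ly$cheap) {
      r <- per_layer_table(ch, h, w)
      rows <- c(rows, list(r$rows))
    }
  } else {
    for (ch in ly$children) {
      r <- per_layer_table(ch, h, w)
      rows <- c(rows, list(r$rows)); h <- r$h; w <- r$w
    }
  }
  list(rows = do.call(rbind, rows), h = h, w = w)
}

#' Count trainable parameters
#'
#' Counts every trainable weight and bias, including the affine pairs of
#' every batch-normalization layer. Deterministic and independent of
#' input resolution or content.
#'
#' @param model a built model.
#' @return list with `params_exact` (integer), `params_M` (millions,
#'   2-decimal) and `per_layer` (data.frame id/kind/params).
#' @export
count_params <- function(model) {
  leaves <- layer_leaves(model)
  per <- data.frame(
    id = vapply(leaves, function(l) l$id %||% l$name, character(1)),
    kind = vapply(leaves, function(l) l$kind, character(1)),
    params = vapply(leaves, function(l)
      sum(vapply(l$w, length, numeric(1)), 0), numeric(1)),
    stringsAsFactors = FALSE)
  total <- sum(per$params)
  list(params_exact = as.integer(total), params_M = round(total / 1e6, 2),
       per_layer = per)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count multiply-accumulates
#'
#' Analytic per-layer MAC tally at a given square input resolution:
#' convolution MACs are `k^2 * Cin/groups * Cout * Hout * Wout`, linear
#' layers `in * out`; pooling, BN and activations are excluded.
#'
#' @param model a built model.
#' @param input_hw input resolution in pixels (square).
#' @param flops_multiplier 1 (MAC convention, default) or 2.
#' @return list with `macs`, `flops_G` (convention-tagged), `params_exact`,
#'   `params_M`, and the `per_layer` ledger.
#' @export
count_macs <- function(model, input_hw = 224, flops_multiplier = 1) {
  stopifnot(input_hw >= 2)
  tab <- per_layer_table(model, input_hw, input_hw)
  p <- count_params(model)
  list(macs = sum(tab$rows$macs),
       flops_G = round(flops_multiplier * sum(tab$rows$macs) / 1e9, 2),
       flops_convention = if (flops_multiplier == 1) "MACs" else "2*MACs",
       params_exact = p$params_exact, params_M = p$params_M,
       per_layer = tab$rows)
}

#' Per-stage complexity profile
#'
#' Mirrors the architecture-table layout: one row per top-level section
#' (stem, stages, head, classifier) with parameters and MACs.
#'
#' @param model a built model.
#' @param input_hw input resolution.
#' @return data.frame section/params/macs plus a `totals` attribute.
#' @export
model_profile <- function(model, input_hw = 224) {
  h <- input_hw; w <- input_hw
  rows <- list()
  for (top in model$children) {
    ct <- layer_count(top, h, w)
    rows[[length(rows) + 1L]] <- data.frame(
      section = top$name, out_h = as.integer(ct$h), out_w = as.integer(ct$w),
      params = ct$params, macs = ct$macs, stringsAsFactors = FALSE)
    h <- ct$h; w <- ct$w
  }
  out <- do.call(rbind, rows)
  attr(out, "totals") <- list(params = sum(out$params), macs = sum(out$macs))
  out
}
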