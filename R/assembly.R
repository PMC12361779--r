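# Assembling CGENet and its ablation variants: substitute ghost
# bottlenecks for the MBConv blocks of chosen backbone stages (same
# in/out channels, expansion, kernel and stride), choose the channel
# attention, and insert the parameter-free CPCA stage.
#
# Variant geometries over the seven MBConv stages:
#   A_cgenet     stages {4, 7} of the printed table (indices {3, 6} here):
#                the two 5x5 down-sampling stages. This is the calibrated
#                CGENet recipe reproducing the published 2.82M parameters.
#   B_top_two    first two stages.
#   C_bottom_two last two stages.
#   D_all        all seven.
# B/C/D are structural ablations only; their published parameter counts
# are not reproducible from the stated substitution and are not targeted.

#' Variant specification
#'
#' @param name one of `"A_cgenet"`, `"B_top_two"`, `"C_bottom_two"`,
#'   `"D_all"`, `"baseline"`, or `"custom"` (then give `replaced_stages`).
#' @param replaced_stages integer set in 1..7 (MBConv stage indices)
#'   overriding the named geometry.
#' @param use_cpca insert the CPCA stage.
#' @param attention channel attention inside ghost bottlenecks.
#' @return a `variant_spec` list.
#' @export
variant_spec <- function(name = c("A_cgenet", "B_top_two", "C_bottom_two",
                                  "D_all", "baseline", "custom"),
                         replaced_stages = NULL, use_cpca = NULL,
                         attention = c("ECA", "SE", "none")) {
  name <- match.arg(name)
  attention <- match.arg(attention)
  if (is.null(replaced_stages))
    replaced_stages <- switch(name,
      A_cgenet = c(3L, 6L), B_top_two = c(1L, 2L),
      C_bottom_two = c(6L, 7L), D_all = 1:7,
      baseline = integer(0),
      custom = stop("custom variant requires replaced_stages"))
  replaced_stages <- as.integer(sort(unique(replaced_stages)))
  if (length(replaced_stages) && (min(replaced_stages) < 1 ||
                                  max(replaced_stages) > 7))
    stop("replaced_stages must lie in 1..7")
  if (is.null(use_cpca)) use_cpca <- name == "A_cgenet"
  structure(list(name = name, replaced_stages = replaced_stages,
                 use_cpca = use_cpca, attention = attention),
            class = "variant_spec")
}

#' Apply a variant to an architecture
#'
#' Returns the per-stage block kinds after substitution; every block of a
#' replaced stage becomes a ghost bottleneck with the same channels,
#' expansion, kernel and stride as the MBConv it replaces.
#'
#' @param spec an [b0_architecture()] spec.
#' @param variant a [variant_spec()].
#' @return list with `spec` (unchanged geometry) and `block_kinds`
#'   (length-7 character vector of `"mbconv"`/`"ghost"`).
#' @export
replace_stages <- function(spec, variant) {
  stopifnot(inherits(variant, "variant_spec"))
  kinds <- rep("mbconv", 7L)
  kinds[variant$replaced_stages] <- "ghost"
  list(spec = spec, block_kinds = kinds)
}

#' Build CGENet (or an ablation variant)
#'
#' EfficientNet-B0 skeleton with ghost(attention) bottlenecks substituted
#' per the variant and an optional CPCA stage at the configured placement.
#' The forward contract is identical to [build_efficientnet()].
#'
#' @param num_classes classifier width (>= 2).
#' @param variant a [variant_spec()]; default is variant A (CGENet).
#' @param cpca_cfg a [cpca_config()]; used when `variant$use_cpca`.
#' @param ghost_cfg a [ghost_config()].
#' @param dropout dropout rate before the classifier.
#' @return a model object.
#' @examples
#' \donttest{
#' m <- build_cgenet(num_classes = 60)
#' count_params(m)$params_M  # 2.82
#' }
#' @export
build_cgenet <- function(num_classes, variant = variant_spec("A_cgenet"),
                         cpca_cfg = cpca_config(),
                         ghost_cfg = ghost_config(), dropout = 0.2) {
  stopifnot(num_classes >= 2)
  spec <- b0_architecture(num_classes)
  rp <- replace_stages(spec, variant)
  build_backbone(spec, block_kinds = rp$block_kinds,
                 cpca_cfg = if (variant$use_cpca) cpca_cfg else NULL,
                 attention = variant$attention, dropout = dropout,
                 ghost_cfg = ghost_cfg)
}

#' Per-stage block census of a built model
#'
#' @param model a built model.
#' @return data.frame with one row per block: stage label, block index and
#'   block kind — used for structural audits of variant substitution.
#' @export
model_blocks <- function(model) {
  out <- list()
  for (top in model$children) {
    if (!grepl("^stage", top$name)) next
    for (i in seq_along(top$children)) {
      bl <- top$children[[i]]
      out[[length(out) + 1L]] <- data.frame(
        stage = top$name, block = i, kind = bl$kind,
        residual = isTRUE(bl$residual), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
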