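#' Single-cell genotype matrix bundle
#'
#' The central container of the package: a set of aligned cells-by-variants
#' layers. `NGT` holds genotype codes (0 = hom ref, 1 = het, 2 = hom alt,
#' `NA` = missing), `DP` read depth at the variant's amplicon, `GQ` genotype
#' quality, and `AF` the alternate-allele read fraction. All layers share
#' dimensions and dimnames; the missing sentinel is `NA`, never 0.
#'
#' @param ngt integer matrix of genotype codes, cells in rows, variants in
#'   columns, with dimnames.
#' @param dp,gq,af optional aligned numeric layers (depth, quality,
#'   alternate fraction).
#' @return An object of class `mpt_bundle`: a list with elements `cell_ids`,
#'   `variant_ids` and `layers`.
#' @examples
#' ngt <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'               dimnames = list(c("c1", "c2"), c("v1", "v2")))
#' b <- mpt_bundle(ngt)
#' dim(b)
#' @export
mpt_bundle <- function(ngt, dp = NULL, gq = NULL, af = NULL) {
  layers <- list(NGT = ngt, DP = dp, GQ = gq, AF = af)
  layers <- layers[!vapply(layers, is.null, logical(1))]
  validate_layers(layers)
  structure(
    list(
      cell_ids = rownames(layers$NGT),
      variant_ids = colnames(layers$NGT),
      layers = layers
    ),
    class = "mpt_bundle"
  )
}

BUNDLE_LAYERS <- c("NGT", "DP", "GQ", "AF")

validate_layers <- function(layers) {
  if (!"NGT" %in% names(layers)) {
    abort("an `NGT` layer is required")
  }
  unknown <- setdiff(names(layers), BUNDLE_LAYERS)
  if (length(unknown)) {
    abort(paste0("unknown layer name(s): ", paste(unknown, collapse = ", ")))
  }
  ngt <- layers$NGT
  if (!is.matrix(ngt) || is.null(rownames(ngt)) || is.null(colnames(ngt))) {
    abort("`NGT` must be a matrix with cell and variant dimnames")
  }
  if (anyDuplicated(rownames(ngt))) abort("duplicate cell ids")
  if (anyDuplicated(colnames(ngt))) abort("duplicate variant ids")
  bad <- !is.na(ngt) & !(ngt %in% NGT_CODES)
  if (any(bad)) abort("NGT codes must be 0, 1, 2 or NA")
  for (nm in setdiff(names(layers), "NGT")) {
    l <- layers[[nm]]
    if (!is.matrix(l) || !identical(dim(l), dim(ngt))) {
      abort(paste0("layer `", nm, "` does not match the NGT layer shape"))
    }
  }
  if ("DP" %in% names(layers) && any(layers$DP < 0, na.rm = TRUE)) {
    abort("DP must be non-negative")
  }
  if ("AF" %in% names(layers) &&
      any(layers$AF < 0 | layers$AF > 1, na.rm = TRUE)) {
    abort("AF must lie in [0, 1]")
  }
  invisible(layers)
}

#' @export
dim.mpt_bundle <- function(x) dim(x$layers$NGT)

#' @export
dimnames.mpt_bundle <- function(x) list(x$cell_ids, x$variant_ids)

#' Subset a genotype bundle by cells and/or variants
#'
#' @param x an [mpt_bundle()].
#' @param i,j cell / variant indices (ids, logicals or integers).
#' @param ... ignored.
#' @export
`[.mpt_bundle` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$variant_ids)
  layers <- lapply(x$layers, function(l) l[i, j, drop = FALSE])
  do.call(mpt_bundle, setNames(layers, tolower(names(layers))))
}

#' @export
print.mpt_bundle <- function(x, ...) {
  cat(sprintf(
    "<mpt_bundle> %d cells x %d variants; layers: %s\n",
    length(x$cell_ids), length(x$variant_ids),
    paste(names(x$layers), collapse = ", ")
  ))
  miss <- mean(is.na(x$layers$NGT))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Turn a genotype bundle into a long tibble
#'
#' One row per cell/variant entry with one column per layer; missing
#' genotypes are `NA`.
#'
#' @param x an [mpt_bundle()].
#' @param ... ignored.
#' @return A tibble with columns `cell_id`, `variant_id` and one per layer.
#' @method tidy mpt_bundle
#' @export
tidy.mpt_bundle <- function(x, ...) {
  out <- tibble(
    cell_id = rep(x$cell_ids, times = length(x$variant_ids)),
    variant_id = rep(x$variant_ids, each = length(x$cell_ids))
  )
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]])
  out
}

#' @method glance mpt_bundle
#' @export
glance.mpt_bundle <- function(x, ...) {
  ngt <- x$layers$NGT
  tibble(
    n_cells = nrow(ngt),
    n_variants = ncol(ngt),
    frac_missing = mean(is.na(ngt)),
    frac_mutated = mean(ngt > 0, na.rm = TRUE)
  )
}
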