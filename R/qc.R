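#' Single-cell genotype filter configuration
#'
#' Thresholds of the genotype-matrix filter cascade. Defaults follow the
#' standard targeted scDNA-seq settings: genotype quality < 30, depth
#' < 10 and alternate-call allele fraction < 20% are masked to missing;
#' variants genotyped in < 50% of cells, cells genotyped at < 50% of
#' variants, variants mutated in < 1% of cells and heterozygous germline
#' variants present in > 95% of cells are removed; finally rows/columns
#' with > 50% missing entries are dropped.
#'
#' @param min_gq,min_dp entry-level quality and depth cutoffs.
#' @param min_af_for_alt minimum allele fraction for an alternate
#'   (het/hom-alt) call; reference calls are not AF-masked.
#' @param min_frac_cells_genotyped_per_variant,min_frac_variants_genotyped_per_cell
#'   genotyped-fraction cutoffs per variant / per cell.
#' @param min_frac_cells_mutated minimum fraction of genotyped cells
#'   carrying the mutation.
#' @param germline_het_frac heterozygous fraction (of genotyped cells)
#'   above which a variant is removed as germline.
#' @param max_na_frac final missingness cap per row/column.
#' @param cell_completeness minimum fraction of amplicons with nonzero
#'   reads for a barcode to be called a cell.
#' @param total_reads_cutoff absolute minimum per-cell total reads;
#'   `NULL` uses `0.2 x` the median per-cell total.
#' @return A list of class `mpt_sc_filter_config`.
#' @export
sc_filter_config <- function(min_gq = 30,
                             min_dp = 10,
                             min_af_for_alt = 0.20,
                             min_frac_cells_genotyped_per_variant = 0.50,
                             min_frac_variants_genotyped_per_cell = 0.50,
                             min_frac_cells_mutated = 0.01,
                             germline_het_frac = 0.95,
                             max_na_frac = 0.50,
                             cell_completeness = 0.80,
                             total_reads_cutoff = NULL) {
  cfg <- as.list(environment())
  fr <- c("min_af_for_alt", "min_frac_cells_genotyped_per_variant",
          "min_frac_variants_genotyped_per_cell", "min_frac_cells_mutated",
          "germline_het_frac", "max_na_frac", "cell_completeness")
  stopifnot(all(unlist(cfg[fr]) >= 0), all(unlist(cfg[fr]) <= 1),
            min_gq >= 0, min_dp >= 0)
  structure(cfg, class = "mpt_sc_filter_config")
}

#' Call cells from an amplicon count matrix
#'
#' A barcode is retained iff at least `cell_completeness` of amplicons
#' have nonzero reads and its total reads reach the cutoff (default
#' `0.2 x` the median per-cell total, a scale-free stand-in for the
#' vendor's absolute cutoff).
#'
#' @param counts cells-by-amplicons non-negative matrix.
#' @param cfg an [sc_filter_config()].
#' @return A tibble with `cell_id`, `completeness`, `total_reads`,
#'   `retained`.
#' @export
call_cells <- function(counts, cfg = sc_filter_config()) {
  if (is.null(dim(counts)) || ncol(counts) == 0) {
    abort("count matrix has no amplicons")
  }
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  completeness <- rowMeans(counts > 0)
  total <- rowSums(counts)
  cutoff <- cfg$total_reads_cutoff %||% (0.2 * median(total))
  tibble(
    cell_id = rownames(counts),
    completeness = completeness,
    total_reads = total,
    retained = completeness >= cfg$cell_completeness & total >= cutoff
  )
}

#' Filter a single-cell genotype matrix
#'
#' Applies the filter cascade in a fixed, logged order:
#' \enumerate{
#'   \item entry masking to missing where `GQ < min_gq`, `DP < min_dp`,
#'     or an alternate call has `AF < min_af_for_alt`;
#'   \item drop variants genotyped in fewer than
#'     `min_frac_cells_genotyped_per_variant` of cells;
#'   \item drop cells genotyped at fewer than
#'     `min_frac_variants_genotyped_per_cell` of variants;
#'   \item drop variants mutated (codes 1/2) in fewer than
#'     `min_frac_cells_mutated` of genotyped cells;
#'   \item drop variants heterozygous in more than `germline_het_frac`
#'     of genotyped cells (germline);
#'   \item drop cells/variants whose missing fraction exceeds
#'     `max_na_frac`.
#' }
#' Entry masking precedes the percentage filters because those are
#' defined over genotyped entries. The ledger records every removal with
#' its stage; rerunning the cascade on its own output changes nothing.
#'
#' @param bundle an [mpt_bundle()] with NGT (and optionally DP/GQ/AF)
#'   layers.
#' @param cfg an [sc_filter_config()].
#' @return A list of class `mpt_filter_result`: `bundle` (filtered),
#'   `ledger` (tibble: `stage`, `rule`, `axis`, `id`), `masked_entries`
#'   (count masked at stage 1) and `all_filtered` (flag).
#' @export
filter_single_cell_matrix <- function(bundle, cfg = sc_filter_config()) {
  stopifnot(inherits(bundle, "mpt_bundle"))
  ngt <- bundle$layers$NGT
  dp <- bundle$layers$DP
  gq <- bundle$layers$GQ
  af <- bundle$layers$AF

  mask <- matrix(FALSE, nrow(ngt), ncol(ngt))
  if (!is.null(gq)) mask <- mask | (!is.na(gq) & gq < cfg$min_gq)
  if (!is.null(dp)) mask <- mask | (!is.na(dp) & dp < cfg$min_dp)
  if (!is.null(af)) {
    mask <- mask | (!is.na(ngt) & ngt > 0 & !is.na(af) &
                      af < cfg$min_af_for_alt)
  }
  masked_entries <- sum(mask & !is.na(ngt))
  ngt[mask] <- NA_integer_

  ledger <- list()
  note <- function(stage, rule, axis, ids) {
    if (length(ids)) {
      ledger[[length(ledger) + 1]] <<-
        tibble(stage = stage, rule = rule, axis = axis, id = ids)
    }
  }
  drop_variants <- function(ngt, bad, stage, rule) {
    note(stage, rule, "variant", colnames(ngt)[bad])
    ngt[, !bad, drop = FALSE]
  }

  # 2: variants genotyped in too few cells
  geno_frac <- colMeans(!is.na(ngt))
  ngt <- drop_variants(ngt, geno_frac < cfg$min_frac_cells_genotyped_per_variant,
                       2L, "variant_genotyped_frac")
  # 3: cells genotyped at too few variants
  cell_frac <- rowMeans(!is.na(ngt))
  bad_cells <- cell_frac < cfg$min_frac_variants_genotyped_per_cell
  note(3L, "cell_genotyped_frac", "cell", rownames(ngt)[bad_cells])
  ngt <- ngt[!bad_cells, , drop = FALSE]
  # 4: variants mutated in too few genotyped cells
  if (nrow(ngt) && ncol(ngt)) {
    mut_frac <- colMeans(ngt > 0, na.rm = TRUE)
    mut_frac[is.nan(mut_frac)] <- 0
    ngt <- drop_variants(ngt, mut_frac < cfg$min_frac_cells_mutated,
                         4L, "cells_mutated_frac")
  }
  # 5: germline het variants
  if (nrow(ngt) && ncol(ngt)) {
    het_frac <- colMeans(ngt == 1L, na.rm = TRUE)
    het_frac[is.nan(het_frac)] <- 0
    ngt <- drop_variants(ngt, het_frac > cfg$germline_het_frac,
                         5L, "germline_het")
  }
  # 6: residual high-missingness rows/columns
  if (nrow(ngt) && ncol(ngt)) {
    ngt <- drop_variants(ngt, colMeans(is.na(ngt)) > cfg$max_na_frac,
                         6L, "variant_na_frac")
  }
  if (nrow(ngt) && ncol(ngt)) {
    bad_cells <- rowMeans(is.na(ngt)) > cfg$max_na_frac
    note(6L, "cell_na_frac", "cell", rownames(ngt)[bad_cells])
    ngt <- ngt[!bad_cells, , drop = FALSE]
  }

  ledger <- if (length(ledger)) bind_rows(ledger) else
    tibble(stage = integer(), rule = character(), axis = character(),
           id = character())
  all_filtered <- nrow(ngt) == 0 || ncol(ngt) == 0
  out_bundle <- NULL
  if (!all_filtered) {
    keep_layers <- lapply(bundle$layers, function(l) {
      l[rownames(ngt), colnames(ngt), drop = FALSE]
    })
    keep_layers$NGT <- ngt
    out_bundle <- do.call(mpt_bundle,
                          setNames(keep_layers, tolower(names(keep_layers))))
  } else {
    warn("all cells or variants removed by the filter cascade")
  }
  structure(
    list(bundle = out_bundle, ledger = ledger,
         masked_entries = masked_entries, all_filtered = all_filtered,
         config = cfg,
         input_dim = dim(bundle$layers$NGT)),
    class = "mpt_filter_result"
  )
}

#' @export
print.mpt_filter_result <- function(x, ...) {
  cat("<mpt_filter_result>\n")
  cat(sprintf("  input: %d cells x %d variants; masked entries: %d\n",
              x$input_dim[1], x$input_dim[2], x$masked_entries))
  if (x$all_filtered) {
    cat("  all entries filtered\n")
  } else {
    cat(sprintf("  output: %d cells x %d variants\n",
                nrow(x$bundle$layers$NGT), ncol(x$bundle$layers$NGT)))
  }
  invisible(x)
}

#' @method tidy mpt_filter_result
#' @export
tidy.mpt_filter_result <- function(x, ...) x$ledger

#' @method glance mpt_filter_result
#' @export
glance.mpt_filter_result <- function(x, ...) {
  tibble(
    n_cells_in = x$input_dim[1], n_variants_in = x$input_dim[2],
    n_cells_out = if (x$all_filtered) 0L else nrow(x$bundle$layers$NGT),
    n_variants_out = if (x$all_filtered) 0L else ncol(x$bundle$layers$NGT),
    masked_entries = x$masked_entries,
    n_removed_cells = sum(x$ledger$axis == "cell"),
    n_removed_variants = sum(x$ledger$axis == "variant")
  )
}

#' Bulk variant filter configuration
#'
#' @param min_supporting_reads consensus filter: minimum alternate-read
#'   support.
#' @param cluster_window_bp window size of the clustered-mutation filter;
#'   any variant with another variant within this many base pairs (same
#'   chromosome, inclusive) is removed along with it.
#' @param min_site_coverage sites below this coverage are flagged as
#'   missing (retained but unusable downstream).
#' @param min_mapq minimum mapping quality; applied only when a `mapq`
#'   column is present (a no-op for plain VCF input).
#' @return A list of class `mpt_bulk_filter_config`.
#' @export
bulk_filter_config <- function(min_supporting_reads = 3,
                               cluster_window_bp = 10,
                               min_site_coverage = 10,
                               min_mapq = 40) {
  stopifnot(min_supporting_reads >= 1, cluster_window_bp >= 1,
            min_site_coverage >= 1, min_mapq >= 0)
  structure(as.list(environment()), class = "mpt_bulk_filter_config")
}

#' Filter a bulk variant table
#'
#' Consensus filter (supporting reads), clustered-region filter (all
#' members of any group of mutations within `cluster_window_bp` of one
#' another are removed) and low-coverage flagging.
#'
#' @param variants tibble with `chrom`, `pos`, `support` (alternate-read
#'   count) and `depth` columns; optionally `mapq`.
#' @param cfg a [bulk_filter_config()].
#' @return The filtered tibble with a logical `coverage_na` column; a
#'   `removed` attribute holds the removed rows with reasons.
#' @export
filter_bulk_variants <- function(variants, cfg = bulk_filter_config()) {
  v <- variants
  reason <- rep(NA_character_, nrow(v))
  if ("mapq" %in% names(v)) {
    reason[is.na(reason) & !is.na(v$mapq) & v$mapq < cfg$min_mapq] <- "mapq"
  }
  low_support <- !is.na(v$support) & v$support < cfg$min_supporting_reads
  reason[is.na(reason) & low_support] <- "min_supporting_reads"
  # clustered-region rule over the candidates still alive
  alive <- which(is.na(reason))
  if (length(alive) > 1) {
    av <- v[alive, ]
    clustered <- vapply(seq_along(alive), function(i) {
      any(av$chrom == av$chrom[i] &
            abs(av$pos - av$pos[i]) <= cfg$cluster_window_bp &
            seq_along(alive) != i)
    }, logical(1))
    reason[alive[clustered]] <- "cluster_window"
  }
  out <- v[is.na(reason), , drop = FALSE]
  out$coverage_na <- !is.na(out$depth) & out$depth < cfg$min_site_coverage
  removed <- v[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  attr(out, "removed") <- removed
  out
}
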