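#' GC fraction of a nucleotide sequence
#'
#' `(#G + #C) / #non-N bases`; `N` bases are excluded from the
#' denominator. Vectorized over sequences.
#'
#' @param seq character vector of sequences over `{A, C, G, T, N}`
#'   (case-insensitive).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_fraction(c("GCGC", "ATAT", "GCATN"))
#' @export
gc_fraction <- function(seq) {
  if (any(is.na(seq)) || any(nchar(seq) == 0)) {
    abort("empty sequence")
  }
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) {
    abort("sequence contains characters outside {A,C,G,T,N}")
  }
  gc <- nchar(gsub("[^GC]", "", up))
  denom <- nchar(gsub("N", "", up))
  if (any(denom == 0)) abort("all-N sequence has no defined GC fraction")
  gc / denom
}

#' Amplicon panel feasibility rules
#'
#' The rule set applied when assembling a multi-patient targeted panel:
#' amplifiable region GC window, primer GC window, amplicon length window,
#' masked-region exclusion, non-overlap, and a maximum panel size.
#'
#' @param region_gc,primer_gc,amplicon_len closed `[lo, hi]` intervals.
#' @param forbid_overlap drop lower-priority members of overlapping pairs.
#' @param masked_regions optional tibble of `chrom`, `start`, `end`
#'   (0-based half-open) intervals to exclude (centromeres, telomeres,
#'   repeats).
#' @param max_panel_size maximum accepted amplicons.
#' @return A list of class `mpt_panel_rules`.
#' @export
panel_rules <- function(region_gc = c(0.27, 0.70),
                        primer_gc = c(0.27, 0.62),
                        amplicon_len = c(125, 275),
                        forbid_overlap = TRUE,
                        masked_regions = NULL,
                        max_panel_size = 380) {
  stopifnot(region_gc[1] <= region_gc[2], primer_gc[1] <= primer_gc[2],
            amplicon_len[1] <= amplicon_len[2], max_panel_size >= 1)
  structure(
    list(region_gc = region_gc, primer_gc = primer_gc,
         amplicon_len = amplicon_len, forbid_overlap = forbid_overlap,
         masked_regions = masked_regions,
         max_panel_size = max_panel_size),
    class = "mpt_panel_rules"
  )
}

#' Design a multi-patient targeted panel
#'
#' Pools candidate (variant, amplicon) pairs across patients, collapses
#' identical variants shared between patients into a single amplicon
#' (recording all carriers), applies the feasibility rules in a fixed
#' order — region GC, primer GC, amplicon length, masked regions — then
#' resolves overlaps among survivors by keeping the higher bulk-VAF
#' variant (genomic order breaks ties) and finally truncates to
#' `max_panel_size`, dropping lowest-VAF candidates first. Every rejected
#' candidate is reported with the first rule it failed.
#'
#' @param candidates tibble with one row per candidate: `patient`,
#'   `chrom`, `pos`, `ref`, `alt`, `bulk_vaf`, `amplicon_id`, `start`,
#'   `end`, `length_bp`, `gc_fraction`, `primer_gc`.
#' @param rules a [panel_rules()] object.
#' @return A list of class `mpt_panel`: `panel` (accepted tibble, with a
#'   `carriers` list-column), `rejected` (tibble with `reason`), and
#'   `retention` (per-patient retained fraction).
#' @export
design_panel <- function(candidates, rules = panel_rules()) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    abort("empty candidate set")
  }
  req <- c("patient", "chrom", "pos", "ref", "alt", "bulk_vaf",
           "amplicon_id", "length_bp", "gc_fraction", "primer_gc")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols)) {
    abort(paste0("candidates lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("start", "end") %in% names(candidates))) {
    candidates$start <- candidates$pos - 1L
    candidates$end <- candidates$pos
  }

  # collapse identical variants across patients: shared sites save space
  pooled <- candidates |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      carriers = list(sort(unique(.data$patient))),
      bulk_vaf = max(.data$bulk_vaf),
      amplicon_id = .data$amplicon_id[1],
      start = .data$start[1], end = .data$end[1],
      length_bp = .data$length_bp[1],
      gc_fraction = .data$gc_fraction[1],
      primer_gc = .data$primer_gc[1],
      .groups = "drop"
    )

  in_int <- function(x, int) !is.na(x) & x >= int[1] & x <= int[2]
  reason <- rep(NA_character_, nrow(pooled))
  fail <- function(ok, why) {
    hit <- is.na(reason) & !ok
    reason[hit] <<- why
    invisible(NULL)
  }
  fail(in_int(pooled$gc_fraction, rules$region_gc), "region_gc")
  fail(in_int(pooled$primer_gc, rules$primer_gc), "primer_gc")
  fail(in_int(pooled$length_bp, rules$amplicon_len), "amplicon_len")
  if (!is.null(rules$masked_regions) && nrow(rules$masked_regions)) {
    m <- rules$masked_regions
    masked <- vapply(seq_len(nrow(pooled)), function(i) {
      any(m$chrom == pooled$chrom[i] & m$start < pooled$end[i] &
            pooled$start[i] < m$end)
    }, logical(1))
    fail(!masked, "masked_region")
  }

  surv <- pooled[is.na(reason), , drop = FALSE]
  if (rules$forbid_overlap && nrow(surv) > 1) {
    ord <- order(-surv$bulk_vaf, surv$chrom, surv$start)
    keep <- logical(nrow(surv))
    for (i in ord) {
      clash <- keep & surv$chrom == surv$chrom[i] &
        surv$start < surv$end[i] & surv$start[i] < surv$end
      if (!any(clash)) keep[i] <- TRUE
    }
    reason[is.na(reason)][!keep] <- "overlap"
    surv <- surv[keep, , drop = FALSE]
  }
  if (nrow(surv) > rules$max_panel_size) {
    ord <- order(-surv$bulk_vaf, surv$chrom, surv$start)
    dropped <- ord[-seq_len(rules$max_panel_size)]
    drop_key <- paste(surv$chrom, surv$pos, surv$ref, surv$alt)[dropped]
    all_key <- paste(pooled$chrom, pooled$pos, pooled$ref, pooled$alt)
    reason[all_key %in% drop_key] <- "panel_size"
    surv <- surv[-dropped, , drop = FALSE]
  }

  rejected <- pooled[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  accepted_key <- paste(surv$chrom, surv$pos, surv$ref, surv$alt)
  cand_key <- paste(candidates$chrom, candidates$pos, candidates$ref,
                    candidates$alt)
  retention <- candidates |>
    mutate(kept = cand_key %in% accepted_key) |>
    group_by(.data$patient) |>
    summarise(n_candidates = n(), n_retained = sum(.data$kept),
              retained_frac = mean(.data$kept), .groups = "drop")

  structure(
    list(
      panel = arrange(surv, .data$chrom, .data$start),
      rejected = rejected,
      retention = retention,
      rules = rules
    ),
    class = "mpt_panel"
  )
}

#' @export
print.mpt_panel <- function(x, ...) {
  cat(sprintf("<mpt_panel> %d accepted, %d rejected\n",
              nrow(x$panel), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    cat("  rejections:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy mpt_panel
#' @export
tidy.mpt_panel <- function(x, ...) {
  acc <- mutate(x$panel, accepted = TRUE, reason = NA_character_)
  rej <- mutate(x$rejected, accepted = FALSE)
  bind_rows(acc, rej)
}

#' @method glance mpt_panel
#' @export
glance.mpt_panel <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$panel) + nrow(x$rejected),
    n_accepted = nrow(x$panel),
    accept_frac = nrow(x$panel) / (nrow(x$panel) + nrow(x$rejected))
  )
}
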