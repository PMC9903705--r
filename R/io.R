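#' Read a bulk variant table from VCF
#'
#' Parses a VCF 4.x file into a tidy variant table, one row per ALT allele
#' (multi-allelic sites are split, with `Number=A` INFO fields split
#' alongside). Positions are reported 1-based as in the VCF; the 0-based
#' half-open start used for interval arithmetic against amplicon panels is
#' exposed as `pos0 = pos - 1`.
#'
#' Annotation scores (PolyPhen, SIFT, CADD, ...) are read from INFO keys;
#' the key names differ between annotation pipelines and are therefore
#' configurable through `info_keys`. A missing key yields `NA`, not an
#' error.
#'
#' @param path path to a VCF file.
#' @param info_keys named character vector mapping output columns to INFO
#'   keys. Defaults:
#'   `c(bulk_vaf="AF", depth="DP", gene="GENE", variant_class="CLASS",
#'      polyphen="POLYPHEN", sift="SIFT", cadd="CADD",
#'      support="SUPPORT", mapq="MQ")`.
#' @return A tibble with columns `chrom`, `pos`, `pos0`, `ref`, `alt`,
#'   `gene`, `variant_class`, `bulk_vaf`, `depth`, `polyphen`, `sift`,
#'   `cadd`, `support`.
#' @export
read_variant_table <- function(path, info_keys = NULL) {
  keys <- c(
    bulk_vaf = "AF", depth = "DP", gene = "GENE", variant_class = "CLASS",
    polyphen = "POLYPHEN", sift = "SIFT", cadd = "CADD",
    support = "SUPPORT", mapq = "MQ"
  )
  if (!is.null(info_keys)) keys[names(info_keys)] <- info_keys
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_variant_table())
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  which_alt <- unlist(lapply(n_alt, seq_len))

  info_col <- function(key, per_allele) {
    val <- tryCatch(vcfR::extract.info(v, key),
                    error = function(e) rep(NA_character_, nrow(fix)))
    if (is.null(val)) val <- rep(NA_character_, nrow(fix))
    val <- as.character(val)
    if (per_allele) {
      parts <- strsplit(val, ",", fixed = TRUE)
      out <- vapply(seq_along(idx), function(k) {
        p <- parts[[idx[k]]]
        if (length(p) >= which_alt[k]) p[which_alt[k]] else p[1]
      }, character(1))
    } else {
      out <- val[idx]
    }
    out
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_split),
    gene = info_col(keys[["gene"]], FALSE),
    variant_class = info_col(keys[["variant_class"]], FALSE),
    bulk_vaf = num(info_col(keys[["bulk_vaf"]], TRUE)),
    depth = as.integer(num(info_col(keys[["depth"]], FALSE))),
    polyphen = num(info_col(keys[["polyphen"]], TRUE)),
    sift = num(info_col(keys[["sift"]], TRUE)),
    cadd = num(info_col(keys[["cadd"]], TRUE)),
    support = as.integer(num(info_col(keys[["support"]], FALSE)))
  )
  out$pos0 <- out$pos - 1L
  bad <- !is.na(out$bulk_vaf) & (out$bulk_vaf < 0 | out$bulk_vaf > 1)
  if (any(bad)) abort("bulk VAF outside [0, 1]")
  if (anyDuplicated(out[c("chrom", "pos", "ref", "alt")])) {
    abort("duplicate (chrom, pos, ref, alt) records in VCF")
  }
  dplyr::relocate(out, "pos0", .after = "pos")
}

empty_variant_table <- function() {
  tibble(
    chrom = character(), pos = integer(), pos0 = integer(),
    ref = character(), alt = character(), gene = character(),
    variant_class = character(), bulk_vaf = numeric(), depth = integer(),
    polyphen = numeric(), sift = numeric(), cadd = numeric(),
    support = integer()
  )
}

#' Write a variant table as a minimal VCF
#'
#' Inverse of [read_variant_table()] for round-tripping; numeric
#' annotations are emitted as INFO keys.
#'
#' @param variants tibble as returned by [read_variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Bulk VAF\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=POLYPHEN,Number=A,Type=Float,Description=\"PolyPhen\">",
    "##INFO=<ID=SIFT,Number=A,Type=Float,Description=\"SIFT\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info_of <- function(i) {
    kv <- c(
      AF = variants$bulk_vaf[i], DP = variants$depth[i],
      GENE = variants$gene[i], CLASS = variants$variant_class[i],
      POLYPHEN = variants$polyphen[i], SIFT = variants$sift[i],
      CADD = variants$cadd[i], SUPPORT = variants$support[i]
    )
    kv <- kv[!is.na(kv)]
    if (!length(kv)) return(".")
    paste(names(kv), kv, sep = "=", collapse = ";")
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
          variants$alt[i], ".", "PASS", info_of(i), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an amplicon panel from BED
#'
#' BED intervals are 0-based half-open, kept as such internally. A VCF
#' position `pos` (1-based) falls inside amplicon `[start, end)` iff
#' `start <= pos - 1 < end`. Pairwise overlaps among amplicons are
#' precomputed; GC content is filled in when a genome source is supplied.
#'
#' @param path path to a BED file (3+ columns; optional 4th column is the
#'   amplicon id).
#' @param genome optional named character vector of chromosome sequences
#'   used to compute `gc_fraction`.
#' @return A tibble with columns `amplicon_id`, `chrom`, `start`, `end`,
#'   `length_bp`, `gc_fraction` and a list-column `overlaps`.
#' @export
read_panel_bed <- function(path, genome = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  bed <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    amplicon_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      paste0("amp_", seq_len(nrow(raw)))
  )
  bad <- which(bed$start >= bed$end)
  if (length(bad)) {
    abort(paste0("degenerate interval (start >= end) at BED line ",
                 paste(bad, collapse = ", ")))
  }
  bed$length_bp <- bed$end - bed$start
  bed$gc_fraction <- NA_real_
  if (!is.null(genome)) {
    for (i in seq_len(nrow(bed))) {
      chr_seq <- genome[[bed$chrom[i]]]
      if (!is.null(chr_seq) && !is.na(chr_seq)) {
        bed$gc_fraction[i] <-
          gc_fraction(substr(chr_seq, bed$start[i] + 1L, bed$end[i]))
      }
    }
  }
  bed$overlaps <- interval_overlaps(bed$chrom, bed$start, bed$end,
                                    bed$amplicon_id)
  dplyr::relocate(bed, "amplicon_id")
}

# half-open interval intersection, O(n^2) over panel-sized inputs
interval_overlaps <- function(chrom, start, end, ids) {
  lapply(seq_along(ids), function(i) {
    hit <- chrom == chrom[i] & start < end[i] & start[i] < end &
      seq_along(ids) != i
    ids[hit]
  })
}

#' Write / read the tab-delimited matrix layer dialect
#'
#' One file per layer (`NGT.tsv`, `DP.tsv`, `GQ.tsv`, `AF.tsv`,
#' `COUNT.tsv`): first row variant/amplicon ids, first column cell ids,
#' missing entries written as `NA`. Round trips are lossless, including
#' the missing sentinel.
#'
#' @param bundle an [mpt_bundle()].
#' @param dir directory to write into (created if needed).
#' @return `write_matrix_bundle()` returns `dir` invisibly;
#'   `read_matrix_bundle()` the reconstructed bundle.
#' @export
write_matrix_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mpt_bundle"))
  validate_layers(bundle$layers)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle$layers)) {
    write_layer(bundle$layers[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_matrix_bundle
#' @export
read_matrix_bundle <- function(dir) {
  files <- list.files(dir, pattern = "^(NGT|DP|GQ|AF)\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) abort("no layer files found")
  layers <- lapply(files, read_layer)
  names(layers) <- sub("\\.tsv$", "", basename(files))
  for (nm in intersect(c("NGT", "DP", "GQ"), names(layers))) {
    storage.mode(layers[[nm]]) <- "integer"
  }
  do.call(mpt_bundle, setNames(layers, tolower(names(layers))))
}

#' Write / read a cells-by-amplicons count matrix
#'
#' Same dialect as [write_matrix_bundle()], a single `COUNT` layer.
#'
#' @param counts non-negative matrix, cells in rows, with dimnames.
#' @param path output file.
#' @export
write_count_matrix <- function(counts, path) {
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  write_layer(counts, path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) read_layer(path)

write_layer <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("layer must have cell and column ids")
  }
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

read_layer <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA")
  if (!nrow(df)) abort(paste0("empty layer file: ", path))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("malformed layer file ", path, " (line ",
                 probs$row[1], ")"))
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) abort("duplicate cell ids in layer file")
  m <- as.matrix(df[-1])
  rownames(m) <- ids
  m
}

#' Locate variants inside panel amplicons
#'
#' Applies the coordinate conversion rule: a 1-based VCF position `pos`
#' lies inside the 0-based half-open amplicon `[start, end)` iff
#' `start < pos <= end`.
#'
#' @param variants tibble with `chrom` and `pos` (1-based).
#' @param panel tibble from [read_panel_bed()].
#' @return `variants` with an `amplicon_id` column (`NA` when uncovered).
#' @export
locate_variants <- function(variants, panel) {
  amp <- vapply(seq_len(nrow(variants)), function(i) {
    hit <- which(panel$chrom == variants$chrom[i] &
                   panel$start < variants$pos[i] &
                   variants$pos[i] <= panel$end)
    if (length(hit)) panel$amplicon_id[hit[1]] else NA_character_
  }, character(1))
  variants$amplicon_id <- amp
  variants
}
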