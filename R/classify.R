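#' Read a known-variant catalog from VCF or TSV
#'
#' Accepts either a VCF (CHROM/POS/REF/ALT, 1-based; multi-allelic rows are
#' split into one record per alternate allele) or a three-column TSV
#' (`contig`, 1-based `position`, `alt` base). Positions are converted to
#' the package's internal 0-based convention.
#'
#' @param path Path to a `.vcf` or a TSV file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A tibble of class `known_variants` with columns `contig`, `pos`
#'   (0-based), `ref` (may be `NA` for TSV input), `alt`.
#' @export
read_known_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    abort(sprintf("malformed VCF: %s", conditionMessage(e)),
                          class = "ivt_input_error")
                  })
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fx) == 0L) {
      out <- tibble(contig = character(), pos = integer(),
                    ref = character(), alt = character())
    } else {
      out <- tibble(contig = fx$CHROM, pos = as.integer(fx$POS) - 1L,
                    ref = fx$REF, alt = fx$ALT) |>
        tidyr::separate_longer_delim("alt", delim = ",")
    }
  } else {
    raw <- tryCatch(
      readr::read_tsv(path, show_col_types = FALSE,
                      col_names = c("contig", "position", "alt"),
                      comment = "#"),
      error = function(e) {
        abort(sprintf("malformed known-variant TSV: %s",
                      conditionMessage(e)), class = "ivt_input_error")
      })
    # tolerate a header row
    if (nrow(raw) > 0L && is.na(suppressWarnings(as.integer(raw$position[1])))) {
      raw <- raw[-1L, ]
    }
    pos1 <- suppressWarnings(as.integer(raw$position))
    if (any(is.na(pos1))) {
      abort("known-variant TSV column 2 must be 1-based integer positions",
            class = "ivt_input_error")
    }
    out <- tibble(contig = raw$contig, pos = pos1 - 1L,
                  ref = NA_character_, alt = toupper(raw$alt))
  }
  class(out) <- c("known_variants", class(out))
  out
}

#' Partition flagged mismatches into three bins
#'
#' Every record receives exactly one bin, with precedence
#' `known_variant > low_confidence_kmer > novel`:
#'
#' 1. `known_variant` — the record matches the known-variant catalog, either
#'    by `(contig, position, alt base)` (`match_mode = "pos_alt"`, default)
#'    or by position alone (`"pos"`; useful when the catalog's alleles are
#'    reported on the opposite strand).
#' 2. `low_confidence_kmer` — the reference k-mer centered on the position
#'    is in the low-confidence set.
#' 3. `novel` — everything else.
#'
#' The bins are disjoint and exhaustive, so their counts always sum to the
#' number of input records.
#'
#' @param records An `ivt_variants` tibble.
#' @param known A `known_variants` tibble (or `NULL` for none).
#' @param lowconf A `kmer_confidence_set` (or `NULL` for none).
#' @param reference Reference sequences, needed when `lowconf` is supplied.
#' @param match_mode `"pos_alt"` or `"pos"`.
#' @return A tibble of class `ivt_classified`: the record columns plus
#'   `bin`; the match mode is kept as an attribute.
#' @export
classify_variants <- function(records, known = NULL, lowconf = NULL,
                              reference = NULL,
                              match_mode = c("pos_alt", "pos")) {
  match_mode <- match.arg(match_mode)
  out <- as_tibble(records)
  n <- nrow(out)
  is_known <- rep(FALSE, n)
  if (!is.null(known) && nrow(known) > 0L) {
    if (match_mode == "pos_alt") {
      is_known <- var_key(out$contig, out$pos, out$alt) %in%
        var_key(known$contig, known$pos, known$alt)
    } else {
      is_known <- pos_key(out$contig, out$pos) %in%
        pos_key(known$contig, known$pos)
    }
  }
  is_lowconf <- rep(FALSE, n)
  if (!is.null(lowconf) && n > 0L) {
    if (is.null(reference)) {
      abort("`reference` is required for low-confidence context lookup",
            class = "ivt_input_error")
    }
    is_lowconf <- in_low_confidence(reference, out$contig, out$pos, lowconf)
  }
  out$bin <- dplyr::case_when(
    is_known ~ "known_variant",
    is_lowconf ~ "low_confidence_kmer",
    .default = "novel"
  )
  attr(out, "match_mode") <- match_mode
  class(out) <- c("ivt_classified", class(out))
  out
}

#' Summarise a classified catalog
#'
#' @param x An `ivt_classified` tibble.
#' @param ... Unused.
#' @return A one-row tibble with `n_total`, `n_known`, `n_lowconf`,
#'   `n_novel` and the match mode.
#' @export
glance.ivt_classified <- function(x, ...) {
  tibble(
    n_total = nrow(x),
    n_known = sum(x$bin == "known_variant"),
    n_lowconf = sum(x$bin == "low_confidence_kmer"),
    n_novel = sum(x$bin == "novel"),
    match_mode = attr(x, "match_mode") %||% NA_character_
  )
}

#' Cross-sample mismatch overlap table
#'
#' For each sample, counts its variants by the number of *other* samples
#' that also contain them (variant identity is `(contig, position, alt)`).
#' A sample's counts sum to its catalog size, and the "shared with all
#' others" count is the size of the global intersection, identical for every
#' row.
#'
#' @param catalogs Either a named list of `ivt_variants`/`ivt_classified`
#'   tibbles (one per sample) or a single tibble with a `sample` column.
#' @return A tibble of class `ivt_overlap` in long form: `sample`,
#'   `n_other_samples` (0 .. n-1), `n_variants`.
#' @export
overlap_table <- function(catalogs) {
  if (inherits(catalogs, "data.frame")) {
    if (!"sample" %in% names(catalogs) || any(is.na(catalogs$sample))) {
      abort("a single-table input needs a complete `sample` column",
            class = "ivt_input_error")
    }
    catalogs <- split(as_tibble(catalogs), catalogs$sample)
  }
  if (length(catalogs) < 2L) {
    abort("overlap accounting needs at least two samples",
          class = "ivt_input_error")
  }
  if (is.null(names(catalogs)) || anyDuplicated(names(catalogs))) {
    abort("samples must carry unique names", class = "ivt_input_error")
  }
  n_samples <- length(catalogs)
  keys <- lapply(catalogs, function(cat) {
    unique(var_key(cat$contig, cat$pos, cat$alt))
  })
  membership <- table(unlist(keys, use.names = FALSE))  # key -> #samples
  out <- purrr::imap_dfr(keys, function(kk, nm) {
    shared <- as.integer(membership[kk]) - 1L
    tibble(sample = nm,
           n_other_samples = factor(shared, levels = 0:(n_samples - 1L))) |>
      count(.data$sample, .data$n_other_samples, name = "n_variants",
            .drop = FALSE) |>
      mutate(n_other_samples = as.integer(as.character(.data$n_other_samples)))
  })
  class(out) <- c("ivt_overlap", class(out))
  out
}

#' @export
#' @rdname overlap_table
#' @param x An `ivt_overlap` table.
#' @param ... Unused.
tidy.ivt_overlap <- function(x, ...) {
  tidyr::pivot_wider(as_tibble(x), names_from = "n_other_samples",
                     values_from = "n_variants", names_prefix = "shared_with_")
}

#' Write a classified catalog and its per-bin BED tracks
#'
#' @param classified An `ivt_classified` tibble.
#' @param out_prefix Path prefix: writes `<prefix>_classified.tsv` plus one
#'   `<prefix>_<bin>.bed` per bin.
#' @return Invisibly, the paths written.
#' @export
write_classified <- function(classified, out_prefix) {
  tsv <- sprintf("%s_classified.tsv", out_prefix)
  readr::write_tsv(as_tibble(classified), tsv)
  beds <- vapply(unique(classified$bin), function(b) {
    recs <- classified[classified$bin == b, ]
    path <- sprintf("%s_%s.bed", out_prefix, b)
    gr <- GenomicRanges::GRanges(
      recs$contig, IRanges::IRanges(start = recs$pos + 1L, width = 1L),
      name = sprintf("%s>%s|%.4f", recs$ref, recs$alt, recs$fraction))
    rtracklayer::export(sort(gr), path, format = "BED")
    path
  }, character(1))
  invisible(c(tsv, beds))
}
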