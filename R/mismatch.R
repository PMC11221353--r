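#' Flag candidate mismatch positions from a pileup
#'
#' Emits one record per (position, alternate base) at every reference
#' position with depth at or above `min_coverage` and at least one called
#' nucleotide differing from the reference. The occurrence fraction is the
#' alt-base count divided by the number of canonical bases **plus deletions**
#' at the location (the pileup `depth`), so deletions dilute substitution
#' fractions but are never themselves emitted as variants.
#'
#' With `aggregate = TRUE` a single record per position is emitted instead,
#' whose fraction is the total non-reference substitution count over the same
#' denominator and whose `alt` is the most abundant alternate base; this mode
#' exists for sensitivity analysis of the per-alt default.
#'
#' @param pileup An `ivt_pileup` tibble.
#' @param min_coverage Minimum depth for a position to be considered
#'   (default 10).
#' @param sample Optional sample label carried into the records.
#' @param aggregate Logical; aggregate all alternate bases per position.
#' @return A tibble of class `ivt_variants` with columns `contig`, `pos`
#'   (0-based), `ref`, `alt`, `alt_count`, `denom`, `fraction`, `sample`.
#' @export
call_candidates <- function(pileup, min_coverage = 10L, sample = NA_character_,
                            aggregate = FALSE) {
  if (length(min_coverage) != 1L || is.na(min_coverage) || min_coverage < 1L) {
    abort("`min_coverage` must be a single count >= 1",
          class = "ivt_config_error")
  }
  covered <- filter(pileup, .data$depth >= min_coverage,
                    .data$ref %in% DNA_BASES)
  long <- covered |>
    tidyr::pivot_longer(cols = dplyr::all_of(DNA_BASES), names_to = "alt",
                        values_to = "alt_count") |>
    filter(.data$alt != .data$ref, .data$alt_count > 0L)
  if (aggregate) {
    long <- long |>
      group_by(.data$contig, .data$pos, .data$ref, .data$depth) |>
      summarise(alt = .data$alt[which.max(.data$alt_count)],
                alt_count = sum(.data$alt_count), .groups = "drop")
  }
  out <- long |>
    mutate(denom = .data$depth,
           fraction = .data$alt_count / .data$denom,
           sample = sample) |>
    select("contig", "pos", "ref", "alt", "alt_count", "denom",
           "fraction", "sample") |>
    arrange(.data$contig, .data$pos, .data$alt)
  class(out) <- c("ivt_variants", class(out))
  out
}

#' Apply the occurrence-threshold sweep to a mismatch catalog
#'
#' Sequentially filters the records at each occurrence threshold (percent of
#' reads at the location carrying the alternate base). The comparison is
#' inclusive (`fraction >= threshold/100`), so a record exactly at the cutoff
#' survives. The retained sets are nested: every record at a higher
#' threshold is present at every lower one.
#'
#' @param candidates An `ivt_variants` tibble from [call_candidates()].
#' @param thresholds Strictly increasing percentages in `(0, 100]`
#'   (default `c(30, 40, 50, 60, 70, 80, 95)`).
#' @return A tibble of class `ivt_threshold_sweep`: the record columns plus
#'   `threshold`, one row per record per threshold at which it is retained.
#'   The threshold list is kept in the `thresholds` attribute.
#' @export
threshold_sweep <- function(candidates,
                            thresholds = c(30, 40, 50, 60, 70, 80, 95)) {
  if (length(thresholds) == 0L) {
    abort("`thresholds` must be non-empty", class = "ivt_config_error")
  }
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds > 100)) {
    abort("`thresholds` must be strictly increasing percentages in (0, 100]",
          class = "ivt_config_error")
  }
  out <- purrr::map_dfr(thresholds, function(t) {
    hits <- filter(candidates, .data$fraction >= t / 100)
    if (nrow(hits) == 0L) return(mutate(candidates[0, ], threshold = t))
    mutate(hits, threshold = t)
  })
  out <- out[, c("threshold", setdiff(names(out), "threshold"))]
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ivt_threshold_sweep", class(out))
  out
}

#' Extract the variant set retained at one threshold
#'
#' @param sweep An `ivt_threshold_sweep`.
#' @param threshold One of the sweep's thresholds (percent).
#' @return An `ivt_variants` tibble.
#' @export
variants_at <- function(sweep, threshold) {
  ths <- attr(sweep, "thresholds")
  if (!threshold %in% ths) {
    abort(sprintf("threshold %s is not in the sweep (%s)",
                  threshold, paste(ths, collapse = ", ")),
          class = "ivt_config_error")
  }
  out <- as_tibble(sweep[sweep$threshold == threshold,
                         setdiff(names(sweep), "threshold")])
  class(out) <- c("ivt_variants", class(out))
  out
}

#' Write one BED track per occurrence threshold
#'
#' Each retained record becomes a single-base BED feature (0-based half-open,
#' `start = pos`, `end = pos + 1`) whose name encodes `ref>alt|fraction`,
#' suitable for IGV browsing. Files are sorted by contig then start, and an
#' empty threshold bin still yields a valid (empty) BED file.
#'
#' @param sweep An `ivt_threshold_sweep`.
#' @param out_prefix Path prefix; files are written as
#'   `<out_prefix>_t<threshold>.bed`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_threshold_beds <- function(sweep, out_prefix) {
  ths <- attr(sweep, "thresholds")
  paths <- vapply(ths, function(t) {
    recs <- variants_at(sweep, t)
    path <- sprintf("%s_t%g.bed", out_prefix, t)
    gr <- GenomicRanges::GRanges(
      recs$contig, IRanges::IRanges(start = recs$pos + 1L, width = 1L),
      name = sprintf("%s>%s|%.4f", recs$ref, recs$alt, recs$fraction))
    rtracklayer::export(sort(gr), path, format = "BED")
    path
  }, character(1))
  invisible(paths)
}

#' Read a mismatch BED track back into records
#'
#' Inverse of [write_threshold_beds()] for a single file: recovers `contig`,
#' `pos`, `ref`, `alt` and `fraction` from the single-base features and their
#' name field.
#'
#' @param path A BED file written by [write_threshold_beds()].
#' @return An `ivt_variants`-shaped tibble (without counts).
#' @export
read_mismatch_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), fraction = double())
    return(out)
  }
  nm <- as.character(gr$name)
  parts <- stringr::str_match(nm, "^([ACGT])>([ACGT])\\|([0-9.]+)$")
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         pos = GenomicRanges::start(gr) - 1L,
         ref = parts[, 2], alt = parts[, 3],
         fraction = as.numeric(parts[, 4]))
}

#' Write and read the master mismatch catalog TSV
#'
#' @param variants An `ivt_variants` tibble.
#' @param path File path.
#' @export
write_catalog <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$pos <- as.integer(out$pos)
  class(out) <- c("ivt_variants", class(out))
  out
}
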