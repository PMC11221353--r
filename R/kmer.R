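#' Profile per-k-mer base quality from an aligned biological sample
#'
#' For every reference k-mer context observed by the reads, accumulates the
#' basecaller's phred quality. The profile is indexed by **reference**-
#' sequence k-mers (not read sequence), so membership of a genomic position
#' is stable across samples. Two attribution modes exist because "the quality
#' of a 9-mer" is ambiguous:
#'
#' * `"center"` (default): the quality of the read base aligned to the
#'   context's center position. Variant positions are classified by their
#'   centered context, so this is the attribution the classification uses.
#' * `"all"`: the mean quality of the nine read bases aligned to the nine
#'   context positions, counted once per read covering the full window with
#'   aligned (non-deleted) bases.
#'
#' The profile should come from a biological DRS sample, not an IVT one:
#' the low-confidence set is meant to capture basecaller uncertainty on
#' native RNA.
#'
#' @param alignments An `ivt_alignments` tibble with quality strings.
#' @param reference An `ivt_reference` or named DNAStringSet.
#' @param k Odd context length, default 9.
#' @param mode `"center"` or `"all"` (see above).
#' @return A tibble of class `kmer_quality_profile` with columns `kmer`,
#'   `mean_quality`, `n_obs`; attributes `k` and `mode`.
#' @export
profile_kmer_quality <- function(alignments, reference, k = 9L,
                                 mode = c("center", "all")) {
  mode <- match.arg(mode)
  if (k < 3L || k %% 2L == 0L) {
    abort("`k` must be an odd integer >= 3", class = "ivt_config_error")
  }
  if (any(is.na(alignments$qual)) || any(alignments$qual == "*")) {
    abort("alignments are missing base-quality strings",
          class = "ivt_input_error")
  }
  aln <- filter_primary(alignments)
  ex <- expand_alignments(aln)
  ex <- filter(ex, .data$base != "-")

  seqs <- as.character(ref_seqs(reference))
  kmers_by_contig <- lapply(seqs, contig_kmers, k = k)

  if (mode == "center") {
    ex$kmer <- NA_character_
    for (cg in unique(ex$contig)) {
      sel <- ex$contig == cg
      ex$kmer[sel] <- kmers_by_contig[[cg]][ex$pos[sel] + 1L]
    }
    obs <- filter(ex, !is.na(.data$kmer))
  } else {
    flank <- (k - 1L) %/% 2L
    # rolling mean of quality over windows of k contiguous aligned bases,
    # one observation per full window per read
    obs <- ex |>
      arrange(.data$read, .data$pos) |>
      group_by(.data$read, .data$contig) |>
      mutate(
        roll_q = if (dplyr::n() < k) rep(NA_real_, dplyr::n()) else
          as.numeric(stats::filter(.data$qual, rep(1 / k, k))),
        span = dplyr::lead(.data$pos, flank) - dplyr::lag(.data$pos, flank)
      ) |>
      ungroup() |>
      filter(!is.na(.data$roll_q), .data$span == k - 1L) |>
      mutate(qual = .data$roll_q)
    obs$kmer <- NA_character_
    for (cg in unique(obs$contig)) {
      sel <- obs$contig == cg
      obs$kmer[sel] <- kmers_by_contig[[cg]][obs$pos[sel] + 1L]
    }
    obs <- filter(obs, !is.na(.data$kmer))
  }

  out <- obs |>
    group_by(.data$kmer) |>
    summarise(mean_quality = mean(.data$qual), n_obs = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$kmer)
  attr(out, "k") <- as.integer(k)
  attr(out, "mode") <- mode
  class(out) <- c("kmer_quality_profile", class(out))
  out
}

#' Select the low-confidence k-mer set from a quality profile
#'
#' Takes the lowest quantile (default the lowest quartile) of profiled
#' k-mers by mean quality, computed over k-mer *types* (each k-mer counted
#' once, not weighted by occurrences). The cutoff is the largest observed
#' mean quality whose cumulative fraction of types does not exceed the
#' quantile; membership uses an inclusive `<=` comparison, so ties at the
#' cutoff are all included. With all-distinct means and `n` divisible by 4
#' this selects exactly `n/4` k-mers at the default quantile; with heavily
#' tied means (e.g. a two-level quality scheme) it selects the whole
#' low-quality tie class and nothing above it. If even the smallest mean
#' carries more than the quantile's mass (all means identical, say), the
#' smallest mean becomes the cutoff and its full tie class is selected.
#'
#' @param profile A `kmer_quality_profile`.
#' @param quantile Fraction in (0, 1); default 0.25 (lowest quartile).
#' @return A tibble of class `kmer_confidence_set` with columns `kmer`,
#'   `mean_quality`; attributes `k`, `cutoff`, `quantile`.
#' @export
select_low_confidence <- function(profile, quantile = 0.25) {
  if (length(quantile) != 1L || is.na(quantile) || quantile <= 0 ||
      quantile >= 1) {
    abort("`quantile` must lie strictly in (0, 1)", class = "ivt_config_error")
  }
  if (nrow(profile) == 0L) {
    abort("empty k-mer quality profile", class = "ivt_input_error")
  }
  mq <- profile$mean_quality
  vals <- sort(unique(mq))
  cum_frac <- vapply(vals, function(v) mean(mq <= v), double(1))
  eligible <- vals[cum_frac <= quantile]
  cutoff <- if (length(eligible) > 0L) max(eligible) else vals[1L]
  out <- profile |>
    filter(.data$mean_quality <= cutoff) |>
    select("kmer", "mean_quality") |>
    arrange(.data$kmer)
  attr(out, "k") <- attr(profile, "k")
  attr(out, "cutoff") <- cutoff
  attr(out, "quantile") <- quantile
  class(out) <- c("kmer_confidence_set", class(out))
  out
}

#' Test whether positions fall in low-confidence k-mer contexts
#'
#' Looks up the reference k-mer centered on each position in the
#' low-confidence set. Positions closer than `(k-1)/2` bases to a contig
#' edge have no full context; they return `FALSE` and are reported via a
#' message so the caller can audit them.
#'
#' @param reference An `ivt_reference` or named DNAStringSet.
#' @param contig,pos Parallel vectors of contig names and 0-based positions.
#' @param set A `kmer_confidence_set`.
#' @return Logical vector, one element per position.
#' @export
in_low_confidence <- function(reference, contig, pos, set) {
  seqs <- as.character(ref_seqs(reference))
  unknown <- setdiff(unique(contig), names(seqs))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown contig(s): %s", paste(unknown, collapse = ", ")),
          class = "ivt_input_error")
  }
  k <- attr(set, "k") %||% unique(nchar(set$kmer))
  if (length(k) != 1L) {
    abort("low-confidence set has inconsistent k-mer lengths",
          class = "ivt_input_error")
  }
  flank <- (k - 1L) %/% 2L
  out <- logical(length(pos))
  n_edge <- 0L
  for (cg in unique(contig)) {
    sel <- which(contig == cg)
    len <- nchar(seqs[[cg]])
    ok <- pos[sel] >= flank & pos[sel] <= len - flank - 1L
    n_edge <- n_edge + sum(!ok)
    if (any(ok)) {
      ctx <- substring(seqs[[cg]], pos[sel[ok]] + 1L - flank,
                       pos[sel[ok]] + 1L + flank)
      out[sel[ok]] <- ctx %in% set$kmer
    }
  }
  if (n_edge > 0L) {
    inform(sprintf(
      "%d position(s) within %d bases of a contig edge have no full %d-mer context; treated as not low-confidence",
      n_edge, flank, k))
  }
  out
}

#' Write and read a low-confidence k-mer set
#'
#' Two-column TSV (`kmer`, `mean_quality`) preceded by comment lines
#' carrying `k`, the quantile and the phred cutoff, so a set can be shared
#' between analyses without recomputation.
#'
#' @param set A `kmer_confidence_set`.
#' @param path File path.
#' @export
write_kmer_set <- function(set, path) {
  hdr <- sprintf("# k=%d quantile=%g cutoff=%.6g",
                 attr(set, "k"), attr(set, "quantile"), attr(set, "cutoff"))
  readr::write_lines(hdr, path)
  readr::write_tsv(as_tibble(set), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  hdr <- readr::read_lines(path, n_max = 1L)
  m <- stringr::str_match(hdr, "k=(\\d+) quantile=([0-9.]+) cutoff=([0-9.eE+-]+)")
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "k") <- as.integer(m[2])
  attr(out, "quantile") <- as.numeric(m[3])
  attr(out, "cutoff") <- as.numeric(m[4])
  class(out) <- c("kmer_confidence_set", class(out))
  out
}
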