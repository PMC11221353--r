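#' Decide candidate RNA-modification sites from paired evidence
#'
#' Encodes the decision procedure that combines the biological DRS mismatch
#' state of a position with the IVT negative control:
#'
#' * IVT mismatches the reference at the chosen occurrence threshold →
#'   `exclude` — the baseline itself is unreliable there (genomic variant,
#'   IVT/basecalling artifact), regardless of mismatch category.
#' * IVT has no usable coverage → `needs_orthogonal` — no baseline exists;
#'   orthogonal evidence (e.g. Sanger sequencing of gDNA) is required.
#' * IVT matches the reference with coverage and the biological sample
#'   mismatches → `candidate` — the signature consistent with an RNA
#'   modification.
#' * Neither sample mismatches → `no_evidence`.
#'
#' @param states A tibble with logical columns `bio_mismatch`,
#'   `ivt_mismatch`, `ivt_covered` (plus any identifier columns, carried
#'   through). `ivt_mismatch` implies `ivt_covered`.
#' @return The input tibble with `verdict` and `reason` columns appended.
#' @export
decide_sites <- function(states) {
  req <- c("bio_mismatch", "ivt_mismatch", "ivt_covered")
  missing_cols <- setdiff(req, names(states))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`states` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ivt_input_error")
  }
  if (any(states$ivt_mismatch & !states$ivt_covered)) {
    abort("invalid state: ivt_mismatch implies ivt_covered",
          class = "ivt_input_error")
  }
  mutate(as_tibble(states),
    verdict = dplyr::case_when(
      .data$ivt_mismatch ~ "exclude",
      !.data$ivt_covered ~ "needs_orthogonal",
      .data$bio_mismatch ~ "candidate",
      .default = "no_evidence"
    ),
    reason = dplyr::case_when(
      .data$ivt_mismatch ~ "ivt_baseline_mismatch",
      !.data$ivt_covered ~ "no_ivt_baseline",
      .data$bio_mismatch ~ "bio_only_mismatch",
      .default = "no_mismatch"
    )
  )
}

#' Apply the decision procedure across a biological mismatch catalog
#'
#' Every biological mismatch position at the stated occurrence threshold
#' receives a verdict: its IVT mismatch state is looked up in the threshold
#' sweep of the IVT (or pooled panIVT) catalog, and IVT coverage in the IVT
#' pileup. Decisions are made per position — any alternate base at or above
#' the threshold makes the position mismatched.
#'
#' @param bio_catalog `ivt_variants` from the biological sample
#'   ([call_candidates()] on its pileup).
#' @param ivt_sweep `ivt_threshold_sweep` of the IVT catalog; must contain
#'   `threshold`.
#' @param ivt_pileup `ivt_pileup` of the IVT data, for the coverage state.
#' @param threshold IVT occurrence threshold in percent; must be one of the
#'   sweep's thresholds.
#' @param bio_threshold Occurrence threshold applied to the biological
#'   catalog; defaults to `threshold`.
#' @param min_coverage Minimum IVT depth for a usable baseline (default 10).
#' @param bed_out Optional path: writes the candidate sites as a BED track.
#' @return A tibble of class `ivt_decisions`: `contig`, `pos`, `verdict`,
#'   `reason`, `bio_fraction`, `ivt_fraction`, `ivt_depth`.
#' @export
apply_decisions <- function(bio_catalog, ivt_sweep, ivt_pileup, threshold,
                            bio_threshold = threshold, min_coverage = 10L,
                            bed_out = NULL) {
  ths <- attr(ivt_sweep, "thresholds")
  if (!threshold %in% ths) {
    abort(sprintf("threshold %s is not in the IVT sweep (%s)",
                  threshold, paste(ths, collapse = ", ")),
          class = "ivt_config_error")
  }
  bio_hits <- filter(as_tibble(bio_catalog),
                     .data$fraction >= bio_threshold / 100)
  if (nrow(bio_hits) == 0L) {
    out <- tibble(contig = character(), pos = integer(), verdict = character(),
                  reason = character(), bio_fraction = double(),
                  ivt_fraction = double(), ivt_depth = integer())
    class(out) <- c("ivt_decisions", class(out))
    if (!is.null(bed_out)) write_candidate_bed(out, bed_out)
    return(out)
  }
  bio_pos <- bio_hits |>
    group_by(.data$contig, .data$pos) |>
    summarise(bio_fraction = max(.data$fraction), .groups = "drop")
  ivt_hits <- variants_at(ivt_sweep, threshold) |>
    distinct(.data$contig, .data$pos) |>
    mutate(ivt_mismatch = TRUE)
  ivt_cov <- ivt_pileup |>
    select("contig", "pos", ivt_depth = "depth")
  ivt_frac <- ivt_pileup |>
    mutate(ivt_fraction = ifelse(
      .data$depth > 0,
      (.data$A + .data$C + .data$G + .data$T -
         ifelse(.data$ref == "A", .data$A, 0L) -
         ifelse(.data$ref == "C", .data$C, 0L) -
         ifelse(.data$ref == "G", .data$G, 0L) -
         ifelse(.data$ref == "T", .data$T, 0L)) / .data$depth,
      NA_real_)) |>
    select("contig", "pos", "ivt_fraction")

  states <- bio_pos |>
    left_join(ivt_hits, by = c("contig", "pos")) |>
    left_join(ivt_cov, by = c("contig", "pos")) |>
    left_join(ivt_frac, by = c("contig", "pos")) |>
    mutate(
      ivt_depth = dplyr::coalesce(.data$ivt_depth, 0L),
      ivt_mismatch = dplyr::coalesce(.data$ivt_mismatch, FALSE),
      ivt_covered = .data$ivt_depth >= min_coverage,
      # a flagged IVT mismatch is only trusted where the baseline is covered
      ivt_mismatch = .data$ivt_mismatch & .data$ivt_covered,
      bio_mismatch = TRUE
    )
  out <- decide_sites(states) |>
    select("contig", "pos", "verdict", "reason", "bio_fraction",
           "ivt_fraction", "ivt_depth") |>
    arrange(.data$contig, .data$pos)
  class(out) <- c("ivt_decisions", class(out))
  n_by <- table(out$verdict)
  inform(sprintf("site decisions at %g%%: %s", threshold,
                 paste(sprintf("%s=%d", names(n_by), as.integer(n_by)),
                       collapse = ", ")))
  if (!is.null(bed_out)) write_candidate_bed(out, bed_out)
  out
}

write_candidate_bed <- function(decisions, path) {
  cand <- decisions[decisions$verdict == "candidate", ]
  gr <- GenomicRanges::GRanges(
    cand$contig, IRanges::IRanges(start = cand$pos + 1L, width = 1L),
    name = sprintf("candidate|%.4f", cand$bio_fraction))
  rtracklayer::export(sort(gr), path, format = "BED")
  invisible(path)
}

#' Write the full decision table
#'
#' @param decisions An `ivt_decisions` tibble.
#' @param path TSV output path.
#' @export
write_decisions <- function(decisions, path) {
  readr::write_tsv(as_tibble(decisions), path)
  invisible(path)
}
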