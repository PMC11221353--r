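#' Build a per-position nucleotide/deletion pileup
#'
#' Walks every primary alignment's CIGAR and accumulates, for each reference
#' position with at least one spanning read, the counts of A/C/G/T read bases
#' and of reads carrying a deletion at that position. Insertions relative to
#' the reference occupy no reference coordinate and are ignored; soft-clipped
#' bases are skipped. Counting is strand-unaware on the reference forward
#' strand (DRS reads are sense-strand). No mapping- or base-quality filter is
#' applied at this stage.
#'
#' The row invariant `A + C + G + T + del == depth` holds at every position,
#' so `depth` is exactly the deletion-aware mismatch denominator (canonical
#' bases plus deletions).
#'
#' @param alignments An `ivt_alignments` tibble (from [simulate_reads()] or
#'   [read_alignments()]). Rows with secondary/supplementary/unmapped flags
#'   are dropped if present.
#' @param reference An `ivt_reference` or named [Biostrings::DNAStringSet];
#'   every aligned contig must be present.
#' @return A tibble of class `ivt_pileup` with columns `contig`, `pos`
#'   (0-based), `ref`, `A`, `C`, `G`, `T`, `del`, `depth`, one row per
#'   covered position, sorted by contig then position.
#' @export
#' @examples
#' cfg <- sim_config(n_contigs = 1, contig_length = 2000, n_genes = 3,
#'                   reads_per_sample = 40, read_length_mean = 600, seed = 3)
#' ref <- generate_reference(cfg)
#' truth <- simulate_truth(ref, cfg)
#' reads <- simulate_reads(ref, truth, "ivt", cfg)
#' head(build_pileup(reads, ref))
build_pileup <- function(alignments, reference) {
  seqs <- ref_seqs(reference)
  missing_ctg <- setdiff(unique(alignments$contig), names(seqs))
  if (length(missing_ctg) > 0L) {
    abort(sprintf("alignments reference contig(s) absent from the reference: %s",
                  paste(missing_ctg, collapse = ", ")),
          class = "ivt_input_error")
  }
  aln <- filter_primary(alignments)
  if (nrow(aln) == 0L) return(empty_pileup())

  ex <- expand_alignments(aln)
  counts <- ex |>
    count(.data$contig, .data$pos, .data$base, name = "n") |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L)
  for (b in c(DNA_BASES, "-")) {
    if (!b %in% names(counts)) counts[[b]] <- 0L
  }
  counts <- counts |>
    rename(del = "-") |>
    mutate(depth = .data$A + .data$C + .data$G + .data$T + .data$del) |>
    arrange(.data$contig, .data$pos)

  chars <- ref_chars(reference)
  counts$ref <- NA_character_
  for (cg in unique(counts$contig)) {
    sel <- counts$contig == cg
    counts$ref[sel] <- chars[[cg]][counts$pos[sel] + 1L]
  }
  out <- counts[, c("contig", "pos", "ref", "A", "C", "G", "T", "del", "depth")]
  class(out) <- c("ivt_pileup", class(out))
  out
}

empty_pileup <- function() {
  out <- tibble(contig = character(), pos = integer(), ref = character(),
                A = integer(), C = integer(), G = integer(), T = integer(),
                del = integer(), depth = integer())
  class(out) <- c("ivt_pileup", class(out))
  out
}

# Drop unmapped / secondary / supplementary alignments (samtools -F 4 -F 256
# -F 2048); simulated reads are all flag 0 and pass unchanged.
filter_primary <- function(alignments) {
  if (!"flag" %in% names(alignments)) return(alignments)
  keep <- bitwAnd(alignments$flag, 4L + 256L + 2048L) == 0L
  alignments[keep, , drop = FALSE]
}

# One row per (read, reference position): aligned base or "-" for deletion.
# Uses GenomicAlignments' CIGAR decomposition; M/=/X consume ref+query,
# D/N consume ref only (N positions are skipped entirely), I/S query only.
expand_alignments <- function(aln) {
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  nop <- lengths(ops)
  ridx <- rep.int(seq_len(nrow(aln)), nop)
  op <- unlist(ops, use.names = FALSE)
  len <- unlist(lens, use.names = FALSE)

  consumes_ref <- op %in% c("M", "=", "X", "D", "N")
  consumes_qry <- op %in% c("M", "=", "X", "I", "S")
  ref_off <- ave_cumsum_excl(ifelse(consumes_ref, len, 0L), ridx)
  qry_off <- ave_cumsum_excl(ifelse(consumes_qry, len, 0L), ridx)

  keep_m <- op %in% c("M", "=", "X")
  keep_d <- op == "D"
  keep <- keep_m | keep_d
  op_k <- op[keep]; len_k <- len[keep]
  ridx_k <- ridx[keep]; ref_k <- ref_off[keep]; qry_k <- qry_off[keep]

  n_bases <- sum(len_k)
  if (n_bases == 0L) {
    return(tibble(read = integer(), contig = character(), pos = integer(),
                  base = character(), qual = integer()))
  }
  per_base_read <- rep.int(ridx_k, len_k)
  within <- sequence(len_k) - 1L
  refpos <- aln$pos[per_base_read] + rep.int(ref_k, len_k) + within
  is_m <- rep.int(op_k %in% c("M", "=", "X"), len_k)
  qpos <- rep.int(qry_k, len_k) + within + 1L   # 1-based query index, M only

  # global character pools with per-read offsets: O(total bases) extraction
  seq_pool <- strsplit(paste0(aln$seq, collapse = ""), "", fixed = TRUE)[[1]]
  qual_pool <- utf8ToInt(paste0(aln$qual, collapse = "")) - 33L
  read_off <- c(0L, cumsum(nchar(aln$seq)))[seq_len(nrow(aln))]

  base <- rep("-", n_bases)
  qual <- rep(NA_integer_, n_bases)
  if (any(is_m)) {
    gidx <- read_off[per_base_read[is_m]] + qpos[is_m]
    base[is_m] <- seq_pool[gidx]
    qual[is_m] <- qual_pool[gidx]
  }
  tibble(read = per_base_read, contig = aln$contig[per_base_read],
         pos = as.integer(refpos), base = base, qual = qual)
}

# exclusive per-group cumulative sum; groups are contiguous runs of `g`
ave_cumsum_excl <- function(x, g) {
  if (length(x) == 0L) return(integer(0))
  cs <- cumsum(x)
  first_idx <- which(!duplicated(g))
  grp_len <- diff(c(first_idx, length(x) + 1L))
  before <- cs[first_idx] - x[first_idx]
  as.integer((cs - x) - rep.int(before, grp_len))
}

#' Merge pileups across samples
#'
#' Sums every count field position-wise across the input pileups; the result
#' is the pileup of the pooled read set (the "panIVT" construction). Merging
#' is associative and commutative, and pooled depth at every position is at
#' least the maximum single-sample depth.
#'
#' @param ... `ivt_pileup` tibbles, or a single list of them.
#' @return An `ivt_pileup` tibble.
#' @export
merge_pileups <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) &&
      !inherits(inputs[[1]], "data.frame")) {
    inputs <- inputs[[1]]
  }
  if (length(inputs) == 0L) abort("no pileups to merge",
                                  class = "ivt_input_error")
  stacked <- bind_rows(inputs)
  if (nrow(stacked) == 0L) return(empty_pileup())
  refs <- distinct(stacked, .data$contig, .data$pos, .data$ref)
  dup <- refs |> count(.data$contig, .data$pos) |> filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("conflicting reference base at %d position(s); pileups do not share a reference",
                  nrow(dup)), class = "ivt_reference_mismatch")
  }
  out <- stacked |>
    group_by(.data$contig, .data$pos, .data$ref) |>
    summarise(across(c("A", "C", "G", "T", "del", "depth"), sum),
              .groups = "drop") |>
    arrange(.data$contig, .data$pos)
  class(out) <- c("ivt_pileup", class(out))
  out
}

#' Read and write pileup tables
#'
#' The on-disk format is a TSV with columns `contig`, `pos` (0-based), `ref`,
#' `A`, `C`, `G`, `T`, `del`, `depth`, round-trippable by [read_pileup()].
#'
#' @param pileup An `ivt_pileup` tibble.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           contig = "c", pos = "i", ref = "c", A = "i",
                           C = "i", G = "i", T = "i", del = "i", depth = "i"))
  class(out) <- c("ivt_pileup", class(out))
  out
}
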