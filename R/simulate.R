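#' Simulation configuration for synthetic DRS / IVT experiments
#'
#' Collects every knob of the read simulator into a validated list. The
#' defaults describe a small but structurally faithful experiment: a
#' multi-contig reference partly tiled by genes, genomic SNVs present in both
#' IVT and biological reads, IVT-only artifact mismatches, modification sites
#' that miscall only in biological reads, a uniform background substitution
#' error, and a two-level base-quality scheme in which a designated subset of
#' reference 9-mer contexts is basecalled with depressed quality.
#'
#' @param n_contigs Number of reference contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_genes Total number of genes, tiled across contigs as
#'   non-overlapping half-open intervals.
#' @param gene_abundance_skew Zipf exponent for gene expression: gene ranked
#'   `r` is sampled with weight `r^-skew`, giving the long-tailed abundance
#'   profile typical of transcriptomes.
#' @param n_genomic_snv Number of genomic single-nucleotide variants
#'   (appear in both IVT and biological reads).
#' @param snv_allele_fraction Allele fraction of the SNVs, in `[0,1]`;
#'   recycled across SNVs so heterozygous mixes can be simulated.
#' @param n_ivt_artifacts Number of IVT-only systematic mismatches
#'   (e.g. polymerase errors fixed in the template).
#' @param ivt_artifact_fraction Occurrence fraction of IVT artifacts.
#' @param n_modification_sites Number of RNA-modification sites (systematic
#'   miscalls in biological reads only).
#' @param modification_miscall_rate Per-read miscall probability at a
#'   modification site, in `[0,1]`.
#' @param background_error_rate Independent per-base substitution error rate
#'   applied everywhere else, alt base uniform over the three non-reference
#'   bases.
#' @param n_low_quality_kmers Number of distinct reference 9-mers whose
#'   center base is basecalled at `base_quality_low`.
#' @param base_quality_high,base_quality_low Phred scores of the two quality
#'   levels; `base_quality_low < base_quality_high` is required.
#' @param reads_per_sample Number of reads simulated per sample.
#' @param read_length_mean Mean read length in bases (reads are clamped to
#'   their gene's interval).
#' @param deletion_rate Optional per-base deletion probability (0 disables),
#'   exercising the deletion-aware mismatch denominator.
#' @param seed Base RNG seed; sample `i` uses stream `seed + i` so adding a
#'   sample never perturbs the others.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_contigs = 1, contig_length = 2000, n_genes = 4,
#'                   reads_per_sample = 50, seed = 7)
sim_config <- function(n_contigs = 2,
                       contig_length = 20000,
                       n_genes = 30,
                       gene_abundance_skew = 1.2,
                       n_genomic_snv = 10,
                       snv_allele_fraction = 1.0,
                       n_ivt_artifacts = 8,
                       ivt_artifact_fraction = 0.8,
                       n_modification_sites = 8,
                       modification_miscall_rate = 0.5,
                       background_error_rate = 0.02,
                       n_low_quality_kmers = 20,
                       base_quality_high = 25,
                       base_quality_low = 7,
                       reads_per_sample = 500,
                       read_length_mean = 1000,
                       deletion_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    gene_abundance_skew = gene_abundance_skew,
    n_genomic_snv = as.integer(n_genomic_snv),
    snv_allele_fraction = snv_allele_fraction,
    n_ivt_artifacts = as.integer(n_ivt_artifacts),
    ivt_artifact_fraction = ivt_artifact_fraction,
    n_modification_sites = as.integer(n_modification_sites),
    modification_miscall_rate = modification_miscall_rate,
    background_error_rate = background_error_rate,
    n_low_quality_kmers = as.integer(n_low_quality_kmers),
    base_quality_high = as.integer(base_quality_high),
    base_quality_low = as.integer(base_quality_low),
    reads_per_sample = as.integer(reads_per_sample),
    read_length_mean = as.integer(read_length_mean),
    deletion_rate = deletion_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_contigs", "contig_length", "n_genes", "n_genomic_snv",
              "n_ivt_artifacts", "n_modification_sites", "n_low_quality_kmers",
              "reads_per_sample", "read_length_mean")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      abort(sprintf("`%s` must be a single non-negative count", f),
            class = "ivt_config_error")
    }
  }
  fracs <- c("snv_allele_fraction", "ivt_artifact_fraction",
             "modification_miscall_rate", "background_error_rate",
             "deletion_rate")
  for (f in fracs) {
    v <- cfg[[f]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      abort(sprintf("`%s` must lie in [0, 1]", f),
            class = "ivt_config_error")
    }
  }
  if (cfg$n_contigs < 1L || cfg$contig_length < 1L || cfg$n_genes < 1L) {
    abort("need at least one contig, one base and one gene",
          class = "ivt_config_error")
  }
  if (cfg$base_quality_low >= cfg$base_quality_high) {
    abort("`base_quality_low` must be below `base_quality_high`",
          class = "ivt_config_error")
  }
  if (cfg$contig_length < cfg$read_length_mean) {
    abort("`contig_length` must be at least `read_length_mean`",
          class = "ivt_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

#' Generate a reference genome with gene annotation
#'
#' Draws i.i.d. uniform A/C/G/T contigs and tiles part of each contig with
#' non-overlapping half-open gene intervals. Genes are distributed across
#' contigs as evenly as possible; within a contig each gene occupies 90% of
#' its slot, leaving intergenic gaps.
#'
#' @param config A [sim_config()].
#' @return A list of class `ivt_reference` with elements `sequences`
#'   (a named [Biostrings::DNAStringSet]) and `genes` (a tibble with columns
#'   `contig`, `gene`, `start`, `end`; 0-based half-open).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    contigs <- sprintf("ctg%02d", seq_len(config$n_contigs))
    seqs <- vapply(contigs, function(nm) {
      paste0(sample(DNA_BASES, config$contig_length, replace = TRUE),
             collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- contigs

    per_contig <- diff(floor(seq(0, config$n_genes,
                                 length.out = config$n_contigs + 1L)))
    genes <- purrr::map2_dfr(contigs, per_contig, function(ctg, g) {
      if (g == 0L) return(tibble())
      slot <- config$contig_length %/% g
      glen <- max(1L, as.integer(floor(slot * 0.9)))
      start <- (seq_len(g) - 1L) * slot
      tibble(contig = ctg, start = as.integer(start),
             end = as.integer(start + glen))
    })
    genes$gene <- sprintf("gene%03d", seq_len(nrow(genes)))
    genes <- genes[, c("contig", "gene", "start", "end")]
    structure(list(sequences = sequences, genes = genes),
              class = "ivt_reference")
  })
}

#' @export
print.ivt_reference <- function(x, ...) {
  cat(sprintf("<ivt_reference> %d contig(s), %d gene(s)\n",
              length(x$sequences), nrow(x$genes)))
  invisible(x)
}

# Accept either an ivt_reference or a bare DNAStringSet everywhere.
ref_seqs <- function(reference) {
  if (inherits(reference, "ivt_reference")) return(reference$sequences)
  if (methods::is(reference, "DNAStringSet")) return(reference)
  abort("`reference` must be an ivt_reference or a named DNAStringSet",
        class = "ivt_input_error")
}

# Per-contig character vectors of single bases (1-based indexing by pos+1).
ref_chars <- function(reference) {
  seqs <- ref_seqs(reference)
  lapply(setNames(as.character(seqs), names(seqs)),
         function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

# Centered k-mer at every 0-based position of a contig; NA within flank of
# either edge.
contig_kmers <- function(seq_string, k) {
  flank <- (k - 1L) %/% 2L
  n <- nchar(seq_string)
  out <- rep(NA_character_, n)
  if (n >= k) {
    centers <- seq.int(flank, n - flank - 1L)       # 0-based centers
    out[centers + 1L] <- substring(seq_string, centers + 1L - flank,
                                   centers + 1L + flank)
  }
  out
}

#' Generate the ground-truth event set for a simulation
#'
#' Samples mutually disjoint genomic positions inside gene bodies (so that
#' reads can observe them, and at least `(k-1)/2` bases from contig edges so
#' 9-mer contexts are defined) for three event classes: genomic SNVs, IVT-only
#' artifacts and modification sites. Also selects the truth set of
#' low-quality reference 9-mers.
#'
#' @param reference An `ivt_reference` from [generate_reference()].
#' @param config The matching [sim_config()].
#' @param k Context length for the low-quality k-mer scheme (odd, default 9).
#' @return A list of class `ivt_truth` with tibbles `snvs`, `ivt_artifacts`,
#'   `modification_sites` (columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `fraction`) and a character vector `low_quality_kmers`.
#' @export
simulate_truth <- function(reference, config, k = 9L) {
  stopifnot(inherits(reference, "ivt_reference"), inherits(config, "sim_config"))
  flank <- (k - 1L) %/% 2L
  withr::with_seed(config$seed + 1000L, {
    chars <- ref_chars(reference)
    cand <- purrr::pmap_dfr(reference$genes, function(contig, gene, start, end) {
      lo <- max(start, flank)
      hi <- min(end - 1L, config$contig_length - flank - 1L)
      if (hi < lo) return(tibble())
      tibble(contig = contig, pos = seq.int(lo, hi))
    })
    cand <- distinct(cand, .data$contig, .data$pos)
    n_events <- config$n_genomic_snv + config$n_ivt_artifacts +
      config$n_modification_sites
    if (n_events > nrow(cand)) {
      abort("not enough in-gene positions for the requested events",
            class = "ivt_config_error")
    }
    picked <- cand[sample.int(nrow(cand), n_events), ]
    picked$ref <- mapply(function(ctg, p) chars[[ctg]][p + 1L],
                         picked$contig, picked$pos, USE.NAMES = FALSE)
    picked$alt <- vapply(picked$ref, function(r) {
      sample(setdiff(DNA_BASES, r), 1L)
    }, character(1), USE.NAMES = FALSE)

    idx <- rep(c("snv", "artifact", "mod"),
               c(config$n_genomic_snv, config$n_ivt_artifacts,
                 config$n_modification_sites))
    split_events <- split(picked, factor(idx, levels = c("snv", "artifact", "mod")))
    snvs <- as_tibble(split_events$snv)
    arts <- as_tibble(split_events$artifact)
    mods <- as_tibble(split_events$mod)
    snvs$fraction <- rep_len(config$snv_allele_fraction, nrow(snvs))
    arts$fraction <- rep_len(config$ivt_artifact_fraction, nrow(arts))
    mods$fraction <- rep_len(config$modification_miscall_rate, nrow(mods))

    all_kmers <- unique(unlist(lapply(
      as.character(ref_seqs(reference)), contig_kmers, k = k
    ), use.names = FALSE))
    all_kmers <- all_kmers[!is.na(all_kmers)]
    if (config$n_low_quality_kmers > length(all_kmers)) {
      abort("fewer distinct reference k-mers than `n_low_quality_kmers`",
            class = "ivt_config_error")
    }
    lowq <- sample(all_kmers, config$n_low_quality_kmers)

    structure(list(snvs = snvs, ivt_artifacts = arts,
                   modification_sites = mods,
                   low_quality_kmers = lowq, k = as.integer(k)),
              class = "ivt_truth")
  })
}

#' @export
print.ivt_truth <- function(x, ...) {
  cat(sprintf(
    "<ivt_truth> %d SNV(s), %d IVT artifact(s), %d modification site(s), %d low-quality %d-mer(s)\n",
    nrow(x$snvs), nrow(x$ivt_artifacts), nrow(x$modification_sites),
    length(x$low_quality_kmers), x$k))
  invisible(x)
}

#' Simulate an aligned DRS read set
#'
#' Emits pre-aligned reads (perfect coordinates, substitutions plus optional
#' deletions) from gene bodies with Zipf-weighted gene abundance. Genomic
#' SNVs substitute in both modes at their allele fraction; IVT artifacts only
#' in `"ivt"` mode; modification miscalls only in `"biological"` mode; every
#' other position suffers an independent background error with a uniform
#' non-reference alt. The base quality of a read base is
#' `base_quality_low` when the reference 9-mer centred on its position is in
#' the truth low-quality set, else `base_quality_high`.
#'
#' @param reference An `ivt_reference`.
#' @param truth An `ivt_truth` from [simulate_truth()].
#' @param mode `"ivt"` or `"biological"`.
#' @param config The [sim_config()].
#' @param sample_index Integer; the RNG stream is `seed + sample_index`, so
#'   adding a sample never changes existing ones.
#' @return A tibble of class `ivt_alignments` with one row per read:
#'   `read_id`, `flag`, `contig`, `pos` (0-based leftmost), `mapq`, `cigar`,
#'   `seq`, `qual` (phred+33), `gene`, `mode`.
#' @export
simulate_reads <- function(reference, truth, mode = c("ivt", "biological"),
                           config, sample_index = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "ivt_reference"), inherits(truth, "ivt_truth"),
            inherits(config, "sim_config"))
  chars <- ref_chars(reference)
  check_truth_against_reference(truth, chars)
  genes <- reference$genes
  k <- truth$k
  # per-contig logical: is this position the center of a truth low-quality k-mer
  lowq_pos <- lapply(as.character(ref_seqs(reference)), function(s) {
    km <- contig_kmers(s, k)
    !is.na(km) & km %in% truth$low_quality_kmers
  })

  withr::with_seed(config$seed + sample_index, {
    n <- config$reads_per_sample
    if (n == 0L) {
      return(empty_alignments(mode))
    }
    weights <- seq_len(nrow(genes))^(-config$gene_abundance_skew)
    gidx <- sample.int(nrow(genes), n, replace = TRUE, prob = weights)
    glen <- genes$end[gidx] - genes$start[gidx]
    want <- pmax(50L, as.integer(round(rnorm(n, config$read_length_mean,
                                             0.1 * config$read_length_mean))))
    rlen <- pmin(want, glen)
    start <- genes$start[gidx] +
      as.integer(floor(runif(n) * (glen - rlen + 1L)))
    contig <- genes$contig[gidx]

    # expanded (read, reference-position) table
    ridx <- rep.int(seq_len(n), rlen)
    refpos <- unlist(lapply(seq_len(n), function(i) {
      seq.int(start[i], length.out = rlen[i])
    }), use.names = FALSE)
    ctg <- contig[ridx]
    base <- character(length(refpos))
    for (cg in unique(contig)) {
      sel <- ctg == cg
      base[sel] <- chars[[cg]][refpos[sel] + 1L]
    }

    # event lookup by position key
    base <- apply_substitutions(base, ctg, refpos, truth, mode,
                                config$background_error_rate)

    # base quality by reference context
    qual <- rep(config$base_quality_high, length(refpos))
    for (cg in unique(contig)) {
      sel <- ctg == cg
      qual[sel][lowq_pos[[cg]][refpos[sel] + 1L]] <- config$base_quality_low
    }

    # optional deletions (never the first or last base of a read)
    deleted <- rep(FALSE, length(refpos))
    if (config$deletion_rate > 0) {
      offs <- sequence(rlen)
      interior <- offs > 1L & offs < rep.int(rlen, rlen)
      deleted <- interior & runif(length(refpos)) < config$deletion_rate
    }

    cigar <- unname(vapply(split(deleted, ridx), cigar_from_deleted,
                           character(1)))
    keep <- !deleted
    seq_str <- unname(vapply(split(base[keep], ridx[keep]),
                             paste0, character(1), collapse = ""))
    qual_str <- unname(vapply(split(qual[keep], ridx[keep]), function(q) {
      intToUtf8(q + 33L)
    }, character(1)))

    out <- tibble(
      read_id = sprintf("%s_s%02d_r%05d", mode, sample_index, seq_len(n)),
      flag = 0L,
      contig = contig,
      pos = as.integer(start),
      mapq = 60L,
      cigar = cigar,
      seq = seq_str,
      qual = qual_str,
      gene = genes$gene[gidx],
      mode = mode
    )
    class(out) <- c("ivt_alignments", class(out))
    out
  })
}

empty_alignments <- function(mode = NA_character_) {
  out <- tibble(read_id = character(), flag = integer(), contig = character(),
                pos = integer(), mapq = integer(), cigar = character(),
                seq = character(), qual = character(), gene = character(),
                mode = mode[0])
  class(out) <- c("ivt_alignments", class(out))
  out
}

check_truth_against_reference <- function(truth, chars) {
  ev <- bind_rows(truth$snvs, truth$ivt_artifacts, truth$modification_sites)
  if (nrow(ev) == 0L) return(invisible(TRUE))
  bad <- mapply(function(ctg, p, r) {
    is.null(chars[[ctg]]) || p + 1L > length(chars[[ctg]]) ||
      chars[[ctg]][p + 1L] != r
  }, ev$contig, ev$pos, ev$ref, USE.NAMES = FALSE)
  if (any(bad)) {
    abort(sprintf("%d truth event(s) disagree with the reference sequence",
                  sum(bad)), class = "ivt_truth_error")
  }
  invisible(TRUE)
}

# Substitute event and background alt bases into the expanded base vector.
apply_substitutions <- function(base, ctg, refpos, truth, mode, bg_rate) {
  key <- pos_key(ctg, refpos)
  events <- bind_rows(
    mutate(truth$snvs, class = "snv"),
    mutate(truth$ivt_artifacts, class = "artifact"),
    mutate(truth$modification_sites, class = "mod")
  )
  active <- switch(mode,
                   ivt = c("snv", "artifact"),
                   biological = c("snv", "mod"))
  is_event <- rep(FALSE, length(base))
  if (nrow(events) > 0L) {
    ekey <- pos_key(events$contig, events$pos)
    m <- match(key, ekey)
    hit <- !is.na(m)
    # only events active in this mode replace the background error process;
    # e.g. a modification site in IVT mode is ordinary background
    act <- hit & events$class[m] %in% active
    is_event <- act
    if (any(act)) {
      flip <- act & runif(length(base)) < events$fraction[m]
      base[flip] <- events$alt[m[flip]]
    }
  }
  if (bg_rate > 0) {
    err <- !is_event & runif(length(base)) < bg_rate
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      cur <- match(base[err], DNA_BASES)
      base[err] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  base
}

cigar_from_deleted <- function(del) {
  if (!any(del)) return(sprintf("%dM", length(del)))
  r <- rle(del)
  paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
}

#' Write simulation outputs to standard formats
#'
#' `write_reference_fasta()` writes the contigs as FASTA.
#' `write_sam()` writes alignments as SAM with the gene label in an `XG` tag.
#' `write_gene_tsv()` mirrors the read-to-gene mapping as a two-column TSV.
#' `write_truth_tables()` writes one TSV per truth event class plus the
#' low-quality k-mer list. `write_truth_bed()` writes all truth positions as
#' a 0-based half-open BED track. `write_sim_config()` snapshots the
#' configuration as a key/value TSV.
#'
#' @param reference An `ivt_reference`.
#' @param path,dir Output file or directory.
#' @param alignments An `ivt_alignments` tibble.
#' @param truth An `ivt_truth`.
#' @param config A `sim_config`.
#' @name simulation-io
NULL

#' @rdname simulation-io
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(ref_seqs(reference), filepath = path)
  invisible(path)
}

#' @rdname simulation-io
#' @export
write_sam <- function(alignments, reference, path) {
  seqs <- ref_seqs(reference)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)))
  tag <- ifelse(is.na(alignments$gene), "",
                sprintf("\tXG:Z:%s", alignments$gene))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  alignments$read_id, alignments$flag, alignments$contig,
                  alignments$pos + 1L, alignments$mapq, alignments$cigar,
                  alignments$seq, alignments$qual, tag)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname simulation-io
#' @export
write_gene_tsv <- function(alignments, path) {
  readr::write_tsv(alignments[, c("read_id", "gene")], path)
  invisible(path)
}

#' @rdname simulation-io
#' @export
write_truth_tables <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(truth$snvs, file.path(dir, "truth_snvs.tsv"))
  readr::write_tsv(truth$ivt_artifacts, file.path(dir, "truth_ivt_artifacts.tsv"))
  readr::write_tsv(truth$modification_sites,
                   file.path(dir, "truth_modification_sites.tsv"))
  readr::write_lines(truth$low_quality_kmers,
                     file.path(dir, "truth_low_quality_kmers.txt"))
  invisible(dir)
}

#' @rdname simulation-io
#' @export
write_truth_bed <- function(truth, path) {
  ev <- bind_rows(snv = truth$snvs, ivt_artifact = truth$ivt_artifacts,
                  modification = truth$modification_sites, .id = "class")
  gr <- GenomicRanges::GRanges(
    ev$contig, IRanges::IRanges(start = ev$pos + 1L, width = 1L),
    name = sprintf("%s|%s>%s", ev$class, ev$ref, ev$alt)
  )
  rtracklayer::export(sort(gr), path, format = "BED")
  invisible(path)
}

#' @rdname simulation-io
#' @export
write_sim_config <- function(config, path) {
  readr::write_tsv(
    tibble(field = names(config),
           value = vapply(config, function(v) paste(v, collapse = ","),
                          character(1))),
    path)
  invisible(path)
}

#' Read aligned reads from SAM/BAM, keeping primary alignments only
#'
#' Loads a SAM or BAM file into the tibble representation used throughout the
#' package. Unmapped, secondary and supplementary alignments are dropped
#' (the samtools `-F 4 -F 256 -F 2048` convention). A gene label is recovered
#' from the `XG` tag when present.
#'
#' @param path Path to a SAM or BAM file. SAM input is converted on the fly.
#' @return An `ivt_alignments` tibble (positions 0-based).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "ivt_input_error")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "XG",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  gene <- rec$tag$XG %||% rep(NA_character_, length(rec$qname))
  out <- tibble(
    read_id = rec$qname,
    flag = as.integer(rec$flag),
    contig = as.character(rec$rname),
    pos = as.integer(rec$pos) - 1L,
    mapq = as.integer(rec$mapq),
    cigar = rec$cigar,
    seq = as.character(rec$seq),
    qual = as.character(rec$qual),
    gene = as.character(gene),
    mode = NA_character_
  )
  class(out) <- c("ivt_alignments", class(out))
  out
}
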