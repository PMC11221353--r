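#' Gene counts from read-to-gene labels
#'
#' @param alignments An `ivt_alignments` tibble (or any tibble with
#'   `read_id` and `gene` columns). Only primary alignments are counted.
#' @return A tibble `gene`, `count`.
#' @export
gene_read_counts <- function(alignments) {
  aln <- filter_primary(alignments)
  aln |>
    filter(!is.na(.data$gene)) |>
    count(.data$gene, name = "count") |>
    arrange(.data$gene)
}

#' Fraction of a gene universe observed at increasing read-count cutoffs
#'
#' For each cutoff, the fraction of universe genes with at least that many
#' primary-aligned reads. Genes in `counts` but outside the universe are
#' ignored (their number is reported via a message); universe genes with no
#' reads count as zero. Fractions are non-increasing in the cutoff.
#'
#' @param counts A tibble with columns `gene`, `count` (see
#'   [gene_read_counts()]).
#' @param universe Character vector of gene identifiers defining the
#'   denominator (e.g. all annotated protein-coding genes).
#' @param cutoffs Strictly increasing positive integer cutoffs.
#' @return A tibble of class `ivt_coverage_cutoff`: `cutoff`, `n_genes`,
#'   `fraction`.
#' @export
coverage_vs_cutoff <- function(counts, universe, cutoffs = c(1, 5, 10, 50)) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    abort("`universe` must contain at least one gene",
          class = "ivt_config_error")
  }
  if (any(cutoffs < 1) || any(diff(cutoffs) <= 0)) {
    abort("`cutoffs` must be strictly increasing and >= 1",
          class = "ivt_config_error")
  }
  outside <- setdiff(unique(counts$gene), universe)
  if (length(outside) > 0L) {
    inform(sprintf("%d gene(s) with reads fall outside the universe and are ignored",
                   length(outside)))
  }
  cvec <- setNames(rep(0L, length(universe)), universe)
  inside <- counts[counts$gene %in% universe, ]
  cvec[inside$gene] <- inside$count
  out <- tibble(
    cutoff = cutoffs,
    n_genes = vapply(cutoffs, function(ct) sum(cvec >= ct), integer(1)),
    fraction = vapply(cutoffs, function(ct) mean(cvec >= ct), double(1))
  )
  class(out) <- c("ivt_coverage_cutoff", class(out))
  out
}

as_gene_labels <- function(x, what = "reads") {
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) {
      abort(sprintf("%s table needs a `gene` column", what),
            class = "ivt_input_error")
    }
    x <- x$gene
  }
  as.character(x[!is.na(x)])
}

#' Round-robin gene-coverage saturation curve
#'
#' Measures how well a representative population of samples approximates the
#' gene set of a held-out target sample. The target gene set is formed from
#' one draw of `target_draw` reads from the target sample (all reads if it
#' has fewer, with a warning). Then, for per-sample subsample sizes
#' `0, step, 2*step, ..., target_draw`, the same number of reads is drawn
#' without replacement from each population sample, the union of their gene
#' sets is formed, and the curve records the fraction of target genes
#' present in that union. The procedure is repeated `repeats` times and
#' averaged.
#'
#' `score = "intersection"` (default) reports
#' `|population genes ∩ target genes| / |target genes|`, a proportion in
#' `[0, 1]` that starts at 0 and rises to the intersection-over-target
#' asymptote. `score = "union"` reports the literal
#' `|population genes ∪ target genes| / |target genes|` ratio (>= 1),
#' retained for auditability.
#'
#' @param target Read-to-gene labels for the target sample: a character
#'   vector of gene labels (one per read) or a tibble with a `gene` column.
#' @param population A list of such label sets, one per population sample
#'   (the study design uses 5).
#' @param target_draw Reads drawn from the target (default 1,000,000).
#' @param step Per-sample subsample increment (default 100,000).
#' @param repeats Number of resampling repeats averaged (default 100).
#' @param seed Optional RNG seed for reproducibility.
#' @param score `"intersection"` or `"union"` (see above).
#' @return A tibble of class `ivt_saturation`: `per_sample_reads`,
#'   `combined_reads`, `mean_proportion`, `sd_proportion`; attributes
#'   `repeats`, `score`, `asymptote` (full-population score) and
#'   `n_target_genes`.
#' @export
saturation_curve <- function(target, population, target_draw = 1000000L,
                             step = 100000L, repeats = 100L, seed = NULL,
                             score = c("intersection", "union")) {
  score <- match.arg(score)
  if (repeats < 1L) abort("`repeats` must be >= 1", class = "ivt_config_error")
  target <- as_gene_labels(target, "target")
  population <- lapply(population, as_gene_labels, what = "population")
  run <- function() {
    if (length(target) > target_draw) {
      tgt_reads <- sample(target, target_draw)
    } else {
      if (length(target) < target_draw) {
        warn(sprintf("target has %d reads, fewer than target_draw = %d; using all",
                     length(target), target_draw))
      }
      tgt_reads <- target
    }
    tgt_genes <- unique(tgt_reads)
    if (length(tgt_genes) == 0L) {
      abort("target gene set is empty", class = "ivt_input_error")
    }
    sizes <- seq(0L, as.integer(target_draw), by = as.integer(step))
    short <- vapply(population, length, integer(1)) < max(sizes)
    if (any(short)) {
      warn(sprintf("%d population sample(s) have fewer reads than the largest draw; all their reads are used",
                   sum(short)))
    }

    # Per repeat: permute each population sample once and score prefixes —
    # each prefix of a uniform permutation is a uniform without-replacement
    # subsample, so the mean curve matches independent draws at each size.
    prop <- matrix(NA_real_, nrow = repeats, ncol = length(sizes))
    for (r in seq_len(repeats)) {
      perms <- lapply(population, sample)
      # earliest draw index at which each target gene appears, per sample
      min_hit <- do.call(pmin, lapply(perms, function(perm) {
        hit <- match(tgt_genes, perm)       # first occurrence position
        hit[is.na(hit)] <- Inf
        hit
      }))
      covered <- vapply(sizes, function(s) sum(min_hit <= s), double(1))
      if (score == "intersection") {
        prop[r, ] <- covered / length(tgt_genes)
      } else {
        # |P ∪ T| / |T| = 1 + |P \ T| / |T|
        nt_first <- lapply(perms, function(perm) {
          g <- setdiff(unique(perm), tgt_genes)
          setNames(match(g, perm), g)
        })
        prop[r, ] <- vapply(sizes, function(s) {
          seen <- unique(unlist(lapply(nt_first, function(h) names(h)[h <= s]),
                                use.names = FALSE))
          1 + length(seen) / length(tgt_genes)
        }, double(1))
      }
    }
    out <- tibble(
      per_sample_reads = sizes,
      combined_reads = sizes * length(population),
      mean_proportion = colMeans(prop),
      sd_proportion = apply(prop, 2, stats::sd)
    )
    full_pop_genes <- unique(unlist(population, use.names = FALSE))
    asymptote <- if (score == "intersection") {
      length(intersect(full_pop_genes, tgt_genes)) / length(tgt_genes)
    } else {
      length(union(full_pop_genes, tgt_genes)) / length(tgt_genes)
    }
    attr(out, "repeats") <- as.integer(repeats)
    attr(out, "score") <- score
    attr(out, "asymptote") <- asymptote
    attr(out, "n_target_genes") <- length(tgt_genes)
    class(out) <- c("ivt_saturation", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
#' @rdname saturation_curve
#' @param x An `ivt_saturation` curve.
#' @param ... Unused.
glance.ivt_saturation <- function(x, ...) {
  tibble(repeats = attr(x, "repeats"), score = attr(x, "score"),
         asymptote = attr(x, "asymptote"),
         n_target_genes = attr(x, "n_target_genes"),
         final_proportion = x$mean_proportion[nrow(x)])
}

#' Naive transcripts-per-million from primary-alignment counts
#'
#' Length-normalised relative abundance:
#' `TPM_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6`.
#' This is a deliberately simple estimator — counts of primary alignments
#' per transcript (or gene), no EM re-assignment of ambiguous reads — and is
#' documented as such wherever it is used.
#'
#' @param counts Tibble with an id column (`gene` or `transcript`) and
#'   `count`.
#' @param lengths Named numeric vector (id -> effective length in bases) or
#'   a tibble with the id column and `length`.
#' @return A tibble `id`, `count`, `length`, `tpm`; TPM sums to 1e6.
#' @export
naive_tpm <- function(counts, lengths) {
  id_col <- intersect(c("gene", "transcript", "id"), names(counts))[1]
  if (is.na(id_col)) {
    abort("`counts` needs a `gene`, `transcript` or `id` column",
          class = "ivt_input_error")
  }
  if (is.data.frame(lengths)) {
    lid <- intersect(c("gene", "transcript", "id"), names(lengths))[1]
    lengths <- setNames(lengths$length, lengths[[lid]])
  }
  ids <- counts[[id_col]]
  len <- unname(lengths[ids])
  if (any(is.na(len)) || any(len <= 0)) {
    abort("every counted id needs a positive length",
          class = "ivt_input_error")
  }
  if (sum(counts$count) <= 0) {
    abort("total count is zero; TPM undefined", class = "ivt_input_error")
  }
  rate <- counts$count / len
  tibble(id = ids, count = counts$count, length = len,
         tpm = rate / sum(rate) * 1e6)
}

#' Squared Pearson correlation between two TPM tables
#'
#' Restricted to ids present in both tables (at least 3 required). With
#' `log_transform = TRUE` (the conventional choice for abundances spanning
#' orders of magnitude) the correlation is computed on log10(TPM) over the
#' ids with positive TPM in both samples.
#'
#' @param tpm_a,tpm_b Tibbles from [naive_tpm()] (columns `id`, `tpm`).
#' @param log_transform Logical, default `TRUE`.
#' @return An object of class `tpm_cor`: list with `r_squared`, `n_shared`,
#'   `n_used`, `log_transform`.
#' @export
tpm_correlation <- function(tpm_a, tpm_b, log_transform = TRUE) {
  shared <- inner_join(tpm_a[, c("id", "tpm")], tpm_b[, c("id", "tpm")],
                       by = "id", suffix = c("_a", "_b"))
  if (nrow(shared) < 3L) {
    abort(sprintf("only %d shared id(s); need at least 3 for a correlation",
                  nrow(shared)), class = "ivt_insufficient_data")
  }
  used <- shared
  if (log_transform) {
    used <- filter(shared, .data$tpm_a > 0, .data$tpm_b > 0)
    if (nrow(used) < 3L) {
      abort("fewer than 3 ids with positive TPM in both samples",
            class = "ivt_insufficient_data")
    }
    r <- cor(log10(used$tpm_a), log10(used$tpm_b))
  } else {
    r <- cor(used$tpm_a, used$tpm_b)
  }
  structure(list(r_squared = r^2, n_shared = nrow(shared),
                 n_used = nrow(used), log_transform = log_transform),
            class = "tpm_cor")
}

#' @export
print.tpm_cor <- function(x, ...) {
  cat(sprintf("<tpm_cor> r^2 = %.3f over %d shared id(s) (%d used%s)\n",
              x$r_squared, x$n_shared, x$n_used,
              if (x$log_transform) ", log10 scale" else ""))
  invisible(x)
}

#' @export
#' @rdname tpm_correlation
#' @param x A `tpm_cor` object.
#' @param ... Unused.
glance.tpm_cor <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_shared = x$n_shared, n_used = x$n_used,
         log_transform = x$log_transform)
}
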