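# Shared fixtures and independent brute-force oracles.

# Construct an alignments tibble by hand. `specs` is a list of lists with
# fields contig, pos (0-based), seq, and optional cigar/qual/gene.
make_aln <- function(specs, mode = "ivt") {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    n <- nchar(s$seq)
    tibble::tibble(
      read_id = s$read_id %||% sprintf("r%03d", i),
      flag = s$flag %||% 0L,
      contig = s$contig,
      pos = as.integer(s$pos),
      mapq = 60L,
      cigar = s$cigar %||% sprintf("%dM", n),
      seq = s$seq,
      qual = s$qual %||% strrep("I", n),   # Q40
      gene = s$gene %||% NA_character_,
      mode = mode
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ivt_alignments", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap bare sequences into a minimal reference object.
make_ref <- function(..., genes = NULL) {
  seqs <- Biostrings::DNAStringSet(c(...))
  if (is.null(genes)) {
    genes <- tibble::tibble(
      contig = names(seqs),
      gene = paste0("g_", names(seqs)),
      start = 0L,
      end = Biostrings::width(seqs)
    )
  }
  structure(list(sequences = seqs, genes = genes), class = "ivt_reference")
}

# Brute-force pileup: hand-parses each CIGAR and walks the read base by base,
# incrementing per-position counters. Deliberately scalar and independent of
# the package's vectorized path.
oracle_pileup <- function(aln, reference) {
  seqs <- as.character(if (inherits(reference, "ivt_reference"))
    reference$sequences else reference)
  tallies <- new.env(hash = TRUE)
  bump <- function(ctg, pos, what) {
    key <- paste0(ctg, ":", pos)
    cur <- tallies[[key]]
    if (is.null(cur)) cur <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L)
    cur[what] <- cur[what] + 1L
    tallies[[key]] <- cur
  }
  for (i in seq_len(nrow(aln))) {
    if (bitwAnd(aln$flag[i], 4L + 256L + 2048L) != 0L) next
    ops <- regmatches(aln$cigar[i],
                      gregexpr("\\d+[MIDNSHP=X]", aln$cigar[i]))[[1]]
    rp <- aln$pos[i]          # 0-based reference cursor
    qp <- 1L                  # 1-based query cursor
    bases <- strsplit(aln$seq[i], "")[[1]]
    for (op in ops) {
      len <- as.integer(sub("[MIDNSHP=X]", "", op))
      type <- sub("\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (j in seq_len(len)) {
          bump(aln$contig[i], rp, bases[qp])
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (type == "D") {
        for (j in seq_len(len)) {
          bump(aln$contig[i], rp, "del")
          rp <- rp + 1L
        }
      } else if (type == "N") {
        rp <- rp + len
      } else if (type %in% c("I", "S")) {
        qp <- qp + len
      }
    }
  }
  if (length(tallies) == 0L) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), A = integer(), C = integer(),
                          G = integer(), T = integer(), del = integer(),
                          depth = integer()))
  }
  parts <- strsplit(names(tallies), ":", fixed = TRUE)
  out <- tibble::tibble(
    contig = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    A = vapply(tallies, `[[`, 0L, "A"),
    C = vapply(tallies, `[[`, 0L, "C"),
    G = vapply(tallies, `[[`, 0L, "G"),
    T = vapply(tallies, `[[`, 0L, "T"),
    del = vapply(tallies, `[[`, 0L, "del")
  )
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out$ref <- mapply(function(ctg, p) substr(seqs[[ctg]], p + 1, p + 1),
                    out$contig, out$pos, USE.NAMES = FALSE)
  out <- out[order(out$contig, out$pos),
             c("contig", "pos", "ref", "A", "C", "G", "T", "del", "depth")]
  rownames(out) <- NULL
  out
}

# Independent saturation oracle: literal independent without-replacement
# draws at every size (no permutation-prefix shortcut).
oracle_saturation <- function(target_genes, population, sizes, repeats) {
  sapply(sizes, function(s) {
    mean(replicate(repeats, {
      pop_genes <- unique(unlist(lapply(population, function(p) {
        unique(sample(p, min(s, length(p))))
      })))
      length(intersect(pop_genes, target_genes)) / length(target_genes)
    }))
  })
}

# compare pileup tables field-for-field regardless of class/encoding
expect_same_pileup <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  a <- a[order(a$contig, a$pos), ]; b <- b[order(b$contig, b$pos), ]
  rownames(a) <- rownames(b) <- NULL
  testthat::expect_equal(nrow(a), nrow(b))
  for (col in c("contig", "pos", "ref", "A", "C", "G", "T", "del", "depth")) {
    testthat::expect_true(all(a[[col]] == b[[col]]),
                          label = sprintf("pileup column %s matches", col))
  }
}

default_thresholds <- c(30, 40, 50, 60, 70, 80, 95)
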