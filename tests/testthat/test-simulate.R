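test_that("reference generation is deterministic and structurally valid", {
  cfg <- sim_config(n_contigs = 2, contig_length = 10000, n_genes = 50,
                    seed = 1)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(ref1, f1); write_reference_fasta(ref2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_length(ref1$sequences, 2L)
  expect_true(all(Biostrings::width(ref1$sequences) == 10000L))
  expect_false(any(grepl("[^ACGT]", as.character(ref1$sequences))))

  # pairwise overlap brute force over all gene-interval pairs
  g <- ref1$genes
  expect_equal(nrow(g), 50L)
  for (i in seq_len(nrow(g) - 1L)) {
    for (j in seq((i + 1L), nrow(g))) {
      if (g$contig[i] != g$contig[j]) next
      overlaps <- g$start[i] < g$end[j] && g$start[j] < g$end[i]
      expect_false(overlaps)
    }
  }
  expect_true(all(g$end <= cfg$contig_length))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(contig_length = 100, read_length_mean = 500),
               class = "ivt_config_error")
  expect_error(sim_config(base_quality_low = 30, base_quality_high = 20),
               class = "ivt_config_error")
  expect_error(sim_config(background_error_rate = 1.5),
               class = "ivt_config_error")
  expect_error(sim_config(n_genes = 0), class = "ivt_config_error")
})

test_that("truth events are disjoint, in-bounds, and alt differs from ref", {
  cfg <- sim_config(seed = 11)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  ev <- dplyr::bind_rows(truth$snvs, truth$ivt_artifacts,
                         truth$modification_sites)
  expect_equal(nrow(ev),
               cfg$n_genomic_snv + cfg$n_ivt_artifacts + cfg$n_modification_sites)
  expect_equal(anyDuplicated(paste(ev$contig, ev$pos)), 0L)
  expect_true(all(ev$alt != ev$ref))
  chars <- lapply(as.character(ref$sequences), \(s) strsplit(s, "")[[1]])
  expect_true(all(mapply(\(c, p, r) chars[[c]][p + 1] == r,
                         ev$contig, ev$pos, ev$ref)))
  expect_true(all(nchar(truth$low_quality_kmers) == 9L))
  expect_equal(anyDuplicated(truth$low_quality_kmers), 0L)
})

test_that("simulated reads are deterministic per stream and carry gene labels", {
  cfg <- sim_config(n_contigs = 1, contig_length = 4000, n_genes = 4,
                    reads_per_sample = 40, read_length_mean = 600, seed = 2)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  a <- simulate_reads(ref, truth, "ivt", cfg, sample_index = 3)
  b <- simulate_reads(ref, truth, "ivt", cfg, sample_index = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c <- simulate_reads(ref, truth, "ivt", cfg, sample_index = 4)
  expect_false(identical(a$seq, c$seq))
  expect_true(all(a$gene %in% ref$genes$gene))
  # reads stay inside their gene's interval
  g <- ref$genes[match(a$gene, ref$genes$gene), ]
  expect_true(all(a$pos >= g$start))
  expect_true(all(a$pos + nchar(a$seq) <= g$end))
})

test_that("zero-error simulation reproduces the reference exactly", {
  cfg <- sim_config(n_contigs = 1, contig_length = 3000, n_genes = 3,
                    n_genomic_snv = 0, n_ivt_artifacts = 0,
                    n_modification_sites = 0, background_error_rate = 0,
                    reads_per_sample = 30, read_length_mean = 700, seed = 8)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  for (mode in c("ivt", "biological")) {
    reads <- simulate_reads(ref, truth, mode, cfg)
    refstr <- as.character(ref$sequences)[[1]]
    expect_true(all(vapply(seq_len(nrow(reads)), function(i) {
      reads$seq[i] == substr(refstr, reads$pos[i] + 1,
                             reads$pos[i] + nchar(reads$seq[i]))
    }, logical(1))))
  }
})

test_that("a fixed SNV at allele fraction 1 forces alt fraction 1 in the pileup", {
  cfg <- sim_config(n_contigs = 1, contig_length = 1000, n_genes = 1,
                    n_genomic_snv = 1, snv_allele_fraction = 1.0,
                    n_ivt_artifacts = 0, n_modification_sites = 0,
                    background_error_rate = 0, reads_per_sample = 100,
                    read_length_mean = 1000, n_low_quality_kmers = 5, seed = 4)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  reads <- simulate_reads(ref, truth, "ivt", cfg)
  p <- build_pileup(reads, ref)
  snv <- truth$snvs
  row <- p[p$pos == snv$pos, ]
  expect_gte(row$depth, 50L)
  expect_equal(row[[snv$alt]], row$depth)
})

test_that("event frequencies converge to configured rates with coverage", {
  # modification site miscalls at 0.4 in biological reads; IVT stays at
  # background per alt base. Binomial 3-SE tolerance from the simulator's
  # own counts, at three coverage levels.
  for (n_reads in c(200L, 800L, 3000L)) {
    cfg <- sim_config(n_contigs = 1, contig_length = 800, n_genes = 1,
                      n_genomic_snv = 0, n_ivt_artifacts = 0,
                      n_modification_sites = 1,
                      modification_miscall_rate = 0.4,
                      background_error_rate = 0.01,
                      reads_per_sample = n_reads, read_length_mean = 800,
                      n_low_quality_kmers = 3, seed = 21)
    ref <- generate_reference(cfg)
    truth <- simulate_truth(ref, cfg)
    bio <- build_pileup(simulate_reads(ref, truth, "biological", cfg, 1), ref)
    ivt <- build_pileup(simulate_reads(ref, truth, "ivt", cfg, 2), ref)
    m <- truth$modification_sites
    brow <- bio[bio$pos == m$pos, ]
    bfrac <- brow[[m$alt]] / brow$depth
    se <- sqrt(0.4 * 0.6 / brow$depth)
    expect_lt(abs(bfrac - 0.4), 3 * se + 1e-9)
    irow <- ivt[ivt$pos == m$pos, ]
    p_bg <- cfg$background_error_rate / 3
    # counts are small at these depths; use the exact binomial test rather
    # than a normal band
    pv <- stats::binom.test(irow[[m$alt]], irow$depth, p = p_bg)$p.value
    expect_gt(pv, 1e-3)
  }
})

test_that("mode contrast: artifacts absent from biological reads, modifications absent from IVT", {
  cfg <- sim_config(n_contigs = 1, contig_length = 1500, n_genes = 1,
                    n_genomic_snv = 0, n_ivt_artifacts = 4,
                    n_modification_sites = 4, background_error_rate = 0,
                    reads_per_sample = 400, read_length_mean = 1500,
                    n_low_quality_kmers = 3, seed = 31)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  bio <- build_pileup(simulate_reads(ref, truth, "biological", cfg, 1), ref)
  ivt <- build_pileup(simulate_reads(ref, truth, "ivt", cfg, 2), ref)
  for (i in seq_len(nrow(truth$ivt_artifacts))) {
    a <- truth$ivt_artifacts[i, ]
    brow <- bio[bio$pos == a$pos, ]
    expect_equal(brow[[a$alt]], 0L)         # zero background: exactly absent
    irow <- ivt[ivt$pos == a$pos, ]
    expect_gt(irow[[a$alt]] / irow$depth, 0.5)
  }
  for (i in seq_len(nrow(truth$modification_sites))) {
    m <- truth$modification_sites[i, ]
    irow <- ivt[ivt$pos == m$pos, ]
    expect_equal(irow[[m$alt]], 0L)
    brow <- bio[bio$pos == m$pos, ]
    expect_gt(brow[[m$alt]] / brow$depth, 0.2)
  }
})

test_that("low-quality 9-mer contexts depress center-base quality; deletions make valid CIGARs", {
  cfg <- sim_config(n_contigs = 1, contig_length = 2000, n_genes = 2,
                    n_genomic_snv = 0, n_ivt_artifacts = 0,
                    n_modification_sites = 0, background_error_rate = 0,
                    n_low_quality_kmers = 30, reads_per_sample = 60,
                    read_length_mean = 900, deletion_rate = 0.01, seed = 6)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  reads <- simulate_reads(ref, truth, "biological", cfg)
  expect_true(any(grepl("D", reads$cigar)))
  # M/D lengths in each CIGAR sum consistently with seq length and span
  for (i in seq_len(nrow(reads))) {
    ops <- regmatches(reads$cigar[i], gregexpr("\\d+[MD]", reads$cigar[i]))[[1]]
    lens <- as.integer(sub("[MD]", "", ops))
    types <- sub("\\d+", "", ops)
    expect_equal(sum(lens[types == "M"]), nchar(reads$seq[i]))
  }
  # the two quality levels partition read bases by reference context
  quals <- unique(utf8ToInt(paste0(reads$qual, collapse = ""))) - 33L
  expect_setequal(quals, c(cfg$base_quality_low, cfg$base_quality_high))
})

test_that("simulation outputs round-trip through standard formats", {
  cfg <- sim_config(n_contigs = 2, contig_length = 2000, n_genes = 6,
                    reads_per_sample = 30, read_length_mean = 400, seed = 9)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  reads <- simulate_reads(ref, truth, "ivt", cfg)

  sam <- tempfile(fileext = ".sam")
  write_sam(reads, ref, sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), nrow(reads))
  o1 <- order(reads$read_id); o2 <- order(back$read_id)
  expect_true(all(reads$seq[o1] == back$seq[o2]))
  expect_true(all(reads$qual[o1] == back$qual[o2]))
  expect_true(all(reads$pos[o1] == back$pos[o2]))
  expect_true(all(reads$gene[o1] == back$gene[o2]))

  dir <- tempfile(); write_truth_tables(truth, dir)
  snvs_back <- readr::read_tsv(file.path(dir, "truth_snvs.tsv"),
                               show_col_types = FALSE)
  expect_equal(nrow(snvs_back), nrow(truth$snvs))

  bed <- tempfile(fileext = ".bed"); write_truth_bed(truth, bed)
  gr <- rtracklayer::import(bed)
  expect_equal(length(gr),
               nrow(truth$snvs) + nrow(truth$ivt_artifacts) +
                 nrow(truth$modification_sites))

  cfg_file <- tempfile(fileext = ".tsv"); write_sim_config(cfg, cfg_file)
  snap <- readr::read_tsv(cfg_file, show_col_types = FALSE)
  expect_equal(nrow(snap), length(unclass(cfg)))
})
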