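qual_str <- function(q, n) intToUtf8(rep(q + 33L, n))

make_profile <- function(kmers, means, k = 9L) {
  out <- tibble::tibble(kmer = kmers, mean_quality = means,
                        n_obs = 1L)
  attr(out, "k") <- k
  attr(out, "mode") <- "center"
  class(out) <- c("kmer_quality_profile", class(out))
  out
}

test_that("constant qualities give a constant profile; means average occurrences", {
  ref <- make_ref(c1 = "ACGTACGTACGTACGTACGTA")
  aln <- make_aln(list(
    list(contig = "c1", pos = 0L, seq = "ACGTACGTACGTA",
         qual = qual_str(20, 13))
  ))
  prof <- profile_kmer_quality(aln, ref, k = 9)
  expect_true(all(prof$mean_quality == 20))

  # one context observed twice with center qualities 10 and 30 -> mean 20
  ref2 <- make_ref(c1 = "AACCGGTTAAT")
  q1 <- paste0(qual_str(25, 4), qual_str(10, 1), qual_str(25, 4))
  q2 <- paste0(qual_str(25, 4), qual_str(30, 1), qual_str(25, 4))
  aln2 <- make_aln(list(
    list(contig = "c1", pos = 0L, seq = "AACCGGTTA", qual = q1),
    list(contig = "c1", pos = 0L, seq = "AACCGGTTA", qual = q2)
  ))
  prof2 <- profile_kmer_quality(aln2, ref2, k = 9)
  target <- prof2[prof2$kmer == "AACCGGTTA", ]   # context centered at pos 4
  expect_equal(target$mean_quality, 20)
  expect_equal(target$n_obs, 2L)
})

test_that("mean-over-window mode averages all k aligned qualities", {
  ref <- make_ref(c1 = "AACCGGTTAAT")
  q <- intToUtf8(33L + c(10L, 20L, 30L, 10L, 20L, 30L, 10L, 20L, 30L))
  aln <- make_aln(list(list(contig = "c1", pos = 0L, seq = "AACCGGTTA",
                            qual = q)))
  prof <- profile_kmer_quality(aln, ref, k = 9, mode = "all")
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean_quality, mean(c(10, 20, 30, 10, 20, 30, 10, 20, 30)))
})

test_that("missing quality strings are an input error and k must be odd", {
  ref <- make_ref(c1 = "ACGTACGTACGT")
  aln <- make_aln(list(list(contig = "c1", pos = 0L, seq = "ACGT", qual = "*")))
  expect_error(profile_kmer_quality(aln, ref), class = "ivt_input_error")
  aln2 <- make_aln(list(list(contig = "c1", pos = 0L, seq = "ACGT")))
  expect_error(profile_kmer_quality(aln2, ref, k = 8),
               class = "ivt_config_error")
})

test_that("the lowest-quartile rule selects by nearest rank with inclusive ties", {
  prof <- make_profile(c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG", "TTTTTTTTT"),
                       c(5, 10, 15, 20))
  sel <- select_low_confidence(prof, 0.25)
  expect_equal(sel$kmer, "AAAAAAAAA")
  expect_equal(attr(sel, "cutoff"), 5)

  tied <- make_profile(sprintf("AAAA%sAAAA", c("A", "C", "G", "T")),
                       rep(12, 4))
  sel2 <- select_low_confidence(tied, 0.25)
  expect_equal(nrow(sel2), 4L)              # degenerate tie: all selected

  expect_error(select_low_confidence(prof, 0), class = "ivt_config_error")
  expect_error(select_low_confidence(prof, 1), class = "ivt_config_error")
  expect_error(select_low_confidence(prof[0, ]), class = "ivt_input_error")
})

test_that("selection matches a sort-and-slice oracle on many k-mers", {
  set.seed(53)
  n <- 1000L
  kmers <- unique(replicate(n + 200L, paste0(sample(c("A", "C", "G", "T"), 9,
                                                    replace = TRUE),
                                             collapse = "")))[seq_len(n)]
  means <- round(runif(n, 3, 35), 2)
  prof <- make_profile(kmers, means)
  sel <- select_low_confidence(prof, 0.25)
  # sort-and-slice oracle, bracketed by tie handling at the quartile boundary
  boundary <- sort(means)[ceiling(0.25 * n)]
  expect_true(all(kmers[means < boundary] %in% sel$kmer))
  expect_true(all(sel$kmer %in% kmers[means <= boundary]))
  # the selected mass never exceeds the quantile plus its boundary tie class
  expect_lte(nrow(sel), sum(means <= boundary))
})

test_that("two-level quality simulation recovers the truth low-quality set exactly", {
  cfg <- sim_config(n_contigs = 1, contig_length = 4000, n_genes = 2,
                    n_genomic_snv = 0, n_ivt_artifacts = 0,
                    n_modification_sites = 0, background_error_rate = 0,
                    n_low_quality_kmers = 40, reads_per_sample = 150,
                    read_length_mean = 2000, seed = 59)
  ref <- generate_reference(cfg)
  truth <- simulate_truth(ref, cfg)
  reads <- simulate_reads(ref, truth, "biological", cfg)
  prof <- profile_kmer_quality(reads, ref, k = 9)
  # with zero noise the two classes separate exactly
  lowq_means <- prof$mean_quality[prof$kmer %in% truth$low_quality_kmers]
  high_means <- prof$mean_quality[!prof$kmer %in% truth$low_quality_kmers]
  expect_true(all(lowq_means == cfg$base_quality_low))
  expect_true(all(high_means == cfg$base_quality_high))

  sel <- select_low_confidence(prof, 0.25)
  observed_truth <- intersect(truth$low_quality_kmers, prof$kmer)
  # truth mass is far below a quartile of profiled k-mers, so the selected
  # set is exactly the observed truth low-quality class
  expect_lt(length(observed_truth), 0.25 * nrow(prof))
  expect_setequal(sel$kmer, observed_truth)
})

test_that("lowering the low-quality phred never shrinks truth recovery", {
  overlap_at <- function(qlow) {
    cfg <- sim_config(n_contigs = 1, contig_length = 3000, n_genes = 2,
                      n_genomic_snv = 0, n_ivt_artifacts = 0,
                      n_modification_sites = 0, background_error_rate = 0,
                      n_low_quality_kmers = 30, reads_per_sample = 100,
                      read_length_mean = 1500, base_quality_low = qlow,
                      seed = 61)
    ref <- generate_reference(cfg)
    truth <- simulate_truth(ref, cfg)
    prof <- profile_kmer_quality(simulate_reads(ref, truth, "biological", cfg),
                                 ref, k = 9)
    sel <- select_low_confidence(prof, 0.25)
    length(intersect(sel$kmer, truth$low_quality_kmers))
  }
  o <- vapply(c(20L, 12L, 5L), overlap_at, integer(1))
  expect_true(all(diff(o) >= 0))
})

test_that("membership lookup equals a substring oracle and logs edge positions", {
  ref <- make_ref(c1 = "ACGTACGTACGTACGTACGTACGTACGT")
  set_kmers <- c("GTACGTACG", "CGTACGTAC")
  set <- tibble::tibble(kmer = set_kmers, mean_quality = 5)
  attr(set, "k") <- 9L
  class(set) <- c("kmer_confidence_set", class(set))

  s <- as.character(ref$sequences)[[1]]
  inner <- 4:(nchar(s) - 5)
  got <- in_low_confidence(ref, rep("c1", length(inner)), inner, set)
  want <- vapply(inner, function(p) substr(s, p - 3, p + 5) %in% set_kmers,
                 logical(1))
  expect_equal(got, want)
  expect_true(any(got))

  expect_message(
    edge <- in_low_confidence(ref, "c1", 3L, set),
    "edge")
  expect_false(edge)
  expect_error(in_low_confidence(ref, "nope", 10L, set),
               class = "ivt_input_error")
})

test_that("k-mer sets round-trip through TSV with their metadata", {
  set <- tibble::tibble(kmer = c("AAAACAAAA", "AAAAGAAAA"),
                        mean_quality = c(6.25, 7.5))
  attr(set, "k") <- 9L
  attr(set, "quantile") <- 0.25
  attr(set, "cutoff") <- 7.5
  class(set) <- c("kmer_confidence_set", class(set))
  tf <- tempfile(fileext = ".tsv")
  write_kmer_set(set, tf)
  back <- read_kmer_set(tf)
  expect_equal(back$kmer, set$kmer)
  expect_equal(back$mean_quality, set$mean_quality)
  expect_equal(attr(back, "k"), 9L)
  expect_equal(attr(back, "quantile"), 0.25)
  expect_equal(attr(back, "cutoff"), 7.5)
})
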