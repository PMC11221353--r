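---
title: "IVT negative controls for DRS modification analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVT negative controls for DRS modification analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtcontrol)
```

## The model

Nanopore direct RNA sequencing (DRS) reads native RNA, so chemically
modified nucleotides perturb the ionic-current signal and are frequently
basecalled as the wrong canonical base. A position where biological DRS
reads systematically mismatch the reference is therefore *evidence* of a
modification — but only after every other cause of a systematic mismatch
is ruled out: genomic variation in the sample, errors fixed into the
template during in vitro transcription (IVT), and sequence contexts where
the basecaller is unreliable regardless of modification state.

The IVT control makes this separation operational. IVT re-synthesises the
transcriptome from cDNA with canonical NTPs only, erasing modifications
while preserving sequence. The package's pipeline is the counting-and-
filtering procedure built on that idea:

1. **Pileup.** For each sample, count A/C/G/T read bases and deletions at
   every reference position covered by a primary alignment
   (`build_pileup()`). Insertions occupy no reference coordinate and are
   ignored. The invariant `A + C + G + T + del = depth` holds at every
   row, which makes `depth` exactly the denominator of the next step.
2. **Mismatch occurrence fraction.** At every position with
   `depth >= min_coverage` (default 10) and at least one non-reference
   call, each alternate base becomes a record with
   `fraction = alt_count / depth` — i.e. occurrences of the variant
   relative to canonical bases *plus deletions* at the location
   (`call_candidates()`). Deletions dilute the fraction but are never
   themselves emitted as variants.
3. **Threshold sweep.** Records are filtered at occurrence thresholds of
   30, 40, 50, 60, 70, 80 and 95 percent (`threshold_sweep()`); the
   comparison is inclusive (`>=`), so a fraction exactly at a cutoff
   survives. The retained sets are nested by construction and each is
   exported as a single-base BED track for IGV (`write_threshold_beds()`).
4. **Pooling.** Per-sample pileups are summed position-wise into a pooled
   "panIVT" (`merge_pileups()`); pooling is associative and commutative
   and can only increase depth, which is the point — it maximises the
   covered gene space of the control.
5. **Classification.** Each flagged mismatch lands in exactly one of three
   bins: *known variant* (present in a user-supplied VCF/TSV catalog),
   *low-confidence 9-mer* (its centered reference context is in the
   low-confidence set), or *novel*. Precedence is known > low-confidence >
   novel, which is what makes the bins a partition.
6. **Decision.** For a biological sample screened against the control,
   every biological mismatch position at the chosen threshold receives one
   verdict (`apply_decisions()`): `exclude` if the IVT control mismatches
   there too (whatever the bin — a mismatched baseline is unusable),
   `candidate` if the IVT matches the reference with adequate coverage,
   `needs_orthogonal` if the IVT has no usable coverage, `no_evidence`
   otherwise.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_coverage` | 10 | reads | below ~10x a single read moves the fraction by >= 10 points; the floor keeps fractions interpretable |
| `thresholds` | 30...95 | % of reads | 30 % is a stringent screen; individual experiments may raise the threshold to trade specificity for candidate yield |
| `k` | 9 | bases | matches the sequence context a nanopore basecaller effectively conditions on |
| `quantile` | 0.25 | fraction of 9-mer types | "lowest quartile" of mean phred per context |
| `bio_threshold` | = IVT threshold | % | the biological mismatch state has its own threshold so the two screens can be decoupled |

The low-confidence quantile cutoff deserves a note. The cutoff is the
largest observed mean quality whose cumulative fraction of 9-mer *types*
(each context counted once, not occurrence-weighted) does not exceed the
quantile; membership is `<=` the cutoff, so ties at the boundary are all
included. With all-distinct means and `n` divisible by 4 this selects
exactly `n/4` contexts. With heavily tied means — the practically
important case of a basecaller with a bimodal per-context quality profile
— it selects the entire low-quality tie class and nothing above it. A
nearest-rank cutoff would instead land *inside* the high-quality class
and, with inclusive ties, select every context; we consider that behaviour
a defect, not a convention, and do not implement it.

Quality attribution is the **center-base rule**: the quality of the read
base aligned to the center of the reference 9-mer, because variant
positions are classified by their centered context. A mean-over-all-nine
mode (`mode = "all"`) exists for sensitivity analysis; neither mode is
asserted to be the only defensible reading of "the quality of a 9-mer".
Likewise, known-variant matching defaults to `(contig, position, alt)`
but offers a position-only mode, since public catalogs sometimes report
alleles on the opposite strand; the mode used is recorded on the result.

Occurrence fractions are **per alternate base** (one record per alt), on
the reading that a "variant" is a specific substitution; an aggregate
mode (`aggregate = TRUE`), which pools all non-reference substitutions at
a position, is provided for sensitivity analysis rather than asserted as
intent.

## The simulator: what it emulates, and what it does not

`sim_config()` fixes the synthetic study conditions. Defaults: 2 contigs
of 20 kb, 30 genes tiling ~90 % of each contig, Zipf abundance with
exponent 1.2 (a long-tailed transcriptome), 500 reads per sample with
mean length 1 kb (DRS-scale reads, clamped to their gene), 10 genomic
SNVs at allele fraction 1, 8 IVT artifacts at occurrence 0.8, 8
modification sites miscalling at rate 0.5, uniform background
substitution error 0.02, and a two-level base-quality scheme (Q25
everywhere, Q7 at the centers of 20 designated reference 9-mers; Q7
matches the conventional basecaller pass threshold). These are desk-scale
renditions of a realistic DRS experiment: large enough that every
pipeline stage sees non-trivial input, small enough that the entire test
suite runs in minutes on one core.

Semantics worth stating precisely:

- Genomic SNVs substitute in both modes at their allele fraction; IVT
  artifacts only in IVT mode; modification miscalls only in biological
  mode. An event position *inactive in the current mode* (e.g. a
  modification site seen by IVT reads) behaves as ordinary background, so
  IVT pileups at modification sites carry background-rate noise rather
  than implausible zero-error columns. Active event positions are
  shielded from additional background error.
- Background alt bases are uniform over the three non-reference bases.
- Reads are emitted pre-aligned with perfect coordinates and
  substitutions only (plus an optional deletion process,
  `deletion_rate`, which exercises the deletion-aware denominator);
  the pipeline's scope starts after alignment.
- Each sample uses RNG stream `seed + sample_index`, so adding a sample
  never perturbs existing ones, and identical configurations are
  byte-reproducible.

What it does **not** emulate: signal-level data, splicing, reverse-strand
alignments, indel realignment ambiguity, coverage decay along transcripts,
or any quality-miscalibration structure beyond the two-level 9-mer
scheme. Passing tests therefore demonstrate the *counting, filtering and
decision logic* under controlled truth, not basecaller realism: on real
data the low-confidence set is an empirical quartile rather than a
recoverable truth class, and occurrence fractions carry correlated error
the simulator does not model.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally and in BED/TSV;
  1-based rendering appears only in human-readable messages.
- Positions within 4 bases of a contig edge have no full 9-mer context;
  `in_low_confidence()` returns `FALSE` there and reports the count, so
  edge positions can only fall into the known or novel bins.
- `merge_pileups()` refuses to merge pileups that disagree on the
  reference base at any shared coordinate.
- An empty threshold bin still yields a valid, empty BED file.
- `saturation_curve()` draws one permutation per population sample per
  repeat and scores prefixes. Every prefix of a uniform permutation is a
  uniform without-replacement subsample, so the averaged curve is
  distributed identically to literal independent redraws at each size
  (the test suite checks this against an independent redraw oracle with a
  10x repeat budget); per-repeat curves are monotone as a side effect.
  Population samples smaller than a requested draw contribute all their
  reads, with a warning.
- The saturation score is **intersection over target**:
  `|population genes ∩ target genes| / |target genes|`, a proportion in
  [0, 1]. The literal union-over-target ratio is >= 1 by construction and
  cannot be the plotted "proportion of covered genes"; it remains
  available via `score = "union"` for auditability.
- Round-robin repeats default to 100 and are a recorded parameter rather
  than a constant, since reasonable protocols repeat the resampling
  anywhere from 100 to 500 times; draws are split equally across the five
  population samples at each combined size.
- `naive_tpm()` is exactly `rate_i / sum(rate) * 1e6` with
  `rate = count / length`; no EM reassignment of ambiguous reads. It is a
  documented simplification, adequate for correlating paired samples at
  gene level, and `tpm_correlation()` reports r² on log10 TPM over ids
  positive in both samples (linear-scale mode available).
- Decisions are per position (any alternate base), since the screening
  question — "is this position usable?" — is positional.

## Problem sizes

The shipped tests simulate contigs of 1–4 kb with 20–300 reads per sample
(pileup-oracle checks use ten ~50 kb-base samples; SNV recovery uses 100
replicates at 100x coverage; saturation uses 10,000-read targets with
1,000-read steps). The acceptance script runs the default 2 × 20 kb /
6 + 1 sample design end to end. These sizes were chosen so each
statistical check has enough events to be meaningful while the whole
suite stays comfortably interactive.

## Known limitations

- Strand-unaware counting on the forward reference strand assumes
  sense-strand DRS alignments; a reverse-strand primary alignment would
  be counted without complementing.
- The known-variant matcher does not normalise indel representations or
  strand-flip alleles; position-only mode is the blunt workaround.
- The three-bin precedence (known > low-confidence > novel) is a
  convention required for the bins to partition; a site can genuinely be
  both a known variant and a low-confidence context.
- `needs_orthogonal` encodes "no IVT baseline" as an explicit verdict;
  the package deliberately stops at candidate nomination and does not
  attempt modification-type calling or signal-level corroboration.
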