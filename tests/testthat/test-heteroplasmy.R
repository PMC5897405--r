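# Read filtering, duplicate marking, window reconstruction, motif
# extraction, spectra and site classification.

oril <- oril_site()
ref <- make_reference(oril, flank = 200L)

test_that("read filter discards strictly below the quality and length bounds", {
  q299 <- qual_str(c(rep(30L, 39L), 26L))          # mean 29.9
  q300 <- qual_str(rep(30L, 40L))                  # mean 30.0
  reads <- rbind(make_read(10L, "40M", qual = q299, qname = "lowq"),
                 make_read(10L, "40M", qual = q300, qname = "boundary"),
                 make_read(10L, "29M", qual = qual_str(rep(40L, 29L)),
                           qname = "short"),
                 make_read(10L, "30M", qual = qual_str(rep(30L, 30L)),
                           qname = "keep30"),
                 make_read(10L, "40M", flag = 0L, qname = "unpaired"))
  res <- filter_reads(reads)
  expect_setequal(res$reads$qname, c("boundary", "keep30"))
  rep_ <- setNames(res$report$n_removed, res$report$criterion)
  expect_equal(unname(rep_["mean_quality"]), 1L)
  expect_equal(unname(rep_["length"]), 1L)
  expect_equal(unname(rep_["missing_mate"]), 1L)
})

test_that("empty input filters to an empty output with a zero report", {
  res <- filter_reads(parse_sam(c("@HD\tVN:1.6")))
  expect_equal(nrow(res$reads), 0L)
  expect_true(all(res$report$n_removed == 0L))
})

test_that("duplicate marking keeps one read per coordinate/structure key", {
  r <- make_read(100L, "40M", qname = "a")
  r2 <- r; r2$qname <- "b"
  both <- rbind(r, r2)
  marked <- mark_duplicates(both)
  expect_equal(sum(marked$is_duplicate), 1L)

  diff_cigar <- rbind(make_read(100L, "40M", qname = "a"),
                      make_read(100L, "20M1I19M", qname = "b"))
  expect_equal(sum(mark_duplicates(diff_cigar)$is_duplicate), 0L)

  # the highest summed quality survives
  hi <- make_read(100L, "40M", qual = qual_str(rep(40L, 40L)), qname = "hi")
  lo <- make_read(100L, "40M", qual = qual_str(rep(20L, 40L)), qname = "lo")
  m <- mark_duplicates(rbind(lo, hi))
  expect_identical(m$qname[!m$is_duplicate], "hi")
})

test_that("k-fold duplicated simulator reads collapse to the originals", {
  sim <- simulate_polyA_reads(oril, c("11" = 1), n_reads = 100L, seed = 9,
                              substitution_rate = 0, slippage_rate = 0,
                              duplicate_rate = 0.5)
  marked <- mark_duplicates(sim$reads)
  strand <- ifelse(bitwAnd(marked$flag, 0x10L) > 0L, "-", "+")
  n_keys <- length(unique(paste(marked$rname, marked$pos, marked$cigar,
                                strand, marked$pnext)))
  expect_equal(sum(!marked$is_duplicate), n_keys)
  # every truth-marked PCR copy shares its fragment key with its original,
  # so the survivor count cannot exceed the number of original fragments
  expect_lte(sum(!marked$is_duplicate), 100L)
})

test_that("window reconstruction matches the CIGAR walk for M/I/D cases", {
  rd <- make_read(100L, "40M", seq = paste(rep("ACGT", 10L), collapse = ""))
  w <- reconstruct_window(rd, c(110L, 120L))
  expect_equal(w$seq, substr(rd$seq, 11L, 20L))
  expect_equal(length(w$qual), 10L)

  ins <- make_read(100L, "12M1I27M")
  wi <- reconstruct_window(ins, c(105L, 120L))
  expect_equal(nchar(wi$seq), 16L)      # one inserted base inside the window

  del <- make_read(100L, "15M1D24M")
  wd <- reconstruct_window(del, c(105L, 120L))
  expect_equal(nchar(wd$seq), 14L)      # one reference base unobserved

  expect_null(reconstruct_window(rd, c(90L, 120L)))   # not spanning
})

test_that("an error-free reference read yields the reference run length", {
  rd <- reference_read(ref, 5100L)
  ob <- extract_motif(rd, oril)
  expect_true(ob$accepted)
  expect_equal(ob$run_length, 11L)
})

test_that("run-length indels in the CIGAR shift the called length", {
  i <- function(p) p - ref$start + 1L
  pos <- 5100L
  pre <- 5172L - pos                     # bases before the A run
  # 12A molecule: one A inserted, left-aligned at the run start
  seq12 <- paste0(substr(ref$seq, i(pos), i(5171L)), strrep("A", 12L),
                  substr(ref$seq, i(5183L), i(5183L) + 150L - pre - 13L))
  rd12 <- make_read(pos, paste0(pre, "M1I", 150L - pre - 1L, "M"), seq = seq12)
  expect_equal(extract_motif(rd12, oril)$run_length, 12L)
  # same molecule, right-aligned insertion: identical call
  rd12r <- make_read(pos, paste0(pre + 11L, "M1I", 150L - pre - 12L, "M"),
                     seq = seq12)
  expect_equal(extract_motif(rd12r, oril)$run_length, 12L)
  # 10A molecule: one base deleted
  seq10 <- paste0(substr(ref$seq, i(pos), i(5171L)), strrep("A", 10L),
                  substr(ref$seq, i(5183L), i(5183L) + 150L - pre - 11L))
  rd10 <- make_read(pos, paste0(pre, "M1D", 150L - pre, "M"), seq = seq10)
  expect_equal(extract_motif(rd10, oril)$run_length, 10L)
})

test_that("motif observations below mean quality 20 are discarded, 20 kept", {
  rd <- reference_read(ref, 5100L)
  # motif covers the anchor (index 72 in the read) plus the 11 A's
  motif_idx <- 72:83
  q <- rep(35L, 150L)
  q[motif_idx] <- c(rep(20L, 6L), rep(19L, 6L))   # mean 19.5
  ob <- extract_motif(make_read(5100L, "150M",
                                seq = rd$seq, qual = qual_str(q)), oril)
  expect_false(ob$accepted)
  expect_equal(ob$reason, "low_quality")
  q[motif_idx] <- 20L                              # mean exactly 20: retained
  ob2 <- extract_motif(make_read(5100L, "150M",
                                 seq = rd$seq, qual = qual_str(q)), oril)
  expect_true(ob2$accepted)
})

test_that("reads ending inside the run are censored, not truncated", {
  # read covers anchor + first 7 A's only
  rd <- reference_read(ref, 5100L, len = 5178L - 5100L + 1L)
  ob <- extract_motif(rd, oril)
  expect_false(ob$accepted)
  expect_false(ob$spanning)
  expect_equal(ob$reason, "not_spanning")
  # read starting after the anchor window cannot contribute either
  late <- reference_read(ref, 5172L, len = 50L)
  expect_equal(extract_motif(late, oril)$reason, "not_spanning")
})

test_that("spectra count and normalise observed run lengths", {
  sp <- count_spectrum(c(11L, 11L, 12L, 11L), oril)
  expect_equal(sp$total, 4L)
  expect_equal(unname(sp$fractions[c("11", "12")]), c(0.75, 0.25))
  met <- heteroplasmy_metrics(sp)
  expect_equal(met$plus_one_fraction, 0.25)
  expect_equal(met$gt_ref_fraction, 0.25)

  empty <- count_spectrum(integer(0L), oril)
  expect_equal(empty$total, 0L)
  expect_length(empty$fractions, 0L)
  expect_error(heteroplasmy_metrics(empty), "empty spectrum")
})

test_that("metrics aggregate fractions above the reference length", {
  sp <- count_spectrum(rep(c(11L, 12L, 13L), c(70L, 20L, 10L)), oril)
  met <- heteroplasmy_metrics(sp)
  expect_equal(met$gt_ref_fraction, 0.3)
  expect_equal(met$ref_fraction, 0.7)
  sp1 <- count_spectrum(rep(11L, 10L), oril)
  expect_equal(heteroplasmy_metrics(sp1)$gt_ref_fraction, 0)
})

test_that("spectrum fractions sum to one across random mixtures", {
  set.seed(21)
  for (rep_i in 1:20) {
    lens <- sample(8:14, sample(2:5, 1L))
    sp <- count_spectrum(sample(lens, 500L, replace = TRUE), oril)
    expect_lt(abs(sum(sp$fractions) - 1), 1e-12)
  }
})

test_that("pileup counts only bases at or above the quality floor", {
  # 100 reads over position 5171: 95 carry T (alt), 5 carry G (ref)
  base_seq <- function(b) {
    s <- reference_read(ref, 5150L, len = 60L)$seq
    substr(s, 5171L - 5150L + 1L, 5171L - 5150L + 1L) <- b
    s
  }
  reads <- do.call(rbind, c(
    lapply(1:95, function(k) make_read(5150L, "60M", seq = base_seq("T"),
                                       qname = paste0("t", k))),
    lapply(1:5, function(k) make_read(5150L, "60M", seq = base_seq("G"),
                                      qname = paste0("g", k)))))
  pu <- pileup_frequencies(reads, 5171L)
  expect_equal(unname(pu$counts["T"]), 95L)
  expect_equal(unname(pu$frequencies["T"]), 0.95)

  lowq <- make_read(5150L, "60M", seq = base_seq("T"),
                    qual = qual_str(rep(20L, 60L)))
  pu2 <- pileup_frequencies(lowq, 5171L, min_base_quality = 30)
  expect_equal(pu2$depth_used, 0L)
  expect_length(pu2$frequencies, 0L)
  expect_equal(pu2$n_below_quality, 1L)
})

test_that("deletions spanning the position register as depth loss", {
  rd <- make_read(5150L, "10M5D50M")
  pu <- pileup_frequencies(rd, 5162L)
  expect_equal(pu$n_deletion, 1L)
  expect_equal(pu$depth_used, 0L)
})

test_that("site classification applies the 40/90 bands with stated
           boundary semantics", {
  expect_equal(classify_site(0.95), "homoplasmic")
  expect_equal(classify_site(0.65), "heteroplasmic")
  expect_equal(classify_site(0.10), "low_level")
  expect_equal(classify_site(0.90), "heteroplasmic")  # 90% inclusive
  expect_equal(classify_site(0.40), "heteroplasmic")  # 40% inclusive
  expect_error(classify_site(1.2), "\\[0, 1\\]")
  expect_error(classify_site(-0.1), "\\[0, 1\\]")
})

test_that("extraction matches the brute-force oracle on mixed CIGAR reads", {
  sim <- simulate_polyA_reads(
    oril, c("9" = 0.05, "10" = 0.1, "11" = 0.55, "12" = 0.2, "13" = 0.1),
    n_reads = 1500L, seed = 31, substitution_rate = 0.01,
    slippage_rate = 0.05, soft_clip_rate = 0.3,
    indel_align = sample(c("left", "right"), 1L))
  agree <- vapply(seq_len(nrow(sim$reads)), function(i) {
    a <- extract_motif(sim$reads[i, ], oril)
    b <- oracle_extract_motif(sim$reads[i, ], oril)
    identical(a$run_length, b$run_length) &&
      identical(a$accepted, b$accepted) && identical(a$reason, b$reason)
  }, logical(1L))
  expect_true(all(agree))
})

test_that("filtering and duplicate marking commute on simulator output", {
  sim <- simulate_polyA_reads(oril, c("11" = 0.7, "12" = 0.3),
                              n_reads = 400L, seed = 13,
                              duplicate_rate = 0.3, quality_mean = 31,
                              quality_sd = 4)
  a <- drop_duplicates(mark_duplicates(filter_reads(sim$reads)$reads))
  b0 <- drop_duplicates(mark_duplicates(sim$reads))
  b <- filter_reads(b0)$reads
  spec_a <- count_spectrum(extract_motifs(a, oril), oril)
  spec_b <- count_spectrum(extract_motifs(b, oril), oril)
  expect_equal(spec_a$counts, spec_b$counts)
})
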