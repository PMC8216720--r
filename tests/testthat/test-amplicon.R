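amp <- make_amplicon()
REF <- amplicon_ref(amp$sequence, amp$start_codon)
SC <- amp$start_codon

ins_read <- function(base, at = SC) {
  paste0(substr(amp$sequence, 1, at), base,
         substr(amp$sequence, at + 1, nchar(amp$sequence)))
}
del_read <- function(at, len) {
  paste0(substr(amp$sequence, 1, at - 1),
         substr(amp$sequence, at + len, nchar(amp$sequence)))
}

test_that("median-quality filter applies <= semantics and the exact median", {
  mkread <- function(quals) data.frame(
    id = "r", seq = strrep("A", length(quals)),
    qual = rawToChar(as.raw(quals + 33L)), stringsAsFactors = FALSE)
  # all bases Q5 -> removed; all Q6 -> retained
  expect_equal(nrow(filter_reads_by_median_quality(
    mkread(rep(5, 20)))$retained), 0)
  expect_equal(nrow(filter_reads_by_median_quality(
    mkread(rep(6, 20)))$retained), 1)
  # even-length median is the mean of the two central order statistics
  expect_equal(nrow(filter_reads_by_median_quality(
    mkread(c(5, 5, 6, 40)))$retained), 1)   # median 5.5 > 5
  expect_equal(nrow(filter_reads_by_median_quality(
    mkread(c(4, 5, 5, 40)))$retained), 0)   # median 5
  # random qualities agree with a sort-and-pick-middle oracle
  set.seed(12)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    q <- sample(2:40, n, TRUE)
    kept <- nrow(filter_reads_by_median_quality(mkread(q))$retained) == 1
    mid <- sort(q)[c(ceiling(n / 2), floor(n / 2) + 1)]
    expect_equal(kept, mean(mid) > 5)
  }
  expect_error(filter_reads_by_median_quality(
    data.frame(id = "r", seq = "ACGT", qual = "III")), "malformed")
})

test_that("batched median filtering matches per-read filtering", {
  spec <- amplicon_spec(amp$sequence, SC, n_reads = 300, qual_mean = 6,
                        qual_sd = 2, seed = 31)
  sim <- simulate_amplicon_reads(spec)
  batch <- filter_reads_by_median_quality(sim$reads)
  slow <- vapply(sim$reads$qual, function(q)
    median(utf8ToInt(q) - 33L) > 5, logical(1), USE.NAMES = FALSE)
  expect_equal(batch$retained$id, sim$reads$id[slow])
})

test_that("alignment extracts and left-aligns the expected events", {
  a0 <- align_to_amplicon(amp$sequence, REF)
  expect_equal(nrow(a0$events), 0)

  # A inserted between the A and T of ATG left-aligns into the upstream C|A
  # boundary but its placement interval still covers the codon
  aA <- align_to_amplicon(ins_read("A"), REF)
  expect_equal(nrow(aA$events), 1)
  expect_equal(aA$events$type, "ins")
  expect_equal(aA$events$length, 1)
  expect_equal(aA$events$bases, "A")
  expect_equal(aA$events$at, SC - 1)  # leftmost placement, before the A

  aT <- align_to_amplicon(ins_read("T"), REF)
  expect_equal(aT$events$at, SC)      # T cannot shift left past the A

  a2 <- align_to_amplicon(del_read(SC, 2), REF)
  expect_equal(a2$events$type, "del")
  expect_equal(a2$events$length, 2)
  expect_error(align_to_amplicon("", REF), "empty")
})

test_that("alignment scores equal the quadratic DP oracle", {
  set.seed(17)
  small_ref <- amplicon_ref(paste0(random_dna(20), "ATG", random_dna(37)),
                            21)
  for (i in 1:25) {
    read <- random_dna(sample(40:60, 1))
    got <- align_to_amplicon(read, small_ref)$score
    want <- oracle_global_score(read, small_ref$sequence)
    expect_equal(got, want, info = read)
  }
})

test_that("classify_read applies the category rules inside the window", {
  cl <- function(read) classify_read(align_to_amplicon(read, REF), REF)
  expect_equal(cl(amp$sequence)$category, "no_change")
  expect_equal(cl(ins_read("A"))$category, "insertion")
  d2 <- cl(del_read(SC, 2))
  expect_equal(d2$category, "deletion")
  expect_equal(d2$indel_length, 2)
  # 1-bp insertion plus 3-bp deletion in the window -> deletion (3 > 1)
  both <- paste0(substr(amp$sequence, 1, SC - 8), "G",
                 substr(amp$sequence, SC - 7, SC - 1),
                 substr(amp$sequence, SC + 3, nchar(amp$sequence)))
  b <- cl(both)
  expect_equal(b$category, "deletion")
  # equal totals tie to insertion
  tie <- paste0(substr(amp$sequence, 1, SC - 8), "G",
                substr(amp$sequence, SC - 7, SC),
                substr(amp$sequence, SC + 2, nchar(amp$sequence)))
  expect_equal(cl(tie)$category, "insertion")
  # an indel far outside the window is ignored
  far <- paste0(substr(amp$sequence, 1, 2),
                substr(amp$sequence, 4, nchar(amp$sequence)))
  expect_equal(cl(far)$category, "no_change")
  # reads not covering the whole window are discarded as truncated
  half <- substr(amp$sequence, SC + 5, nchar(amp$sequence))
  expect_equal(cl(half)$category, "discarded")
  expect_equal(cl(half)$reason, "truncated")
})

test_that("indel_summary reproduces the printed count arithmetic", {
  s <- indel_summary_from_counts(87554, 68228, 16378, 2948)
  expect_equal(s$pct_no_change, 77.9)
  expect_equal(s$pct_insertion, 18.7)
  expect_equal(s$pct_deletion, 3.4)
  expect_equal(s$pct_indel, 22.1)
  expect_equal(s$n_indel, 19326)
  # all no-change
  s0 <- indel_summary(rep("no_change", 10))
  expect_equal(s0$pct_indel, 0)
  expect_error(indel_summary(character(0)), "zero")
  expect_error(indel_summary_from_counts(100, 90, 20, 10), "sum")
})

test_that("categories partition reads and percentages are conservative", {
  sp <- study_spectrum(0.3, SC)
  spec <- amplicon_spec(amp$sequence, SC, sp, n_reads = 4000, seed = 19)
  q <- quantify_amplicon(simulate_amplicon_reads(spec)$reads, REF)
  s <- indel_summary(q)
  expect_equal(s$n_no_change + s$n_indel, s$total_reads)
  expect_equal(s$n_insertion + s$n_deletion, s$n_indel)
  sp2 <- size_spectrum(q)
  expect_equal(sum(sp2$insertion$n), s$n_insertion)
  expect_equal(sum(sp2$deletion$n), s$n_deletion)
  # histogram mass adds up to the category percentages (unrounded scale)
  expect_equal(sum(sp2$insertion$pct), 100 * s$n_insertion / s$total_reads)
})

test_that("single-insertion composition counts codon insertions only", {
  reads <- data.frame(
    id = sprintf("r%02d", 1:6),
    seq = c(ins_read("A"), ins_read("T"), ins_read("G"), ins_read("C"),
            ins_read("A", at = 10L),   # far from the codon: not counted
            amp$sequence),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  q <- quantify_amplicon(reads, REF)
  comp <- insertion_base_composition(q)
  expect_equal(comp$total, 4)
  expect_equal(unname(comp$counts), c(1, 1, 1, 1))
  # Table 2 count arithmetic
  t2 <- composition_from_counts(7925, 6703, 230, 797)
  expect_equal(t2$total, 15655)
  expect_equal(unname(t2$pct), c(50.6, 42.8, 1.5, 5.1))
  # no qualifying reads -> absent, not 0/0
  q0 <- quantify_amplicon(reads[6, , drop = FALSE], REF)
  expect_null(insertion_base_composition(q0))
})

test_that("kozak_assessment reports the -3 base of the (cryptic) ATG", {
  # unedited GACGCC|ATG context: -3 base G, favourable
  k0 <- kozak_assessment(REF)
  expect_true(k0$cryptic_atg_present)
  expect_equal(k0$minus3_base, "G")
  expect_true(k0$kozak_favorable)
  # A inserted between A and T creates a cryptic ATG with C at -3
  kA <- kozak_assessment(REF, data.frame(type = "ins", length = 1L,
                                         at = SC, bases = "A"))
  expect_true(kA$cryptic_atg_present)
  expect_equal(kA$minus3_base, "C")
  expect_false(kA$kozak_favorable)
  # G inserted between A and T leaves no ATG at the locus
  kG <- kozak_assessment(REF, data.frame(type = "ins", length = 1L,
                                         at = SC, bases = "G"))
  expect_false(kG$cryptic_atg_present)
  expect_error(kozak_assessment(REF, data.frame(type = "del", length = 1L,
                                                at = SC, bases = "")),
               "single-base insertion")
})

test_that("configured spectra are recovered within binomial error", {
  rate <- 0.25
  sp <- study_spectrum(rate, SC)
  spec <- amplicon_spec(amp$sequence, SC, sp, n_reads = 20000, seed = 23)
  q <- quantify_amplicon(simulate_amplicon_reads(spec)$reads, REF)
  s <- indel_summary(q)
  n <- s$total_reads
  expect_lt(abs(s$n_indel / n - rate), 3 * sqrt(rate * (1 - rate) / n))
  comp <- insertion_base_composition(q)
  for (b in c("A", "T", "G", "C")) {
    p <- c(A = 0.487, T = 0.446, G = 0.018, C = 0.049)[[b]]
    expect_lt(abs(comp$counts[[b]] / comp$total - p),
              3 * sqrt(p * (1 - p) / comp$total) + 1e-9)
  }
})
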