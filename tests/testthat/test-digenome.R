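mk_aln <- function(strand, pos, width, contig = "c1") {
  data.frame(qname = sprintf("r%03d", seq_along(pos)), contig = contig,
             strand = strand, pos = as.integer(pos),
             width = as.integer(width), stringsAsFactors = FALSE)
}

test_that("strand_start_profiles follows the read-start conventions", {
  # one forward read at 100, length 50
  p <- strand_start_profiles(mk_aln("+", 100, 50), region = c(90, 160))
  idx <- function(x) x - 90 + 1
  expect_equal(p$S_plus[idx(100)], 1)
  expect_equal(sum(p$S_plus), 1)
  expect_equal(p$D_plus[idx(100:149)], rep(1, 50))
  expect_equal(p$D_plus[idx(150)], 0)
  expect_equal(sum(p$S_minus), 0)
  expect_equal(sum(p$D_minus), 0)

  # one reverse read spanning [100, 149]: its 5' end is the rightmost base
  m <- strand_start_profiles(mk_aln("-", 100, 50), region = c(90, 160))
  expect_equal(m$S_minus[idx(149)], 1)
  expect_equal(sum(m$S_minus), 1)
  expect_equal(m$D_minus[idx(100:149)], rep(1, 50))

  expect_error(strand_start_profiles(mk_aln("+", c(200, 100), c(50, 50))),
               "sorted")
  expect_error(strand_start_profiles(mk_aln("+", 100, 50), contig = "nope"),
               "unknown contig")
})

test_that("profiles equal a position-by-position brute-force recount", {
  set.seed(42)
  n <- 200
  aln <- mk_aln(sample(c("+", "-"), n, TRUE), sample(1:900, n, TRUE),
                sample(30:80, n, TRUE))
  aln <- aln[order(aln$pos), ]
  prof <- strand_start_profiles(aln, region = c(1, 1000))
  ora <- oracle_profile(aln, 1, 1000)
  expect_equal(prof$S_plus, ora$S_plus)
  expect_equal(prof$D_plus, ora$D_plus)
  expect_equal(prof$S_minus, ora$S_minus)
  expect_equal(prof$D_minus, ora$D_minus)
  # S <= D everywhere, per strand
  expect_true(all(prof$S_plus <= prof$D_plus))
  expect_true(all(prof$S_minus <= prof$D_minus))
})

test_that("filter_start_positions applies both thresholds inclusively", {
  # S=5 of D=20 sits exactly at both boundaries -> kept
  aln5 <- mk_aln("+", c(rep(100, 5), 81:95), rep(40, 20))
  aln5 <- aln5[order(aln5$pos), ]
  prof <- strand_start_profiles(aln5)
  hits <- filter_start_positions(prof)
  row <- hits[hits$position == 100, ]
  expect_equal(row$S, 5)
  expect_equal(row$D, 20)
  expect_equal(row$perc, 25)

  # S=4 of D=4: 100% but below min_starts -> removed
  prof4 <- strand_start_profiles(mk_aln("+", rep(100, 4), rep(40, 4)))
  expect_equal(nrow(filter_start_positions(prof4)), 0)

  # S=13 of D=13 -> kept with perc 100 (the on-target plus strand)
  prof13 <- strand_start_profiles(mk_aln("+", rep(100, 13), rep(40, 13)))
  h13 <- filter_start_positions(prof13)
  expect_equal(h13$S, 13)
  expect_equal(h13$perc, 100)
})

test_that("raising thresholds never adds filtered positions", {
  set.seed(7)
  aln <- mk_aln(sample(c("+", "-"), 400, TRUE),
                sample(1:500, 400, TRUE) , sample(30:60, 400, TRUE))
  aln <- aln[order(aln$pos), ]
  prof <- strand_start_profiles(aln)
  base <- filter_start_positions(prof, detector_config(min_starts = 2,
                                                       min_frac = 0.05))
  for (ms in c(3, 5)) for (mf in c(0.1, 0.25)) {
    tighter <- filter_start_positions(prof,
                                      detector_config(min_starts = ms,
                                                      min_frac = mf))
    key <- function(df) paste(df$position, df$strand)
    expect_true(all(key(tighter) %in% key(base)))
  }
})

test_that("join_cut_sites pins the gap sign convention", {
  hit <- function(pos, strand) data.frame(
    contig = "c1", position = pos, strand = strand, S = 10, D = 10,
    perc = 100, stringsAsFactors = FALSE)
  j <- function(p, m) join_cut_sites(hit(p, "+"), hit(m, "-"))
  blunt <- j(101, 100)
  expect_equal(nrow(blunt), 1)
  expect_equal(blunt$gap, 0)
  expect_equal(blunt$geometry, "blunt")
  expect_equal(blunt$start, 101)

  gap1 <- j(102, 100)
  expect_equal(gap1$gap, 1)
  expect_equal(gap1$geometry, "gap1")

  over <- j(100, 100)
  expect_equal(over$gap, -1)
  expect_equal(over$geometry, "overhang1")
  expect_equal(over$start, 100)

  expect_equal(nrow(j(104, 100)), 0)
})

test_that("digenome_score reproduces the published totals and bounds", {
  expect_equal(round(digenome_score(13, 13, 5, 6), 2), 94.74)
  expect_equal(round(digenome_score(7, 8, 10, 10), 2), 94.44)
  # saturation: S = D on both strands
  for (d in list(c(3, 9), c(20, 20), c(1, 50)))
    expect_equal(digenome_score(d[1], d[1], d[2], d[2]), 100)
  expect_error(digenome_score(0, 0, 0, 0), "depth")
  # bounds and monotonicity in S at fixed depths
  set.seed(1)
  for (i in 1:50) {
    D1 <- sample(1:50, 1); D2 <- sample(1:50, 1)
    S1 <- sample(0:D1, 1); S2 <- sample(0:D2, 1)
    sc <- digenome_score(S1, D1, S2, D2)
    expect_gte(sc, 0); expect_lte(sc, 100)
    if (S1 < D1)
      expect_gt(digenome_score(S1 + 1, D1, S2, D2), sc)
  }
})

test_that("candidate calling uses a strict score threshold", {
  # S=6 of D=10 on both strands joins to a score of exactly 60 -> excluded
  mk <- function(n_start_plus) {
    plus <- mk_aln("+", c(rep(101, n_start_plus), rep(80, 10 - n_start_plus)),
                   rep(50, 10))
    minus <- mk_aln("-", c(rep(51, 6), rep(71, 4)), rep(50, 10))
    aln <- rbind(plus, minus)
    aln$qname <- sprintf("r%03d", seq_len(nrow(aln)))
    aln[order(aln$pos), ]
  }
  aln60 <- mk(6)
  prof <- strand_start_profiles(aln60)
  hits <- filter_start_positions(prof)
  cand <- join_cut_sites(hits[hits$strand == "+", , drop = FALSE],
                         hits[hits$strand == "-", , drop = FALSE])
  expect_equal(cand$score[cand$start == 101], 60)
  expect_false(101 %in% call_candidates(aln60)$start)
  # one more start tips the score to 65 -> included
  expect_true(101 %in% call_candidates(mk(7))$start)
})

test_that("translation equivariance: shifting reads shifts candidates", {
  g <- simulate_genome(1, 4000, seed = 21)
  sim <- simulate_digenome_reads(g, true_cut_site("contig1", 2000L),
                                 mean_depth = 25, seed = 22)
  cand <- call_candidates(sim$alignments)
  shifted <- sim$alignments
  shifted$pos <- shifted$pos + 37L
  cand2 <- call_candidates(shifted)
  expect_equal(cand2$start, cand$start + 37L)
  expect_equal(cand2$score, cand$score)
  expect_equal(cand2$gap, cand$gap)
})

test_that("background-only simulation yields no candidates", {
  g <- simulate_genome(1, 10000, seed = 2)
  null <- simulate_digenome_reads(g, NULL, mean_depth = 30, seed = 4)
  expect_equal(nrow(call_candidates(null)), 0)
})

test_that("planted cuts are recovered with their gap geometry", {
  g <- simulate_genome(1, 10000, seed = 2)
  # truth recovery at score 100: all fragments longer than the reads, so
  # no background read ends at the cut (see the methods vignette)
  for (geom in c("blunt", "gap1", "overhang1")) {
    sim <- simulate_digenome_reads(g, true_cut_site("contig1", 5000L, geom),
                                   mean_depth = 30, read_len = 100L,
                                   min_frag = 101L, seed = 5)
    cand <- call_candidates(sim)
    expect_equal(nrow(cand), 1)
    expect_equal(cand$geometry, geom)
    expect_equal(cand$score, 100)
    expect_equal(cand$start, 5001L)
  }
})

test_that("detector equals the brute-force oracle on small instances", {
  g <- simulate_genome(1, 10000, seed = 30)
  cuts <- rbind(true_cut_site("contig1", 2000L, "blunt", 0.9),
                true_cut_site("contig1", 5000L, "gap1", 0.8),
                true_cut_site("contig1", 8000L, "overhang1", 1.0))
  for (seed in 31:33) {
    sim <- simulate_digenome_reads(g, cuts, mean_depth = 20, seed = seed)
    got <- call_candidates(sim)
    want <- oracle_candidates(sim$alignments)
    expect_equal(nrow(got), nrow(want))
    for (col in c("contig", "gap", "start", "plus", "depth_plus",
                  "minus", "depth_minus", "score"))
      expect_equal(got[[col]], want[[col]], info = col)
  }
})

test_that("secondary alignments are excluded by default when reading SAM", {
  g <- simulate_genome(1, 2000, seed = 41)
  sim <- simulate_digenome_reads(g, NULL, mean_depth = 5, seed = 42)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$alignments, nchar(g$contigs), sam, genome = g)
  # append a secondary copy of the first record (flag 256)
  lines <- readLines(sam)
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  rec[2] <- as.character(as.integer(rec[2]) + 256L)
  writeLines(c(lines, paste(rec, collapse = "\t")), sam)
  expect_equal(nrow(read_alignments(sam)), nrow(sim$alignments))
  expect_equal(nrow(read_alignments(sam, detector_config(
    count_secondary = TRUE))), nrow(sim$alignments) + 1L)
})
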