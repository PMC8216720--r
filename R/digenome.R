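# digenome: gap-tolerant cut-site calling from strand-specific read-start
# pileups.
#
# Conventions (used consistently by the simulator and the detector):
#   * coordinates are 1-based;
#   * the start of a reverse-strand read is its 5' end, i.e. its rightmost
#     aligned base;
#   * a candidate joins a plus-strand start p with a minus-strand start m,
#     with gap g = p - m - 1: g = 0 is a blunt cut, g = +1 a 1-bp gap,
#     g = -1 a 1-bp overhang.

#' Detector configuration
#'
#' Defaults implement the published filter: positions with five or more
#' read starts are kept when the starts make up at least 25% of that
#' strand's coverage, and joined candidates are reported when the combined
#' score exceeds 60 (strict inequality).
#'
#' @param min_starts Minimum read starts at a position (default 5).
#' @param min_frac Minimum fraction of that strand's coverage contributed
#'   by the starts (default 0.25).
#' @param score_threshold Candidates must score strictly above this
#'   (default 60).
#' @param allowed_gaps Gap values to join across (default -1, 0, +1).
#' @param count_secondary Whether secondary alignments are counted when
#'   reading a SAM/BAM file (default `FALSE`).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_starts = 5L, min_frac = 0.25,
                            score_threshold = 60, allowed_gaps = c(-1L, 0L, 1L),
                            count_secondary = FALSE) {
  if (min_starts < 1L) stopf("min_starts must be >= 1")
  if (min_frac <= 0 || min_frac > 1) stopf("min_frac must be in (0, 1]")
  if (score_threshold < 0 || score_threshold > 100)
    stopf("score_threshold must be in [0, 100]")
  if (any(abs(allowed_gaps) > 1L)) stopf("gaps beyond +-1 are not supported")
  structure(list(min_starts = as.integer(min_starts), min_frac = min_frac,
                 score_threshold = score_threshold,
                 allowed_gaps = as.integer(allowed_gaps),
                 count_secondary = count_secondary),
            class = "detector_config")
}

#' Read alignments from a SAM or BAM file
#'
#' Unmapped records are always excluded; secondary alignments are excluded
#' unless `cfg$count_secondary` is set (mapping was done with multi-placement
#' reporting in the source study, so this is an explicit escape hatch).
#'
#' @param path SAM or BAM file with header.
#' @param cfg A [detector_config()].
#' @return Coordinate-sorted alignment data frame (`qname`, `contig`,
#'   `strand`, `pos`, `width`).
#' @export
read_alignments <- function(path, cfg = detector_config()) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (cfg$count_secondary) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "qname")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(ga)) stopf("no alignments in %s", path)
  aln <- data.frame(
    qname = S4Vectors::mcols(ga)$qname,
    contig = as.character(GenomeInfoDb::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    pos = BiocGenerics::start(ga),
    width = GenomicAlignments::qwidth(ga),
    stringsAsFactors = FALSE)
  aln <- aln[order(aln$contig, aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Strand-specific read-start and coverage profiles
#'
#' For each position of the requested region, counts forward-strand reads
#' whose 5' end (leftmost base) maps there (`S_plus`) and reverse-strand
#' reads whose 5' end (rightmost base) maps there (`S_minus`), along with
#' total per-strand coverage depths (`D_plus`, `D_minus`).
#'
#' @param alignments Coordinate-sorted alignment data frame.
#' @param contig Contig to profile; defaults to the only contig present.
#' @param region Optional `c(start, end)` 1-based interval; defaults to the
#'   span of the alignments.
#' @return A list of class `start_profile` with integer vectors `S_plus`,
#'   `D_plus`, `S_minus`, `D_minus`, plus `contig` and `offset` (the 1-based
#'   genomic position of the first vector element).
#' @export
strand_start_profiles <- function(alignments, contig = NULL, region = NULL) {
  if (is.null(contig)) {
    contig <- unique(alignments$contig)
    if (length(contig) != 1L)
      stopf("several contigs present; pass `contig`")
  }
  aln <- alignments[alignments$contig == contig, , drop = FALSE]
  if (!nrow(aln)) stopf("unknown contig: %s", contig)
  if (is.unsorted(aln$pos)) stopf("alignments must be coordinate-sorted")
  ends <- aln$pos + aln$width - 1L
  if (is.null(region)) region <- c(min(aln$pos), max(ends))
  lo <- as.integer(region[1L]); hi <- as.integer(region[2L])
  if (lo < 1L || hi < lo) stopf("invalid region")
  n <- hi - lo + 1L
  prof <- function(sel, start_at) {
    s <- integer(n); d <- integer(n)
    if (any(sel)) {
      st <- start_at[sel]
      in_reg <- st >= lo & st <= hi
      s <- tabulate(st[in_reg] - lo + 1L, nbins = n)
      cov <- IRanges::coverage(
        IRanges::IRanges(aln$pos[sel], ends[sel]))
      covv <- as.integer(cov)
      # clip/pad the coverage Rle to the region
      idx <- lo:hi
      d <- ifelse(idx >= 1L & idx <= length(covv), covv[pmax(idx, 1L)], 0L)
      d[is.na(d)] <- 0L
    }
    list(S = as.integer(s), D = as.integer(d))
  }
  plus <- prof(aln$strand == "+", aln$pos)
  minus <- prof(aln$strand == "-", ends)
  structure(list(contig = contig, offset = lo,
                 S_plus = plus$S, D_plus = plus$D,
                 S_minus = minus$S, D_minus = minus$D),
            class = "start_profile")
}

#' Filter read-start positions
#'
#' Keeps positions with at least `min_starts` read starts whose starts make
#' up at least `min_frac` of that strand's own coverage (both thresholds
#' inclusive). `perc` is reported as `100 * S / D`.
#'
#' @param profile A [strand_start_profiles()] result.
#' @param cfg A [detector_config()].
#' @return Data frame with `contig`, `position`, `strand`, `S`, `D`, `perc`.
#' @export
filter_start_positions <- function(profile, cfg = detector_config()) {
  stopifnot(inherits(profile, "start_profile"))
  one <- function(S, D, strand) {
    keep <- which(S >= cfg$min_starts & D > 0L & S / D >= cfg$min_frac)
    data.frame(contig = rep(profile$contig, length(keep)),
               position = profile$offset + keep - 1L,
               strand = rep(strand, length(keep)), S = S[keep], D = D[keep],
               perc = 100 * S[keep] / D[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(profile$S_plus, profile$D_plus, "+"),
               one(profile$S_minus, profile$D_minus, "-"))
  rownames(out) <- NULL
  out
}

#' Combined-strand cut-site score
#'
#' `100 * (S_plus + S_minus) / (D_plus + D_minus)`: the percentage of reads
#' covering a putative cut site that start exactly at it, combined over both
#' strands. Equals 100 exactly when every covering read starts at the site
#' on both strands.
#'
#' @param S_plus,D_plus Forward-strand read-start count and depth.
#' @param S_minus,D_minus Reverse-strand read-start count and depth.
#' @return Score in `[0, 100]` (vectorised).
#' @export
digenome_score <- function(S_plus, D_plus, S_minus, D_minus) {
  if (any(D_plus + D_minus <= 0)) stopf("combined depth must be positive")
  100 * (S_plus + S_minus) / (D_plus + D_minus)
}

#' Join filtered plus- and minus-strand read starts into cut-site candidates
#'
#' A candidate is emitted for each pair of a plus-strand start `p` and a
#' minus-strand start `m` with `g = p - m - 1` among the allowed gaps:
#' `g = 0` is labelled blunt, `g = +1` a 1-bp gap, `g = -1` a 1-bp
#' overhang. The reported start is `min(p, m + 1)`.
#'
#' @param plus_hits,minus_hits Rows of [filter_start_positions()] output for
#'   one contig and the respective strand.
#' @param cfg A [detector_config()].
#' @return Data frame of candidates with per-strand counts and `score`.
#' @export
join_cut_sites <- function(plus_hits, minus_hits, cfg = detector_config()) {
  empty <- data.frame(contig = character(), gap = integer(),
                      start = integer(), geometry = character(),
                      plus = integer(), depth_plus = integer(),
                      perc_plus = numeric(), minus = integer(),
                      depth_minus = integer(), perc_minus = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(plus_hits) || !nrow(minus_hits)) return(empty)
  stopifnot(all(plus_hits$strand == "+"), all(minus_hits$strand == "-"))
  ctg <- unique(c(plus_hits$contig, minus_hits$contig))
  if (length(ctg) != 1L) stopf("hits must come from a single contig")
  geom_label <- c(`-1` = "overhang1", `0` = "blunt", `1` = "gap1")
  midx <- split(seq_len(nrow(minus_hits)), minus_hits$position)
  rows <- list()
  for (i in seq_len(nrow(plus_hits))) {
    p <- plus_hits$position[i]
    for (g in sort(cfg$allowed_gaps)) {
      m <- p - g - 1L
      j <- midx[[as.character(m)]]
      if (is.null(j)) next
      j <- j[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, gap = g, start = min(p, m + 1L),
        geometry = unname(geom_label[as.character(g)]),
        plus = plus_hits$S[i], depth_plus = plus_hits$D[i],
        perc_plus = plus_hits$perc[i],
        minus = minus_hits$S[j], depth_minus = minus_hits$D[j],
        perc_minus = minus_hits$perc[j],
        score = digenome_score(plus_hits$S[i], plus_hits$D[i],
                               minus_hits$S[j], minus_hits$D[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call cut-site candidates from alignments
#'
#' Full detector pipeline: strand-specific profiles, the two-stage
#' read-start filter, gap-tolerant plus/minus joining, and thresholding at
#' `score > cfg$score_threshold` (strict). When one locus passes in several
#' gap configurations all of them are reported. Candidates are ranked best
#' score first; ties are broken by (contig, start, gap) for determinism.
#'
#' @param alignments Coordinate-sorted alignment data frame (or a
#'   `digenome_sim`).
#' @param cfg A [detector_config()].
#' @return Ranked candidate data frame (see [join_cut_sites()]).
#' @export
call_candidates <- function(alignments, cfg = detector_config()) {
  if (inherits(alignments, "digenome_sim"))
    alignments <- alignments$alignments
  parts <- lapply(split(alignments, alignments$contig), function(aln) {
    prof <- strand_start_profiles(aln)
    hits <- filter_start_positions(prof, cfg)
    join_cut_sites(hits[hits$strand == "+", , drop = FALSE],
                   hits[hits$strand == "-", , drop = FALSE], cfg)
  })
  out <- do.call(rbind, parts)
  out <- out[out$score > cfg$score_threshold, , drop = FALSE]
  out <- out[order(-out$score, out$contig, out$start, out$gap), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate table in the report layout
#'
#' Columns: Chr, Gap, Start, Plus, Depth, Perc, Minus, Depth2, Perc2, Total
#' (percentages to two decimals).
#'
#' @param candidates [call_candidates()] output.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  df <- data.frame(Chr = candidates$contig, Gap = candidates$gap,
                   Start = candidates$start, Plus = candidates$plus,
                   Depth = candidates$depth_plus,
                   Perc = round2(candidates$perc_plus),
                   Minus = candidates$minus,
                   Depth2 = candidates$depth_minus,
                   Perc2 = round2(candidates$perc_minus),
                   Total = round2(candidates$score))
  write_tsv(df, path)
}
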