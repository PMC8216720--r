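# amplicon: indel quantification from amplicon deep sequencing.
#
# Pipeline per sample: median-quality filter -> global alignment of each
# read to the expected amplicon -> event extraction with left-aligned
# indels -> per-read classification within a window around the start codon
# -> summaries (category counts, size spectra, inserted-base composition,
# Kozak assessment).

#' Amplicon reference
#'
#' @param sequence Expected amplicon sequence (A/C/G/T).
#' @param start_codon 1-based position of the A of the ATG start codon.
#' @param window Half-width of the classification window around the codon;
#'   alignment events outside `start_codon - window .. start_codon + 2 +
#'   window` are ignored (default 10).
#' @return A list of class `amplicon_ref`.
#' @export
amplicon_ref <- function(sequence, start_codon, window = 10L) {
  assert_dna(sequence, "sequence")
  if (substr(sequence, start_codon, start_codon + 2L) != "ATG")
    stopf("no ATG at position %d", start_codon)
  win <- c(max(1L, start_codon - window),
           min(nchar(sequence), start_codon + 2L + window))
  structure(list(sequence = sequence, start_codon = as.integer(start_codon),
                 window = win), class = "amplicon_ref")
}

#' Filter reads by median base quality
#'
#' A read is removed iff the median of its per-base Phred qualities is at
#' or below the cutoff (the published rule removes median <= 5). The median
#' of an even-length list is the mean of the two central order statistics.
#'
#' @param reads Read data frame (`id`, `seq`, `qual`, Phred+33) or a FASTQ
#'   path.
#' @param cutoff Quality cutoff (default 5).
#' @return List with `retained` (read data frame) and `discarded` (read
#'   data frame with a `reason` column).
#' @export
filter_reads_by_median_quality <- function(reads, cutoff = 5) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (any(nchar(reads$qual) != nchar(reads$seq)))
    stopf("malformed FASTQ record: quality length != sequence length")
  med <- median_qualities(reads$qual)
  drop <- med <= cutoff
  discarded <- reads[drop, , drop = FALSE]
  if (nrow(discarded)) discarded$reason <- "low_median_quality"
  else discarded$reason <- character(0)
  list(retained = reads[!drop, , drop = FALSE], discarded = discarded)
}

# Vectorised per-read median of Phred+33 quality strings. For the common
# fixed-length case the medians are found by counting over the 94 possible
# scores, which avoids a per-read sort.
median_qualities <- function(qual) {
  lens <- nchar(qual)
  if (length(unique(lens)) == 1L && length(qual) > 1L) {
    n <- lens[1L]
    m <- matrix(utf8ToInt(paste(qual, collapse = "")) - 32L,
                nrow = n)  # column per read; scores shifted to 1..94
    lo_k <- (n + 1L) %/% 2L
    hi_k <- n %/% 2L + 1L
    tab <- apply(m, 2L, tabulate, nbins = 94L)
    cum <- apply(tab, 2L, cumsum)
    lo <- apply(cum >= lo_k, 2L, which.max) - 1L
    hi <- apply(cum >= hi_k, 2L, which.max) - 1L
    return((lo + hi) / 2)
  }
  vapply(qual, function(q) median(decode_phred(q)), numeric(1L),
         USE.NAMES = FALSE)
}

#' Globally align a read to the amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gaps (match +1, mismatch
#' -2, a gap of length L costs 6 + (L - 1)): any scheme that keeps a
#' near-identical amplicon read globally alignable works, and this one is
#' pinned for reproducibility. Indels are left-aligned within homopolymers
#' so that equivalent placements are reported canonically.
#'
#' @param read Read sequence.
#' @param ref An [amplicon_ref()].
#' @return A list of class `amplicon_alignment` with `score` and `events`,
#'   a data frame with columns `type` (`"ins"`/`"del"`), `length`, `at`
#'   (1-based reference position: insertions sit after `at`, deletions
#'   remove `at..at+length-1`) and `bases`.
#' @export
align_to_amplicon <- function(read, ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (!nchar(read)) stopf("empty read")
  pa <- pairwise_global(read, ref$sequence)
  ev <- extract_events(pa$pattern, pa$subject)
  if (nrow(ev))
    ev <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
      left_align_event(ev[i, ], ref$sequence)))
  span <- aligned_ref_span(pa$pattern, pa$subject)
  structure(list(score = pa$score, events = ev, ref_span = span),
            class = "amplicon_alignment")
}

pairwise_global <- function(read, refseq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(read, refseq, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# Walk aligned strings column by column; a gap in the subject (reference)
# is an insertion in the read, a gap in the pattern (read) a deletion.
extract_events <- function(p, s) {
  pch <- chars(p); sch <- chars(s)
  refpos <- 0L
  events <- list()
  i <- 1L
  n <- length(pch)
  while (i <= n) {
    if (sch[i] == "-") {
      j <- i
      while (j < n && sch[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- data.frame(
        type = "ins", length = j - i + 1L, at = refpos,
        bases = paste(pch[i:j], collapse = ""), stringsAsFactors = FALSE)
      i <- j + 1L
    } else if (pch[i] == "-") {
      j <- i
      while (j < n && pch[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- data.frame(
        type = "del", length = j - i + 1L, at = refpos + 1L,
        bases = "", stringsAsFactors = FALSE)
      refpos <- refpos + (j - i + 1L)
      i <- j + 1L
    } else {
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  if (!length(events))
    return(data.frame(type = character(), length = integer(),
                      at = integer(), bases = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

aligned_ref_span <- function(p, s) {
  sch <- chars(s)
  pch <- chars(p)
  refpos <- cumsum(sch != "-")
  covered <- refpos[pch != "-" & sch != "-"]
  if (!length(covered)) c(NA_integer_, NA_integer_)
  else c(min(covered), max(covered))
}

# Canonical (leftmost) placement of a single indel event.
left_align_event <- function(ev, refseq) {
  rch <- chars(refseq)
  if (ev$type == "ins") {
    at <- ev$at; b <- chars(ev$bases); L <- length(b)
    while (at >= 1L && rch[at] == b[L]) {
      b <- c(rch[at], b[-L])
      at <- at - 1L
    }
    ev$at <- at
    ev$bases <- paste(b, collapse = "")
  } else {
    at <- ev$at; L <- ev$length
    while (at >= 2L && rch[at - 1L] == rch[at + L - 1L]) at <- at - 1L
    ev$at <- at
  }
  ev
}

# Rightmost equivalent placement of a 1-bp insertion (used to decide
# whether a placement interval covers the start codon's A).
right_align_ins1 <- function(at, base, refseq) {
  rch <- chars(refseq)
  while (at + 1L <= length(rch) && rch[at + 1L] == base) at <- at + 1L
  at
}

#' Classify a read from its alignment events
#'
#' Events outside the reference window are ignored. A read is an insertion
#' if only insertions remain in the window, a deletion if only deletions;
#' a read carrying both counts once, as the type with the larger total
#' event length (tie goes to insertion). No remaining events means no
#' change. Reads whose alignment does not cover the whole window are
#' discarded with reason `"truncated"`.
#'
#' @param alignment An [align_to_amplicon()] result.
#' @param ref The [amplicon_ref()].
#' @return A list of class `read_outcome` with `category` (`"no_change"`,
#'   `"insertion"`, `"deletion"`, `"discarded"`), `events` (the in-window
#'   events), `indel_length` (total length of the classified type) and
#'   `reason` for discarded reads.
#' @export
classify_read <- function(alignment, ref) {
  win <- ref$window
  span <- alignment$ref_span
  if (any(is.na(span)) || span[1L] > win[1L] || span[2L] < win[2L])
    return(structure(list(category = "discarded", events = NULL,
                          indel_length = NA_integer_, reason = "truncated"),
                     class = "read_outcome"))
  ev <- alignment$events
  if (nrow(ev)) {
    ins_in <- ev$type == "ins" & ev$at >= win[1L] - 1L & ev$at <= win[2L]
    del_in <- ev$type == "del" & ev$at <= win[2L] &
      (ev$at + ev$length - 1L) >= win[1L]
    ev <- ev[ins_in | del_in, , drop = FALSE]
  }
  if (!nrow(ev))
    return(structure(list(category = "no_change", events = ev,
                          indel_length = 0L, reason = NA_character_),
                     class = "read_outcome"))
  ins_len <- sum(ev$length[ev$type == "ins"])
  del_len <- sum(ev$length[ev$type == "del"])
  cat <- if (ins_len >= del_len) "insertion" else "deletion"
  structure(list(category = cat, events = ev,
                 indel_length = max(ins_len, del_len),
                 reason = NA_character_),
            class = "read_outcome")
}

#' Quantify one amplicon sample
#'
#' Composes the per-sample pipeline: median-quality filtering, global
#' alignment of every retained read (identical sequences are aligned once
#' and weighted by their multiplicity), per-read classification and event
#' bookkeeping.
#'
#' @param reads Read data frame or FASTQ path.
#' @param ref An [amplicon_ref()].
#' @param quality_cutoff Median-quality cutoff (default 5).
#' @return A list of class `amplicon_sample` with `outcomes` (data frame
#'   `id`, `category`, `indel_length`, `n_events`), `events` (per unique
#'   sequence), `n_input`, `n_retained`, `n_discarded`, `discard_reasons`.
#' @export
quantify_amplicon <- function(reads, ref, quality_cutoff = 5) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n_input <- nrow(reads)
  filt <- filter_reads_by_median_quality(reads, quality_cutoff)
  kept <- filt$retained
  # classify unique sequences once
  useq <- unique(kept$seq)
  ucls <- lapply(useq, function(s)
    classify_read(align_to_amplicon(s, ref), ref))
  names(ucls) <- useq
  cat_u <- vapply(ucls, `[[`, character(1L), "category")
  len_u <- vapply(ucls, function(x)
    if (is.na(x$indel_length)) NA_integer_ else as.integer(x$indel_length),
    integer(1L))
  nev_u <- vapply(ucls, function(x)
    if (is.null(x$events)) 0L else nrow(x$events), integer(1L))
  idx <- match(kept$seq, useq)
  outcomes <- data.frame(id = kept$id, category = cat_u[idx],
                         indel_length = len_u[idx], n_events = nev_u[idx],
                         stringsAsFactors = FALSE)
  trunc <- outcomes$category == "discarded"
  reasons <- c(filt$discarded$reason,
               rep("truncated", sum(trunc)))
  structure(list(outcomes = outcomes[!trunc, , drop = FALSE],
                 unique_outcomes = ucls,
                 seq_of_read = kept$seq[!trunc],
                 ref = ref,
                 n_input = n_input,
                 n_retained = sum(!trunc),
                 n_discarded = n_input - sum(!trunc),
                 discard_reasons = reasons),
            class = "amplicon_sample")
}

#' Summarise read categories
#'
#' Percentages are computed over the total retained reads and reported to
#' 0.1%. `indel = insertion + deletion` at the count level, so the category
#' percentages are exactly conservative.
#'
#' @param x An `amplicon_sample` from [quantify_amplicon()], or a category
#'   character vector.
#' @return A list of class `indel_summary` with counts and percentages.
#' @export
indel_summary <- function(x) {
  categories <- if (inherits(x, "amplicon_sample")) x$outcomes$category
                else x
  total <- length(categories)
  if (!total) stopf("zero retained reads")
  n_ins <- sum(categories == "insertion")
  n_del <- sum(categories == "deletion")
  indel_summary_from_counts(total, sum(categories == "no_change"),
                            n_ins, n_del)
}

#' Build an indel summary from category counts
#'
#' @param total_reads,n_no_change,n_insertion,n_deletion Read counts; the
#'   first three categories must sum to `total_reads`.
#' @return A list of class `indel_summary` with counts and percentages
#'   (over `total_reads`, to 0.1%).
#' @examples
#' indel_summary_from_counts(87554, 68228, 16378, 2948)
#' @export
indel_summary_from_counts <- function(total_reads, n_no_change, n_insertion,
                                      n_deletion) {
  if (total_reads <= 0) stopf("zero retained reads")
  n_indel <- n_insertion + n_deletion
  if (n_no_change + n_indel != total_reads)
    stopf("category counts do not sum to the total")
  pct <- function(n) round1(100 * n / total_reads)
  structure(list(total_reads = total_reads, n_no_change = n_no_change,
                 n_insertion = n_insertion, n_deletion = n_deletion,
                 n_indel = n_indel,
                 pct_no_change = pct(n_no_change),
                 pct_insertion = pct(n_insertion),
                 pct_deletion = pct(n_deletion),
                 pct_indel = pct(n_indel)),
            class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf(
    "reads: %d | no change %d (%.1f%%) | insertion %d (%.1f%%) | deletion %d (%.1f%%) | indel %d (%.1f%%)\n",
    x$total_reads, x$n_no_change, x$pct_no_change, x$n_insertion,
    x$pct_insertion, x$n_deletion, x$pct_deletion, x$n_indel, x$pct_indel))
  invisible(x)
}

#' Indel size spectra
#'
#' Per-length percentages of insertion and deletion reads over the total
#' retained reads of a sample; the histogram masses therefore sum exactly
#' to the insertion and deletion percentages of [indel_summary()].
#'
#' @param x An `amplicon_sample`.
#' @return List of class `size_spectrum` with data frames `insertion` and
#'   `deletion` (`length`, `n`, `pct`), and `total_reads`.
#' @export
size_spectrum <- function(x) {
  stopifnot(inherits(x, "amplicon_sample"))
  total <- nrow(x$outcomes)
  one <- function(category) {
    sel <- x$outcomes$category == category
    if (!any(sel))
      return(data.frame(length = integer(), n = integer(), pct = numeric()))
    t <- table(x$outcomes$indel_length[sel])
    data.frame(length = as.integer(names(t)), n = as.integer(t),
               pct = 100 * as.integer(t) / total)
  }
  structure(list(insertion = one("insertion"), deletion = one("deletion"),
                 total_reads = total), class = "size_spectrum")
}

#' Composition of single-base insertions at the start codon
#'
#' Counts reads whose single alignment event is a 1-bp insertion placed
#' within the start codon between the A and the T — i.e. whose
#' placement-equivalence interval (leftmost to rightmost homopolymer
#' shift) contains the insertion point immediately after the codon's A.
#' Percentages are over that count; with no qualifying reads the
#' composition is reported as absent.
#'
#' @param x An `amplicon_sample`.
#' @return A list of class `insertion_composition` (see
#'   [composition_from_counts()]), or `NULL` when no reads qualify.
#' @export
insertion_base_composition <- function(x) {
  stopifnot(inherits(x, "amplicon_sample"))
  ref <- x$ref
  apos <- ref$start_codon
  counts <- c(A = 0L, T = 0L, G = 0L, C = 0L)
  useq_n <- table(x$seq_of_read)
  for (s in names(useq_n)) {
    out <- x$unique_outcomes[[s]]
    ev <- out$events
    if (is.null(ev) || nrow(ev) != 1L) next
    if (ev$type != "ins" || ev$length != 1L) next
    left <- ev$at
    right <- right_align_ins1(ev$at, ev$bases, ref$sequence)
    if (left <= apos && right >= apos)
      counts[ev$bases] <- counts[ev$bases] + as.integer(useq_n[[s]])
  }
  if (sum(counts) == 0L) return(NULL)
  composition_from_counts(counts[["A"]], counts[["T"]], counts[["G"]],
                          counts[["C"]])
}

#' Build an inserted-base composition from counts
#'
#' @param A,T,G,C Read counts of single-base insertions by inserted base.
#' @return List of class `insertion_composition` with `total`, `counts`
#'   and `pct` (to 0.1%).
#' @examples
#' composition_from_counts(7925, 6703, 230, 797)
#' @export
composition_from_counts <- function(A, T, G, C) {
  counts <- c(A = A, T = T, G = G, C = C)
  total <- sum(counts)
  if (total <= 0) stopf("no qualifying insertions")
  structure(list(total = total, counts = counts,
                 pct = round1(100 * counts / total)),
            class = "insertion_composition")
}

#' Assess the Kozak context after a start-codon insertion
#'
#' Reconstructs the edited sequence, searches for an ATG whose A lies
#' within two bases of the original start-codon position, and reports the
#' base three positions upstream of that A (the -3 position, with the A of
#' ATG as +1). A or G at -3 is the favourable Kozak context.
#'
#' With `event = NULL` the unedited reference itself is assessed.
#'
#' @param ref An [amplicon_ref()].
#' @param event A single-row event data frame (`type = "ins"`,
#'   `length = 1`, `at`, `bases`) describing a 1-bp insertion within the
#'   start codon, or `NULL`.
#' @return A list of class `kozak_call`: `cryptic_atg_present`,
#'   `new_atg_pos` (in edited coordinates), `minus3_base`,
#'   `kozak_favorable`.
#' @export
kozak_assessment <- function(ref, event = NULL) {
  stopifnot(inherits(ref, "amplicon_ref"))
  apos <- ref$start_codon
  if (is.null(event)) {
    seq <- ref$sequence
    center <- apos
  } else {
    if (event$type != "ins" || event$length != 1L)
      stopf("event must be a single-base insertion")
    right <- right_align_ins1(event$at, event$bases, ref$sequence)
    if (event$at > apos + 2L || right < apos - 1L)
      stopf("insertion is not within the start codon")
    seq <- apply_indel_event(ref$sequence, "ins", 1L, event$at, event$bases)
    center <- apos  # the insertion shifts downstream bases by at most 1
  }
  lo <- max(1L, center - 2L)
  hi <- min(nchar(seq) - 2L, center + 2L)
  atg_at <- NA_integer_
  for (i in lo:hi) {
    if (substr(seq, i, i + 2L) == "ATG") { atg_at <- i; break }
  }
  if (is.na(atg_at))
    return(structure(list(cryptic_atg_present = FALSE,
                          new_atg_pos = NA_integer_,
                          minus3_base = NA_character_,
                          kozak_favorable = NA),
                     class = "kozak_call"))
  m3 <- if (atg_at - 3L >= 1L) substr(seq, atg_at - 3L, atg_at - 3L)
        else NA_character_
  structure(list(cryptic_atg_present = TRUE, new_atg_pos = atg_at,
                 minus3_base = m3,
                 kozak_favorable = isTRUE(m3 %in% c("A", "G"))),
            class = "kozak_call")
}

#' @export
print.kozak_call <- function(x, ...) {
  if (!x$cryptic_atg_present) {
    cat("no ATG at the locus after the edit\n")
  } else {
    cat(sprintf("ATG at %d | -3 base %s | Kozak %s\n", x$new_atg_pos,
                x$minus3_base,
                if (x$kozak_favorable) "favorable" else "unfavorable"))
  }
  invisible(x)
}
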