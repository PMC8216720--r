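# synthdata: simulation of genomes, Cas9 digestion read sets, and amplicon
# read sets with known truth, so every downstream stage is testable offline.

#' Simulate a toy genome
#'
#' Draws independent bases with a configurable GC content. Coordinates
#' throughout the package are 1-based, following the R/Bioconductor
#' convention.
#'
#' @param n_contigs Number of contigs.
#' @param length Length of each contig in bases (recycled).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `sim_genome`: a list with `contigs` (named
#'   character vector of A/C/G/T sequences) and `seed`.
#' @examples
#' g <- simulate_genome(1, 1000, gc = 0.5, seed = 1)
#' nchar(g$contigs)
#' @export
simulate_genome <- function(n_contigs = 1L, length = 10000L, gc = 0.41,
                            seed = 1L) {
  if (any(length < 1L)) stopf("contig length must be >= 1")
  if (gc < 0 || gc > 1) stopf("gc must be in [0, 1]")
  lens <- rep_len(as.integer(length), n_contigs)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1L))
  })
  names(contigs) <- sprintf("contig%d", seq_len(n_contigs))
  structure(list(contigs = contigs, seed = as.integer(seed)),
            class = "sim_genome")
}

#' Specify a true cut site for the digestion simulator
#'
#' `position` is the blunt-cut point: the cut falls immediately after the
#' 1-based base `position` of the contig. `geometry` displaces the two
#' strand-specific cleavage points: `"blunt"` cuts both strands at the same
#' point, `"gap1"` removes one base between the fragments (the base at
#' `position + 1` belongs to neither), `"overhang1"` duplicates one base
#' (the base at `position + 1` ends the left fragment and starts the right).
#'
#' @param contig Contig name.
#' @param position 1-based position of the last base left of the cut.
#' @param geometry One of `"blunt"`, `"gap1"`, `"overhang1"`.
#' @param efficiency Fraction of spanning fragments actually cut, in `[0,1]`.
#' @return A one-row data frame; rows can be `rbind`-ed into a cut table.
#' @export
true_cut_site <- function(contig, position, geometry = "blunt",
                          efficiency = 1.0) {
  geometry <- match.arg(geometry, c("blunt", "gap1", "overhang1"))
  if (efficiency < 0 || efficiency > 1) stopf("efficiency must be in [0, 1]")
  data.frame(contig = contig, position = as.integer(position),
             geometry = geometry, efficiency = efficiency,
             stringsAsFactors = FALSE)
}

#' Simulate whole-genome reads from in-vitro Cas9 digestion
#'
#' Emulates random (Covaris-style) background fragmentation of purified
#' genomic DNA followed by Cas9 cleavage at the given cut sites. Fragment
#' lengths are lognormal. Each fragment yields one forward read starting at
#' its first base and one reverse read ending at its last base (two
#' independent single-end records sharing a name, as from a paired-end
#' library). At a cut site with efficiency `e`, a fraction `e` of fragments
#' spanning the cut is split so that forward-strand read starts pile up at
#' the right fragment's first base and reverse-strand 5' ends at the left
#' fragment's last base, displaced according to the geometry.
#'
#' Alignments are emitted directly with their true coordinates (read
#' mapping is out of scope for this package).
#'
#' @param genome A `sim_genome`.
#' @param cuts Data frame of cut sites from [true_cut_site()], or `NULL`.
#' @param mean_depth Target mean read coverage.
#' @param read_len Read length in bases; must be shorter than the contigs.
#' @param frag_meanlog,frag_sdlog Lognormal fragment-length parameters.
#' @param min_frag Fragments shorter than this are dropped (adapter-size
#'   pieces would not be sequenced).
#' @param seed Integer seed.
#' @return A list of class `digenome_sim` with `alignments` (a
#'   coordinate-sorted data frame with columns `qname`, `contig`, `strand`,
#'   `pos`, `width`) and `truth` (the cut table).
#' @export
simulate_digenome_reads <- function(genome, cuts = NULL, mean_depth = 30,
                                    read_len = 100L,
                                    frag_meanlog = log(350), frag_sdlog = 0.35,
                                    min_frag = 30L, seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"))
  lens <- nchar(genome$contigs)
  if (read_len >= min(lens)) stopf("read_len must be shorter than contigs")
  if (!is.null(cuts) && nrow(cuts)) {
    bad <- !(cuts$contig %in% names(genome$contigs))
    if (any(bad)) stopf("cut contig not in genome: %s", cuts$contig[bad][1L])
    for (i in seq_len(nrow(cuts))) {
      L <- lens[[cuts$contig[i]]]
      if (cuts$position[i] < 1L || cuts$position[i] >= L)
        stopf("cut position %d outside contig %s", cuts$position[i],
              cuts$contig[i])
    }
  }
  with_seed(seed, {
    out <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      cname <- names(lens)[ci]
      L <- lens[[ci]]
      n_frag <- ceiling(mean_depth * L / (2 * read_len))
      start <- sample.int(L, n_frag, replace = TRUE)
      flen <- pmax(round(rlnorm(n_frag, frag_meanlog, frag_sdlog)), 2L)
      end <- pmin(start + flen - 1L, L)
      frag <- data.frame(start = start, end = end)
      ccuts <- if (is.null(cuts)) NULL else cuts[cuts$contig == cname, ,
                                                drop = FALSE]
      if (!is.null(ccuts) && nrow(ccuts)) {
        ccuts <- ccuts[order(ccuts$position), , drop = FALSE]
        for (k in seq_len(nrow(ccuts))) {
          p <- ccuts$position[k]
          geom <- ccuts$geometry[k]
          eff <- ccuts$efficiency[k]
          # fragments covering both sides of the blunt-cut point
          span <- frag$start <= p & frag$end >= p + 1L
          hit <- span & runif(nrow(frag)) < eff
          if (!any(hit)) next
          # left/right fragment boundaries by geometry
          left_end <- switch(geom, blunt = p, gap1 = p, overhang1 = p + 1L)
          right_start <- switch(geom, blunt = p + 1L, gap1 = p + 2L,
                                overhang1 = p + 1L)
          left <- data.frame(start = frag$start[hit],
                             end = pmin(frag$end[hit], left_end))
          right <- data.frame(start = pmax(frag$start[hit], right_start),
                              end = frag$end[hit])
          keep_l <- left$end >= left$start
          keep_r <- right$end >= right$start
          frag <- rbind(frag[!hit, , drop = FALSE],
                        left[keep_l, , drop = FALSE],
                        right[keep_r, , drop = FALSE])
        }
      }
      frag <- frag[frag$end - frag$start + 1L >= min_frag, , drop = FALSE]
      n <- nrow(frag)
      if (!n) { out[[ci]] <- NULL; next }
      w <- pmin(read_len, frag$end - frag$start + 1L)
      qn <- sprintf("%s_frag%06d", cname, seq_len(n))
      out[[ci]] <- data.frame(
        qname = c(qn, qn),
        contig = cname,
        strand = rep(c("+", "-"), each = n),
        pos = c(frag$start, frag$end - w + 1L),
        width = c(w, w),
        stringsAsFactors = FALSE)
    }
    aln <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    aln <- aln[order(aln$contig, aln$pos, aln$strand, aln$qname), ,
               drop = FALSE]
    rownames(aln) <- NULL
    structure(list(alignments = aln,
                   truth = if (is.null(cuts))
                     true_cut_site("none", 1L)[0L, ] else cuts),
              class = "digenome_sim")
  })
}

#' Specify an amplicon simulation
#'
#' The indel spectrum is a data frame with one row per event type and
#' columns `type` (`"ins"` or `"del"`), `length`, `at` (1-based reference
#' position: insertions are placed after `at`; deletions remove
#' `at..at+length-1`), `bases` (inserted bases, `""` for deletions) and
#' `prob`. Probabilities must sum to at most 1; the remainder is emitted as
#' unedited reads. Reads are full copies of the (edited) amplicon with
#' per-base Phred qualities drawn from a normal quality model, clipped to
#' `[2, 40]` and encoded Phred+33.
#'
#' @param reference Amplicon reference sequence (A/C/G/T).
#' @param start_codon 1-based position of the A of the ATG start codon.
#' @param indel_spectrum Event data frame as above, or `NULL` for none.
#' @param n_reads Number of reads to emit.
#' @param qual_mean,qual_sd Per-base quality model.
#' @param seed Integer seed.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(reference, start_codon, indel_spectrum = NULL,
                          n_reads = 10000L, qual_mean = 30, qual_sd = 3,
                          seed = 1L) {
  assert_dna(reference, "reference")
  if (start_codon + 2L > nchar(reference))
    stopf("start codon extends past the reference")
  if (substr(reference, start_codon, start_codon + 2L) != "ATG")
    stopf("no ATG at position %d of the reference", start_codon)
  if (is.null(indel_spectrum)) {
    indel_spectrum <- data.frame(type = character(), length = integer(),
                                 at = integer(), bases = character(),
                                 prob = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(indel_spectrum)) {
    if (sum(indel_spectrum$prob) > 1 + 1e-12)
      stopf("indel spectrum probabilities sum to more than 1")
    reflen <- nchar(reference)
    bad_ins <- indel_spectrum$type == "ins" &
      (indel_spectrum$at < 0L | indel_spectrum$at > reflen)
    bad_del <- indel_spectrum$type == "del" &
      (indel_spectrum$at < 1L |
         indel_spectrum$at + indel_spectrum$length - 1L > reflen)
    if (any(bad_ins | bad_del)) stopf("event position outside the reference")
  }
  structure(list(reference = reference, start_codon = as.integer(start_codon),
                 indel_spectrum = indel_spectrum,
                 n_reads = as.integer(n_reads),
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 seed = as.integer(seed)),
            class = "amplicon_spec")
}

apply_indel_event <- function(ref, type, length, at, bases) {
  if (type == "ins") {
    paste0(substr(ref, 1L, at), bases, substr(ref, at + 1L, nchar(ref)))
  } else {
    paste0(substr(ref, 1L, at - 1L),
           substr(ref, at + length, nchar(ref)))
  }
}

#' Simulate amplicon deep-sequencing reads
#'
#' Emits exactly `spec$n_reads` reads drawn from the configured indel
#' spectrum, together with a truth sidecar naming each read's event
#' (`0` = unedited). Sequencing errors beyond the quality strings are not
#' modelled.
#'
#' @param spec An [amplicon_spec()].
#' @return A list of class `amplicon_sim` with `reads` (data frame `id`,
#'   `seq`, `qual`), `truth` (data frame `id`, `event`) and `spec`.
#' @export
simulate_amplicon_reads <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  sp <- spec$indel_spectrum
  n <- spec$n_reads
  with_seed(spec$seed, {
    k <- nrow(sp)
    probs <- c(1 - sum(sp$prob), sp$prob)
    event <- sample.int(k + 1L, n, replace = TRUE, prob = probs) - 1L
    variants <- c(spec$reference,
                  vapply(seq_len(k), function(i)
                    apply_indel_event(spec$reference, sp$type[i],
                                      sp$length[i], sp$at[i], sp$bases[i]),
                    character(1L)))
    seqs <- variants[event + 1L]
    lens <- nchar(seqs)
    quals <- character(n)
    q_all <- pmin(pmax(round(rnorm(sum(lens), spec$qual_mean, spec$qual_sd)),
                       2L), 40L)
    off <- c(0L, cumsum(lens))
    qraw <- as.raw(q_all + 33L)
    for (i in seq_len(n))
      quals[i] <- rawToChar(qraw[(off[i] + 1L):off[i + 1L]])
    ids <- sprintf("read%06d", seq_len(n))
    structure(list(
      reads = data.frame(id = ids, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE),
      truth = data.frame(id = ids, event = event, stringsAsFactors = FALSE),
      spec = spec), class = "amplicon_sim")
  })
}

# ---- plain-text writers ----------------------------------------------------

#' Write a simulated genome as FASTA
#' @param genome A `sim_genome`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "sim_genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), path)
  invisible(path)
}

#' Write alignments as a coordinate-sorted SAM file
#'
#' Reads are written with flag 0 (forward) or 16 (reverse), MAPQ 60 and a
#' fully-matching CIGAR, which is what the simulator guarantees.
#'
#' @param alignments Alignment data frame (`qname`, `contig`, `strand`,
#'   `pos`, `width`).
#' @param contig_lengths Named integer vector of contig lengths for the
#'   header.
#' @param path Output path.
#' @param genome Optional `sim_genome` used to fill in read sequences;
#'   otherwise `*` is written.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, contig_lengths, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  aln <- alignments[order(alignments$contig, alignments$pos), , drop = FALSE]
  seqs <- "*"
  if (!is.null(genome)) {
    seqs <- substr(genome$contigs[aln$contig], aln$pos,
                   aln$pos + aln$width - 1L)
    rev <- aln$strand == "-"
    if (any(rev))
      seqs[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev])))
  }
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     aln$qname, ifelse(aln$strand == "-", 16L, 0L),
                     aln$contig, aln$pos, aln$width, seqs), con)
  invisible(path)
}

#' Write simulated reads as FASTQ (Phred+33)
#' @param reads Data frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con)
  invisible(path)
}

#' Read a FASTQ file into the package's read data frame
#' @param path FASTQ path (uncompressed or gzip).
#' @return Data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # suppress a Biostrings-internal note about dropped metadata columns
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}
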