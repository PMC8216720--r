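# offtarget: homology/PAM classification of candidate cut sites against the
# guide-plus-PAM sequence, with genomic context annotation.

#' Guide specification
#'
#' @param protospacer 19-20 nt protospacer (no PAM).
#' @param target_with_pam The protospacer plus PAM as found at the on-target
#'   locus; defaults to `protospacer` + `"GG"` preceded by the first PAM
#'   base if a concrete `pam` is given.
#' @param pam Concrete 3-nt PAM at the on-target locus (e.g. `"GGG"`); used
#'   to build `target_with_pam` when that is not given directly.
#' @param pam_pattern Degenerate PAM motif candidates must carry
#'   (default `"NGG"`, the SpCas9 motif).
#' @return A list of class `guide_spec`.
#' @examples
#' guide_spec("CGTCCACGGACGCCATGCT", pam = "GGG")
#' @export
guide_spec <- function(protospacer, target_with_pam = NULL, pam = NULL,
                       pam_pattern = "NGG") {
  assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) < 19L || nchar(protospacer) > 20L)
    stopf("protospacer must be 19-20 nt")
  if (nchar(pam_pattern) != 3L) stopf("pam_pattern must be 3 nt")
  if (is.null(target_with_pam)) {
    if (is.null(pam)) stopf("give either `target_with_pam` or `pam`")
    assert_dna(pam, "pam")
    if (nchar(pam) != 3L) stopf("pam must be 3 nt")
    target_with_pam <- paste0(protospacer, pam)
  }
  if (nchar(target_with_pam) != nchar(protospacer) + 3L)
    stopf("target_with_pam must be protospacer length + 3")
  structure(list(protospacer = protospacer,
                 target_with_pam = target_with_pam,
                 pam_pattern = pam_pattern),
            class = "guide_spec")
}

#' Percent identity between the guide-with-PAM and a candidate sequence
#'
#' Position-wise comparison over the full guide+PAM length (PAM positions
#' included); the denominator is always the target length, so identities are
#' multiples of `100 / nchar(target)`. The candidate may carry at most one
#' gap character `-`, which consumes one column and counts as a mismatch.
#'
#' @param target_with_pam Target sequence including PAM.
#' @param candidate Candidate sequence of the same length (one `-` allowed).
#' @return Identity percentage in `[0, 100]`.
#' @examples
#' match_identity("CGTCCACGGACGCCATGCTGGG", "CGTCCATGGACCCCAAGCTAGG")
#' @export
match_identity <- function(target_with_pam, candidate) {
  n_gap <- lengths(regmatches(candidate, gregexpr("-", candidate)))
  if (n_gap > 1L) stopf("at most one gap character is allowed")
  if (nchar(candidate) != nchar(target_with_pam))
    stopf("candidate length must equal target length after gap placement")
  t <- chars(target_with_pam)
  c_ <- chars(candidate)
  100 * sum(t == c_ & c_ != "-") / length(t)
}

#' Check a candidate's PAM against a degenerate motif
#'
#' @param seq Candidate sequence (>= 3 nt); the last three bases are
#'   checked.
#' @param pattern Degenerate motif, IUPAC codes allowed (`N` = any).
#' @return `TRUE` iff the last 3 bases match the motif.
#' @export
pam_check <- function(seq, pattern = "NGG") {
  if (nchar(seq) < 3L) stopf("sequence shorter than a PAM")
  if (nchar(pattern) != 3L) stopf("pattern must be 3 nt")
  pam <- chars(toupper(substr(seq, nchar(seq) - 2L, nchar(seq))))
  pat <- chars(toupper(pattern))
  all(vapply(1:3, function(i) {
    set <- IUPAC_SETS[[pat[i]]]
    if (is.null(set)) stopf("unknown IUPAC code: %s", pat[i])
    pam[i] %in% set
  }, logical(1L)))
}

# Best hit of `target` within one strand of a window sequence: enumerates
# every ungapped offset and every single-gap placement (the gap sits in the
# candidate, i.e. the genome is missing one base relative to the guide).
best_hit_one_strand <- function(target, window_seq) {
  n <- nchar(target)
  L <- nchar(window_seq)
  tch <- chars(target)
  wch <- chars(window_seq)
  best <- NULL
  consider <- function(cand_chars, at) {
    ident <- 100 * sum(tch == cand_chars & cand_chars != "-") / n
    pam_ok <- pam_check(paste(cand_chars, collapse = ""))
    cand <- list(sequence = paste(cand_chars, collapse = ""),
                 identity = ident, pam_ok = pam_ok, at = at)
    if (is.null(best) ||
        ident > best$identity ||
        (ident == best$identity && pam_ok && !best$pam_ok) ||
        (ident == best$identity && pam_ok == best$pam_ok && at < best$at))
      best <<- cand
    invisible(NULL)
  }
  if (L >= n) {
    for (i in seq_len(L - n + 1L))
      consider(wch[i:(i + n - 1L)], i)
  }
  if (L >= n - 1L) {
    for (i in seq_len(L - n + 2L)) {
      sub <- wch[i:(i + n - 2L)]
      for (j in 2L:(n - 1L))  # internal gap columns only
        consider(append(sub, "-", after = j - 1L), i)
    }
  }
  best
}

#' Scan a genomic window around a cut site for the best guide match
#'
#' Both strands are scanned over `site +- window`; all ungapped offsets and
#' all single-gap placements are enumerated and the hit maximising identity
#' is returned (ties: PAM-bearing hit first, then leftmost, plus strand
#' before minus).
#'
#' @param genome A `sim_genome`, a named character vector of contig
#'   sequences, or a FASTA path.
#' @param contig Contig of the cut site.
#' @param position 1-based cut-site position.
#' @param guide A [guide_spec()].
#' @param window Half-width of the scanned window in bases (default 25).
#' @return A list of class `homology_hit`: `sequence` (with any gap
#'   character), `strand`, `identity`, `pam_ok`.
#' @export
scan_window <- function(genome, contig, position, guide, window = 25L) {
  contigs <- as_contigs(genome)
  if (!contig %in% names(contigs)) stopf("unknown contig: %s", contig)
  n <- nchar(guide$target_with_pam)
  if (window < 1L) stopf("window must be positive")
  L <- nchar(contigs[[contig]])
  if (position < 1L || position > L) stopf("site outside the genome")
  lo <- max(1L, position - window - n)
  hi <- min(L, position + window + n)
  fwd <- substr(contigs[[contig]], lo, hi)
  hit_f <- best_hit_one_strand(guide$target_with_pam, fwd)
  hit_r <- best_hit_one_strand(guide$target_with_pam, revcomp(fwd))
  pick_r <- is.null(hit_f) ||
    (!is.null(hit_r) && (hit_r$identity > hit_f$identity ||
                           (hit_r$identity == hit_f$identity &&
                              hit_r$pam_ok && !hit_f$pam_ok)))
  hit <- if (pick_r) c(hit_r, strand = "-") else c(hit_f, strand = "+")
  structure(list(sequence = hit$sequence, strand = hit$strand,
                 identity = hit$identity, pam_ok = hit$pam_ok),
            class = "homology_hit")
}

as_contigs <- function(genome) {
  if (inherits(genome, "sim_genome")) return(genome$contigs)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    return(setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stopf("genome must be a sim_genome, named sequences, or a FASTA path")
}

#' Annotate the genomic context of a position
#'
#' Labels follow the priority coding > intron > antisense > intergenic when
#' overlapping features conflict. The annotation is a data frame (or
#' GRanges) with columns `contig` (`seqnames`), `start`, `end`, `type` and
#' optionally `gene`; `type` values are mapped as exon/CDS/coding -> coding,
#' gene/intron -> intron (gene spans without an exon overlap), antisense ->
#' antisense.
#'
#' @param contig,position Query position (1-based).
#' @param annotation Feature table as above, or `NULL` for "unknown".
#' @return A list with `context` and `gene`.
#' @export
annotate_context <- function(contig, position, annotation = NULL) {
  if (is.null(annotation)) return(list(context = "unknown", gene = NA_character_))
  ann <- as_annotation_df(annotation)
  hit <- ann[ann$contig == contig & ann$start <= position &
               ann$end >= position, , drop = FALSE]
  if (!nrow(hit)) return(list(context = "Intergenic", gene = NA_character_))
  cls <- type_class(hit$type)
  for (lab in c("coding", "intron", "antisense")) {
    j <- which(cls == lab)
    if (length(j))
      return(list(context = lab, gene = hit$gene[j[1L]]))
  }
  list(context = "Intergenic", gene = NA_character_)
}

type_class <- function(type) {
  type <- tolower(type)
  out <- rep(NA_character_, length(type))
  out[type %in% c("exon", "cds", "coding")] <- "coding"
  out[type %in% c("gene", "intron", "transcript", "mrna")] <- "intron"
  out[type %in% c("antisense", "antisense_rna", "lnc_rna_antisense")] <-
    "antisense"
  out
}

as_annotation_df <- function(annotation) {
  if (inherits(annotation, "GRanges")) {
    mc <- S4Vectors::mcols(annotation)
    data.frame(
      contig = as.character(GenomeInfoDb::seqnames(annotation)),
      start = BiocGenerics::start(annotation),
      end = BiocGenerics::end(annotation),
      type = if ("type" %in% names(mc)) as.character(mc$type) else "gene",
      gene = if ("gene" %in% names(mc)) as.character(mc$gene)
             else if ("Name" %in% names(mc)) as.character(mc$Name)
             else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("contig", "start", "end", "type") %in% names(annotation)))
    if (!"gene" %in% names(annotation)) annotation$gene <- NA_character_
    annotation
  }
}

#' Classify cut-site candidates by guide homology
#'
#' Splits the treated run's candidates into a with-homology table
#' (best-window identity at or above the threshold AND a PAM-bearing hit)
#' and a without-homology table; control candidates, when given, are
#' reported separately without classification. With-homology rows carry a
#' genomic context label (or "unknown" when no annotation is supplied).
#'
#' @param treated Candidate table from [call_candidates()] for the treated
#'   run.
#' @param control Optional candidate table for the control (no-guide) run,
#'   computed with identical configuration.
#' @param guide A [guide_spec()].
#' @param genome Genome as in [scan_window()].
#' @param annotation Optional feature table for [annotate_context()].
#' @param identity_threshold Minimum identity (% including PAM) to count as
#'   homologous (default 70).
#' @param window Scan half-width (default 25).
#' @return A list of class `offtarget_tables` with data frames
#'   `with_homology`, `without_homology`, `control`.
#' @export
classify_candidates <- function(treated, control = NULL, guide, genome,
                                annotation = NULL, identity_threshold = 70,
                                window = 25L) {
  scan1 <- function(df) {
    if (!nrow(df)) {
      df$sequence <- character(0); df$hit_strand <- character(0)
      df$identity <- numeric(0); df$pam_ok <- logical(0)
      df$context <- character(0); df$gene <- character(0)
      return(df)
    }
    hits <- lapply(seq_len(nrow(df)), function(i)
      scan_window(genome, df$contig[i], df$start[i], guide, window))
    ctx <- lapply(seq_len(nrow(df)), function(i)
      annotate_context(df$contig[i], df$start[i], annotation))
    df$sequence <- vapply(hits, `[[`, character(1L), "sequence")
    df$hit_strand <- vapply(hits, `[[`, character(1L), "strand")
    df$identity <- vapply(hits, `[[`, numeric(1L), "identity")
    df$pam_ok <- vapply(hits, `[[`, logical(1L), "pam_ok")
    df$context <- vapply(ctx, `[[`, character(1L), "context")
    df$gene <- vapply(ctx, `[[`, character(1L), "gene")
    df
  }
  tr <- scan1(treated)
  homologous <- tr$identity >= identity_threshold & tr$pam_ok
  structure(list(
    with_homology = tr[homologous, , drop = FALSE],
    without_homology = tr[!homologous, , drop = FALSE],
    control = if (is.null(control)) treated[0L, , drop = FALSE] else control),
    class = "offtarget_tables")
}

#' Read a BED or GFF3 annotation into the package's feature table
#'
#' Thin wrapper over `rtracklayer::import()`; requires the rtracklayer
#' package.
#'
#' @param path BED or GFF3 file.
#' @return Feature data frame for [annotate_context()].
#' @export
read_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("rtracklayer is required to read %s", path)
  as_annotation_df(rtracklayer::import(path))
}
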