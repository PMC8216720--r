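# Fixtures and independent oracles, built in code at test time.

# 155-bp amplicon with the start-codon context GACGCC|ATG at position 65,
# mirroring the structure of the sequenced locus (the CATG straddling the
# codon is the restriction-screen site).
make_amplicon <- function(seed = 9) {
  set.seed(seed)
  for (i in 1:1000) {
    left <- paste(sample(c("A", "C", "G", "T"), 58, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 86, TRUE), collapse = "")
    seq <- paste0(left, "GACGCC", "ATG", right)
    # exactly one CATG: the screen site straddling the codon (position 64)
    m <- gregexpr("CATG", seq, fixed = TRUE)[[1L]]
    if (length(m) == 1L && m[1L] == 64L)
      return(list(sequence = seq, start_codon = 65L))
  }
  stop("could not build amplicon fixture")
}

# Indel spectrum shaped like the study's observed outcome mix: `rate` total
# editing, insertions dominated by 1-bp A/T events at the codon, deletions
# dominated by 2-bp events.
study_spectrum <- function(rate, start_codon) {
  sc <- start_codon
  data.frame(
    type = c("ins", "ins", "ins", "ins", "ins", "del", "del", "del"),
    length = c(1L, 1L, 1L, 1L, 2L, 1L, 2L, 3L),
    at = c(sc, sc, sc, sc, sc, sc, sc, sc - 1L),
    bases = c("A", "T", "G", "C", "AT", "", "", ""),
    prob = rate * c(0.835 * c(0.487, 0.446, 0.018, 0.049),
                    0.009, 0.039, 0.094, 0.023),
    stringsAsFactors = FALSE)
}

# 560-bp amplicon whose CATG digest yields fragments 303/131/126, with the
# first site standing in for the start-codon site.
make_560_amplicon <- function(seed = 20) {
  set.seed(seed)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 560, TRUE), collapse = "")
    s <- paste0(substr(s, 1, 302), "CATG", substr(s, 307, 433),
                "CATG", substr(s, 438, 560))
    if (identical(digest_fragments(s)$cut_positions, c(303L, 434L)))
      return(s)
  }
}

# --- independent oracles ----------------------------------------------------

# Naive per-position pileup recount (no coverage() machinery).
oracle_profile <- function(aln, lo, hi) {
  n <- hi - lo + 1
  S_plus <- S_minus <- D_plus <- D_minus <- integer(n)
  for (k in seq_len(nrow(aln))) {
    p <- aln$pos[k]; e <- aln$pos[k] + aln$width[k] - 1L
    idx <- max(p, lo):min(e, hi) - lo + 1L
    if (aln$strand[k] == "+") {
      if (p >= lo && p <= hi) S_plus[p - lo + 1L] <- S_plus[p - lo + 1L] + 1L
      if (length(idx) && min(idx) >= 1) D_plus[idx] <- D_plus[idx] + 1L
    } else {
      if (e >= lo && e <= hi) S_minus[e - lo + 1L] <- S_minus[e - lo + 1L] + 1L
      if (length(idx) && min(idx) >= 1) D_minus[idx] <- D_minus[idx] + 1L
    }
  }
  list(S_plus = S_plus, D_plus = D_plus, S_minus = S_minus,
       D_minus = D_minus)
}

# Brute-force candidate caller: recount pileups position by position,
# filter, then enumerate every (plus, minus) position pair.
oracle_candidates <- function(aln, cfg = detector_config()) {
  out <- list()
  for (ctg in unique(aln$contig)) {
    a <- aln[aln$contig == ctg, , drop = FALSE]
    lo <- min(a$pos); hi <- max(a$pos + a$width - 1L)
    prof <- oracle_profile(a, lo, hi)
    pos <- lo:hi
    keep <- function(S, D) S >= cfg$min_starts & D > 0 & S / D >= cfg$min_frac
    pk <- which(keep(prof$S_plus, prof$D_plus))
    mk <- which(keep(prof$S_minus, prof$D_minus))
    for (i in pk) for (j in mk) {
      g <- pos[i] - pos[j] - 1L
      if (!(g %in% cfg$allowed_gaps)) next
      sc <- 100 * (prof$S_plus[i] + prof$S_minus[j]) /
        (prof$D_plus[i] + prof$D_minus[j])
      if (sc <= cfg$score_threshold) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, gap = g, start = min(pos[i], pos[j] + 1L),
        plus = prof$S_plus[i], depth_plus = prof$D_plus[i],
        minus = prof$S_minus[j], depth_minus = prof$D_minus[j],
        score = sc, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), gap = integer(),
                      start = integer(), score = numeric()))
  df <- do.call(rbind, out)
  df[order(-df$score, df$contig, df$start, df$gap), , drop = FALSE]
}

# Quadratic Gotoh DP for global affine alignment score: match +1,
# mismatch -2, gap of length L costs 6 + (L - 1).
oracle_global_score <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -6 - (i - 2L)
  for (j in 2L:(m + 1L)) Y[1L, j] <- -6 - (j - 2L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) 1 else -2
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - 6, X[i - 1L, j] - 1, Y[i - 1L, j] - 6)
      Y[i, j] <- max(M[i, j - 1L] - 6, Y[i, j - 1L] - 1, X[i, j - 1L] - 6)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Exhaustive best-identity search over every placement in a window, written
# without the package's candidate-generation code path.
oracle_best_identity <- function(target, window_seq) {
  tch <- strsplit(target, "")[[1L]]
  n <- length(tch)
  best <- -1
  for (strand_seq in c(window_seq,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(window_seq))))) {
    wch <- strsplit(strand_seq, "")[[1L]]
    L <- length(wch)
    if (L >= n)
      for (i in 1:(L - n + 1)) {
        cand <- wch[i:(i + n - 1)]
        best <- max(best, 100 * sum(cand == tch) / n)
      }
    if (L >= n - 1)
      for (i in 1:(L - n + 2))
        for (gp in 2:(n - 1)) {
          cand <- append(wch[i:(i + n - 2)], "-", after = gp - 1)
          best <- max(best, 100 * sum(cand == tch & cand != "-") / n)
        }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
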