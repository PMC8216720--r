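# shared internal helpers

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate base -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stopf("%s must be a single non-empty string", what)
  if (grepl("[^ACGT]", x)) stopf("%s must contain only A/C/G/T", what)
  invisible(x)
}

# Phred+33 helpers
decode_phred <- function(qual) utf8ToInt(qual) - 33L
encode_phred <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

round1 <- function(x) round(x, 1L)
round2 <- function(x) round(x, 2L)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
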