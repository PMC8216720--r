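# quantify: cell-number inference from gDNA mass, normalisation of indel
# rates for stromal contamination, cross-sample summaries, and the
# in-silico CATG restriction-digest screen.

#' Constants of the cell-number / normalisation model
#'
#' The per-cell diploid genome mass follows from
#' `genome_bp_2n * bp_molar_mass / avogadro`:
#' 5.46e9 bp x 660 g/mol / 6.022e23 = 5.984 pg. The default, 5.988 pg, is
#' the constant that reproduces the published per-sample cell numbers
#' exactly; the formula-derived value is available via
#' `per_cell_gdna_pg = formula_per_cell_mass_pg()`. The expected
#' endothelial population is density x area = 2300 * pi ~ 7226 cells for a
#' 1 mm-radius disc.
#'
#' @param genome_bp_2n Diploid genome size in base pairs.
#' @param bp_molar_mass Average molar mass of a base pair (g/mol).
#' @param avogadro Avogadro's number (1/mol).
#' @param per_cell_gdna_pg Genomic DNA mass per cell in picograms.
#' @param endothelial_density Cells per mm^2.
#' @param endothelial_area_mm2 Sampled area in mm^2 (default `pi`, a
#'   1 mm-radius disc).
#' @return A list of class `cell_model`.
#' @export
cell_model <- function(genome_bp_2n = 5.46e9, bp_molar_mass = 660,
                       avogadro = 6.022e23, per_cell_gdna_pg = 5.988,
                       endothelial_density = 2300,
                       endothelial_area_mm2 = pi) {
  stopifnot(genome_bp_2n > 0, bp_molar_mass > 0, avogadro > 0,
            per_cell_gdna_pg > 0, endothelial_density > 0,
            endothelial_area_mm2 > 0)
  structure(list(genome_bp_2n = genome_bp_2n,
                 bp_molar_mass = bp_molar_mass, avogadro = avogadro,
                 per_cell_gdna_pg = per_cell_gdna_pg,
                 endothelial_density = endothelial_density,
                 endothelial_area_mm2 = endothelial_area_mm2,
                 expected_cells = endothelial_density * endothelial_area_mm2),
            class = "cell_model")
}

#' Per-cell genome mass implied by the model's physical constants
#' @param model A [cell_model()].
#' @return Mass in picograms (~5.984 for the defaults).
#' @export
formula_per_cell_mass_pg <- function(model = cell_model()) {
  model$genome_bp_2n * model$bp_molar_mass / model$avogadro * 1e12
}

#' Infer cell number from purified gDNA mass
#'
#' `cells = mass_ng / (per_cell_gdna_pg / 1000)`, rounded to the nearest
#' integer for reporting. Linear in mass.
#'
#' @param mass_ng gDNA mass in nanograms (vectorised).
#' @param model A [cell_model()].
#' @return Integer cell counts.
#' @examples
#' cells_from_gdna(192)  # 32064
#' @export
cells_from_gdna <- function(mass_ng, model = cell_model()) {
  if (any(mass_ng < 0)) stopf("mass must be non-negative")
  round(mass_ng / (model$per_cell_gdna_pg / 1000))
}

#' Normalise an indel rate by the endothelial fraction of the gDNA
#'
#' The raw indel rate is measured over all cells contributing gDNA; scaling
#' by inferred cells over the expected endothelial population estimates the
#' rate among endothelial cells alone. The result may exceed 100% when the
#' inferred population is much larger than expected.
#'
#' @param raw_rate Raw indel rate in percent (vectorised).
#' @param mass_ng Purified gDNA mass in nanograms.
#' @param model A [cell_model()].
#' @return A data frame of class `normalized_rate` with `raw_rate`,
#'   `gdna_ng`, `inferred_cells`, `expected_cells`, `normalized_rate`.
#' @examples
#' normalized_indel_rate(18.5, 192)$normalized_rate  # 82.1
#' @export
normalized_indel_rate <- function(raw_rate, mass_ng, model = cell_model()) {
  if (any(raw_rate < 0 | raw_rate > 100)) stopf("raw_rate must be in [0, 100]")
  if (any(mass_ng < 0)) stopf("mass must be non-negative")
  if (model$expected_cells <= 0) stopf("zero expected cells")
  cells <- cells_from_gdna(mass_ng, model)
  out <- data.frame(raw_rate = raw_rate, gdna_ng = mass_ng,
                    inferred_cells = cells,
                    expected_cells = model$expected_cells,
                    normalized_rate = round1(
                      raw_rate * cells / model$expected_cells))
  class(out) <- c("normalized_rate", "data.frame")
  out
}

#' Cross-sample mean and sample standard deviation
#'
#' The SD uses the n-1 denominator, matching the published
#' "mean +- SD" rows.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `mean` and `sd`.
#' @export
summarize_mean_sd <- function(values) {
  if (length(values) < 2L) stopf("need at least two values")
  list(mean = mean(values), sd = sd(values))
}

#' In-silico restriction digest
#'
#' Cuts at every occurrence of the recognition motif, `cut_after` bases
#' into the motif (default `CATG` cut after the C, the CviAII/Hin1II
#' behaviour used for the start-codon screen). Overlapping occurrences are
#' all honoured. Fragment lengths always sum to the input length.
#'
#' @param sequence Uppercase A/C/G/T sequence.
#' @param motif Recognition motif (default `"CATG"`).
#' @param cut_after Offset of the cut within the motif: the cut falls
#'   between motif positions `cut_after` and `cut_after + 1` (default 1,
#'   i.e. C^ATG).
#' @return A list of class `digest_result` with `cut_positions` (prefix
#'   lengths left of each cut) and `fragments` (5'-to-3' ordered lengths).
#' @examples
#' digest_fragments("AACATGAA")$fragments  # 3 5
#' @export
digest_fragments <- function(sequence, motif = "CATG", cut_after = 1L) {
  assert_dna(sequence, "sequence")
  if (cut_after < 0L || cut_after > nchar(motif))
    stopf("cut_after must lie within the motif")
  L <- nchar(sequence)
  m <- nchar(motif)
  starts <- integer(0)
  if (L >= m) {
    # manual scan so overlapping occurrences are all found
    for (i in seq_len(L - m + 1L))
      if (substr(sequence, i, i + m - 1L) == motif)
        starts <- c(starts, i)
  }
  cuts <- starts - 1L + cut_after
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  frags <- diff(c(0L, cuts, L))
  structure(list(motif = motif, cut_after = as.integer(cut_after),
                 cut_positions = cuts, fragments = as.integer(frags),
                 length = L),
            class = "digest_result")
}

#' Predict gel bands for an edited amplicon
#'
#' Determines which reference cut sites are destroyed in the edited
#' sequence and reports the resulting bands as merged *reference* fragment
#' lengths (so the predicted band for a destroyed internal site is the sum
#' of the two reference fragments it separated; the physical band
#' additionally shifts by the net indel size). A reference cut site counts
#' as destroyed when the edited sequence has no cut within the coordinate
#' slack allowed by the net length difference.
#'
#' @param ref_digest A [digest_fragments()] result for the reference.
#' @param edited_sequence The edited amplicon sequence.
#' @return A list of class `band_prediction` with `destroyed_sites`
#'   (reference cut coordinates), `bands` (ordered lengths) and `merged`
#'   (logical flag per band).
#' @export
indel_band_prediction <- function(ref_digest, edited_sequence) {
  stopifnot(inherits(ref_digest, "digest_result"))
  ed <- digest_fragments(edited_sequence, ref_digest$motif,
                         ref_digest$cut_after)
  tol <- abs(ed$length - ref_digest$length)
  surviving <- logical(length(ref_digest$cut_positions))
  used <- logical(length(ed$cut_positions))
  for (i in seq_along(ref_digest$cut_positions)) {
    d <- abs(ed$cut_positions - ref_digest$cut_positions[i])
    j <- which(!used & d <= tol)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      surviving[i] <- TRUE
    }
  }
  # merge reference fragments across destroyed sites
  frags <- ref_digest$fragments
  bands <- integer(0)
  merged <- logical(0)
  acc <- frags[1L]
  acc_merged <- FALSE
  for (i in seq_along(ref_digest$cut_positions)) {
    if (surviving[i]) {
      bands <- c(bands, acc); merged <- c(merged, acc_merged)
      acc <- frags[i + 1L]; acc_merged <- FALSE
    } else {
      acc <- acc + frags[i + 1L]; acc_merged <- TRUE
    }
  }
  bands <- c(bands, acc); merged <- c(merged, acc_merged)
  structure(list(
    destroyed_sites = ref_digest$cut_positions[!surviving],
    bands = bands, merged = merged),
    class = "band_prediction")
}
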