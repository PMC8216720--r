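# pipeline: end-to-end orchestration with run manifests.
#
# All machine output goes to files; log lines go to stderr. Counts are
# reconciled across stages in the manifest (reads in = retained +
# discarded) and a failed reconciliation is an error, not a warning.

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

manifest_skeleton <- function(config) {
  list(tool = "cutscope",
       version = as.character(utils::packageVersion("cutscope")),
       config = config,
       counts = list(),
       elapsed_s = list())
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the digenome discovery + classification pipeline
#'
#' Calls cut-site candidates on the treated alignments (and, when given, on
#' the control run with identical configuration), then classifies the
#' treated candidates by guide homology. When no genome or guide is
#' supplied the homology stage is skipped with a warning and the raw
#' candidate table is returned.
#'
#' @param treated Alignments: a data frame, a `digenome_sim`, or a SAM/BAM
#'   path.
#' @param control Optional control alignments (same forms).
#' @param guide Optional [guide_spec()].
#' @param genome Optional genome (see [scan_window()]).
#' @param annotation Optional feature table for context labels.
#' @param cfg A [detector_config()].
#' @param identity_threshold Homology threshold in percent (default 70).
#' @param out_dir Optional output directory for TSV tables and the JSON
#'   manifest.
#' @return A list with `candidates`, `control_candidates`, `tables` (an
#'   `offtarget_tables` or `NULL`), and `manifest`.
#' @export
run_digenome_pipeline <- function(treated, control = NULL, guide = NULL,
                                  genome = NULL, annotation = NULL,
                                  cfg = detector_config(),
                                  identity_threshold = 70, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  load_aln <- function(x) {
    if (is.character(x)) read_alignments(x, cfg)
    else if (inherits(x, "digenome_sim")) x$alignments
    else x
  }
  aln <- load_aln(treated)
  if (is.null(aln) || !nrow(aln)) stopf("no alignments")
  manifest <- manifest_skeleton(list(
    min_starts = cfg$min_starts, min_frac = cfg$min_frac,
    score_threshold = cfg$score_threshold,
    identity_threshold = identity_threshold))
  manifest$counts$treated_alignments <- nrow(aln)
  log_msg("digenome", "calling candidates on %d alignments", nrow(aln))
  cand <- call_candidates(aln, cfg)
  manifest$counts$treated_candidates <- nrow(cand)
  ctrl_cand <- NULL
  if (!is.null(control)) {
    caln <- load_aln(control)
    manifest$counts$control_alignments <- nrow(caln)
    ctrl_cand <- call_candidates(caln, cfg)
    manifest$counts$control_candidates <- nrow(ctrl_cand)
  }
  tables <- NULL
  if (!is.null(guide) && !is.null(genome)) {
    log_msg("offtarget", "classifying %d candidates", nrow(cand))
    tables <- classify_candidates(cand, ctrl_cand, guide, genome,
                                  annotation, identity_threshold)
    manifest$counts$with_homology <- nrow(tables$with_homology)
    manifest$counts$without_homology <- nrow(tables$without_homology)
    stopifnot(manifest$counts$with_homology +
                manifest$counts$without_homology ==
                manifest$counts$treated_candidates)
  } else if (!is.null(guide) || !is.null(genome)) {
    warning("genome or guide missing; homology stage skipped")
  }
  manifest$elapsed_s$total <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_candidate_table(cand, file.path(out_dir, "candidates.tsv"))
    if (!is.null(ctrl_cand))
      write_candidate_table(ctrl_cand,
                            file.path(out_dir, "control_candidates.tsv"))
    if (!is.null(tables)) {
      write_tsv(tables$with_homology,
                file.path(out_dir, "with_homology.tsv"))
      write_tsv(tables$without_homology,
                file.path(out_dir, "without_homology.tsv"))
    }
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(candidates = cand, control_candidates = ctrl_cand, tables = tables,
       manifest = manifest)
}

#' Run the amplicon quantification + normalisation pipeline
#'
#' Quantifies each sample (quality filter, alignment, classification),
#' builds the per-sample category table with a cross-sample mean +- SD row,
#' the single-insertion base composition table, insertion/deletion size
#' spectra, and — when gDNA masses are supplied — the normalised indel
#' rates.
#'
#' @param samples Named list of read data frames or FASTQ paths.
#' @param ref An [amplicon_ref()].
#' @param gdna_ng Optional numeric vector of per-sample gDNA masses (ng).
#' @param model A [cell_model()] for normalisation.
#' @param quality_cutoff Median-quality cutoff (default 5).
#' @param out_dir Optional output directory.
#' @return A list with `summary` (per-sample category data frame),
#'   `summary_stats` (mean/SD per category), `composition`,
#'   `spectra`, `normalized` (or `NULL`), `samples` (the
#'   `amplicon_sample` objects) and `manifest`.
#' @export
run_amplicon_pipeline <- function(samples, ref, gdna_ng = NULL,
                                  model = cell_model(), quality_cutoff = 5,
                                  out_dir = NULL) {
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- sprintf("sample%d", seq_along(samples))
  t0 <- proc.time()[["elapsed"]]
  manifest <- manifest_skeleton(list(quality_cutoff = quality_cutoff,
                                     start_codon = ref$start_codon,
                                     window = ref$window))
  quant <- list(); summaries <- list(); comps <- list(); spectra <- list()
  for (nm in names(samples)) {
    log_msg("amplicon", "quantifying %s", nm)
    q <- quantify_amplicon(samples[[nm]], ref, quality_cutoff)
    if (q$n_retained == 0L)
      stopf("all reads discarded in %s (%s)", nm,
            paste(unique(q$discard_reasons), collapse = ", "))
    stopifnot(q$n_retained + q$n_discarded == q$n_input)
    manifest$counts[[nm]] <- list(input = q$n_input,
                                  retained = q$n_retained,
                                  discarded = q$n_discarded)
    quant[[nm]] <- q
    summaries[[nm]] <- indel_summary(q)
    comps[[nm]] <- insertion_base_composition(q)
    spectra[[nm]] <- size_spectrum(q)
  }
  summary_df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(sample = nm, total_reads = s$total_reads,
               no_change = s$n_no_change, insertion = s$n_insertion,
               deletion = s$n_deletion, indel = s$n_indel,
               pct_no_change = s$pct_no_change,
               pct_insertion = s$pct_insertion,
               pct_deletion = s$pct_deletion, pct_indel = s$pct_indel,
               stringsAsFactors = FALSE)
  }))
  summary_stats <- NULL
  if (nrow(summary_df) >= 2L) {
    summary_stats <- lapply(
      c("pct_no_change", "pct_insertion", "pct_deletion", "pct_indel"),
      function(col) summarize_mean_sd(summary_df[[col]]))
    names(summary_stats) <- c("no_change", "insertion", "deletion", "indel")
  }
  normalized <- NULL
  if (!is.null(gdna_ng)) {
    stopifnot(length(gdna_ng) == nrow(summary_df))
    normalized <- normalized_indel_rate(summary_df$pct_indel, gdna_ng, model)
    normalized <- cbind(sample = summary_df$sample, normalized)
  }
  manifest$elapsed_s$total <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(summary_df, file.path(out_dir, "indel_summary.tsv"))
    comp_rows <- Filter(Negate(is.null), comps)
    if (length(comp_rows)) {
      comp_df <- do.call(rbind, lapply(names(comp_rows), function(nm) {
        cc <- comp_rows[[nm]]
        data.frame(sample = nm, total = cc$total,
                   A = cc$counts[["A"]], T = cc$counts[["T"]],
                   G = cc$counts[["G"]], C = cc$counts[["C"]],
                   pct_A = cc$pct[["A"]], pct_T = cc$pct[["T"]],
                   pct_G = cc$pct[["G"]], pct_C = cc$pct[["C"]],
                   stringsAsFactors = FALSE)
      }))
      write_tsv(comp_df, file.path(out_dir, "insertion_composition.tsv"))
    }
    spec_df <- do.call(rbind, lapply(names(spectra), function(nm) {
      sp <- spectra[[nm]]
      rbind(
        if (nrow(sp$insertion))
          cbind(sample = nm, type = "ins", sp$insertion) else NULL,
        if (nrow(sp$deletion))
          cbind(sample = nm, type = "del", sp$deletion) else NULL)
    }))
    if (!is.null(spec_df))
      write_tsv(spec_df, file.path(out_dir, "size_spectrum.tsv"))
    if (!is.null(normalized))
      write_tsv(normalized, file.path(out_dir, "normalized_rates.tsv"))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(summary = summary_df, summary_stats = summary_stats,
       composition = comps, spectra = spectra, normalized = normalized,
       samples = quant, manifest = manifest)
}
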