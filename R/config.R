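#' Analysis configuration
#'
#' Collects every tunable threshold used across the pipeline in one object.
#' Defaults follow the published screening protocol: a 10-CDS same-strand
#' neighborhood for operon typing, a 95% genome-completeness floor, mapping
#' identity thresholds of 90% and 95%, fragment lengths of 40/60/80/100 aa
#' (10 fragments each), USEARCH-style pair merging (at most 5 mismatches,
#' at least 20 bases of overlap), expected-error trimming below 0.5, a
#' 200-base minimum merged length, a 2,500,000-read cap per sample, retention
#' of hits within 95% of the best identity, full-length gene sizes of 1,497 bp
#' (nifH) and 894 bp (nifD), and 99% Poisson confidence intervals for the
#' count-proportionality test.
#'
#' @param neighborhood_radius Maximum number of same-strand CDS positions
#'   between nifH and a nifD/nifK-like gene for the pair to count as
#'   neighboring (operonic, T1).
#' @param completeness_min Minimum genome completeness fraction.
#' @param identity_thresholds Identity thresholds used in the fragment-mapping
#'   and similarity-network analyses.
#' @param subseq_lengths Fragment lengths, in amino acids, drawn from each
#'   full-length NifH representative.
#' @param subseqs_per_length Number of random fragments per length.
#' @param msa_window Width, in alignment columns, of each MSA window.
#' @param msa_starts 1-based start columns of the MSA windows.
#' @param min_window_residues Minimum number of residues left after degapping
#'   for an MSA-window subsequence to enter the similarity network.
#' @param cluster_identity Greedy clustering threshold for collapsing
#'   near-identical full-length sequences.
#' @param hit_retention_factor A read's hits are retained when their identity
#'   is at least this multiple of (or, for `retention_mode = "subtractive"`,
#'   within `1 - factor` of) the best identity.
#' @param retention_mode `"multiplicative"` (default) or `"subtractive"`.
#' @param min_merged_length Minimum merged-read length, in bases.
#' @param reads_cap Number of filtered reads retained per sample (first-come).
#' @param max_expected_errors Expected-error ceiling (strict) for trimming.
#' @param merge_max_diffs Maximum mismatches tolerated in the merge overlap.
#' @param merge_min_overlap Minimum merge overlap, in bases.
#' @param allow_merge_stagger Allow staggered (read-through) overlaps, with
#'   overhangs trimmed.
#' @param gene_length_H,gene_length_D,gene_length_K Full gene lengths in bp
#'   used by the proportionality test. nifH and nifD lengths are the published
#'   full-length sizes; nifK is configurable (1,560 bp default, a typical
#'   full-length nifK).
#' @param ci_level Confidence level of the Poisson count intervals.
#' @param gap_open,gap_extend Affine gap parameters (a gap of length L costs
#'   `gap_open + L * gap_extend`, both negative).
#' @param stage1_min_identity,stage1_min_cols First-stage screen: a read is a
#'   nitrogenase candidate when any translated fragment aligns to a
#'   nitrogenase reference at at least this identity over at least this many
#'   non-terminal-gap columns.
#' @param stage2_min_identity Second stage: minimum best identity against the
#'   full reference panel for a gene assignment.
#' @param min_orf_aa Minimum translated-fragment length (fragments are split
#'   at stop codons).
#'
#' @return An object of class `nif_config` (a named list).
#' @export
nif_config <- function(neighborhood_radius = 10L,
                       completeness_min = 0.95,
                       identity_thresholds = c(0.90, 0.95),
                       subseq_lengths = c(40L, 60L, 80L, 100L),
                       subseqs_per_length = 10L,
                       msa_window = 40L,
                       msa_starts = c(31L, 71L, 111L, 151L, 191L, 231L, 271L),
                       min_window_residues = 20L,
                       cluster_identity = 0.95,
                       hit_retention_factor = 0.95,
                       retention_mode = c("multiplicative", "subtractive"),
                       min_merged_length = 200L,
                       reads_cap = 2500000L,
                       max_expected_errors = 0.5,
                       merge_max_diffs = 5L,
                       merge_min_overlap = 20L,
                       allow_merge_stagger = TRUE,
                       gene_length_H = 1497L,
                       gene_length_D = 894L,
                       gene_length_K = 1560L,
                       ci_level = 0.99,
                       gap_open = -11L,
                       gap_extend = -1L,
                       stage1_min_identity = 0.5,
                       stage1_min_cols = 30L,
                       stage2_min_identity = 0.6,
                       min_orf_aa = 20L) {
  retention_mode <- match.arg(retention_mode)
  stopifnot(
    neighborhood_radius >= 0,
    completeness_min >= 0, completeness_min <= 1,
    all(identity_thresholds > 0 & identity_thresholds <= 1),
    all(subseq_lengths > 0), subseqs_per_length > 0,
    msa_window > 0, min_window_residues > 0,
    cluster_identity > 0, cluster_identity <= 1,
    hit_retention_factor > 0, hit_retention_factor <= 1,
    min_merged_length >= 0, reads_cap > 0,
    max_expected_errors > 0,
    merge_max_diffs >= 0, merge_min_overlap >= 1,
    gene_length_H > 0, gene_length_D > 0, gene_length_K > 0,
    ci_level > 0, ci_level < 1,
    gap_open <= 0, gap_extend <= 0,
    stage1_min_identity > 0, stage1_min_identity <= 1,
    stage1_min_cols >= 1,
    stage2_min_identity > 0, stage2_min_identity <= 1,
    min_orf_aa >= 1
  )
  cfg <- list(
    neighborhood_radius = as.integer(neighborhood_radius),
    completeness_min = completeness_min,
    identity_thresholds = sort(identity_thresholds),
    subseq_lengths = as.integer(subseq_lengths),
    subseqs_per_length = as.integer(subseqs_per_length),
    msa_window = as.integer(msa_window),
    msa_starts = as.integer(msa_starts),
    min_window_residues = as.integer(min_window_residues),
    cluster_identity = cluster_identity,
    hit_retention_factor = hit_retention_factor,
    retention_mode = retention_mode,
    min_merged_length = as.integer(min_merged_length),
    reads_cap = as.integer(reads_cap),
    max_expected_errors = max_expected_errors,
    merge_max_diffs = as.integer(merge_max_diffs),
    merge_min_overlap = as.integer(merge_min_overlap),
    allow_merge_stagger = isTRUE(allow_merge_stagger),
    gene_length_H = as.integer(gene_length_H),
    gene_length_D = as.integer(gene_length_D),
    gene_length_K = as.integer(gene_length_K),
    ci_level = ci_level,
    gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend),
    stage1_min_identity = stage1_min_identity,
    stage1_min_cols = as.integer(stage1_min_cols),
    stage2_min_identity = stage2_min_identity,
    min_orf_aa = as.integer(min_orf_aa)
  )
  structure(cfg, class = "nif_config")
}

#' @export
print.nif_config <- function(x, ...) {
  cat("<nif_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# one-line "key=value; ..." echo used in output file headers
config_echo <- function(config) {
  paste(vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]]), collapse = ","))
  }, character(1)), collapse = "; ")
}
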