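# Metagenome screen: paired-end reads -> merged/trimmed/filtered sequences ->
# two-stage translated homology screen -> nifH/nifD-like/nifK-like counts ->
# true/pseudo/ambiguous nifH verdicts -> overestimation factor and the
# Poisson gene-length proportionality test.

#' Quality-control a paired-end sample
#'
#' Merges each read pair by overlap, trims every merged read to its longest
#' window with expected errors strictly below the ceiling, drops reads shorter
#' than `min_merged_length`, and keeps the first `reads_cap` survivors in
#' input order. A sample that ends below the cap is flagged (`below_cap`),
#' mirroring the protocol of discarding samples with fewer filtered reads
#' than the cap.
#'
#' @param r1,r2 Paired reads: file paths to FASTQ, or `list(ids, seqs, quals)`
#'   as returned by [read_fastq()] / [gen_metagenome()].
#' @param config A [nif_config()].
#' @return data.frame `read_id, seq` of retained reads, with attribute
#'   `stats` (named counts for each stage and the `below_cap` flag).
#' @export
qc_reads <- function(r1, r2, config = nif_config()) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  n <- length(r1$ids)
  if (length(r2$ids) != n) stop("unequal read counts in pair files")
  ids <- character(n); seqs <- character(n)
  n_kept <- 0L; n_merged <- 0L; n_trimmed_ok <- 0L
  for (i in seq_len(n)) {
    m <- merge_pair_cpp(r1$seqs[[i]], as.integer(r1$quals[[i]]),
                        r2$seqs[[i]], as.integer(r2$quals[[i]]),
                        config$merge_max_diffs, config$merge_min_overlap,
                        config$allow_merge_stagger)
    if (!isTRUE(m$merged)) next
    n_merged <- n_merged + 1L
    w <- ee_window_cpp(m$qual, config$max_expected_errors)
    if (w[1] == 0L) next
    len <- w[2] - w[1] + 1L
    if (len < config$min_merged_length) next
    n_trimmed_ok <- n_trimmed_ok + 1L
    if (n_kept < config$reads_cap) {
      n_kept <- n_kept + 1L
      ids[n_kept] <- r1$ids[[i]]
      seqs[n_kept] <- substr(m$seq, w[1], w[2])
    }
  }
  out <- data.frame(read_id = ids[seq_len(n_kept)], seq = seqs[seq_len(n_kept)],
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(n_pairs = n, n_merged = n_merged,
                          n_filtered = n_trimmed_ok,
                          n_retained = nrow(out),
                          below_cap = as.integer(n_trimmed_ok < config$reads_cap))
  out
}

# Translate reads in six frames (vectorized), split at stops, drop short
# fragments; returns data.frame(read_idx, fragment) for batch alignment.
read_fragments <- function(seqs, min_aa) {
  frames <- translate_frames_set(seqs)
  idx <- integer(0); frag <- character(0)
  for (fr in frames) {
    pieces <- strsplit(fr, "*", fixed = TRUE)
    n_p <- lengths(pieces)
    v <- unlist(pieces, use.names = FALSE)
    i <- rep(seq_along(seqs), n_p)
    keep <- nchar(v) >= min_aa
    idx <- c(idx, i[keep]); frag <- c(frag, v[keep])
  }
  ord <- order(idx)
  data.frame(read_idx = idx[ord], fragment = frag[ord],
             stringsAsFactors = FALSE)
}

#' First-stage nitrogenase candidate screen
#'
#' Each read is translated in six frames; frame peptides are split at stop
#' codons and fragments of at least `min_orf_aa` residues are globally
#' aligned against the (small) nitrogenase reference panel. A read is a
#' candidate when any fragment reaches `stage1_min_identity` over at least
#' `stage1_min_cols` non-terminal-gap columns.
#'
#' @param reads data.frame `read_id, seq` ([qc_reads()] output).
#' @param refs Named character vector of nitrogenase reference proteins.
#' @param config A [nif_config()].
#' @return The candidate subset of `reads`, with a `stage1_identity` column.
#' @export
screen_stage1 <- function(reads, refs, config = nif_config()) {
  if (nrow(reads) == 0) {
    reads$stage1_identity <- numeric(0)
    return(reads)
  }
  fr <- read_fragments(reads$seq, config$min_orf_aa)
  best <- rep(NA_real_, nrow(reads))
  if (nrow(fr) > 0) {
    am <- alignment_matrix(fr$fragment, refs, config$gap_open, config$gap_extend)
    ok <- am$identity >= config$stage1_min_identity &
      am$interior_columns >= config$stage1_min_cols
    masked <- am$identity
    masked[!ok] <- NA_real_
    rmax <- suppressWarnings(apply(masked, 1, max, na.rm = TRUE))
    frag_best <- ifelse(is.finite(rmax), rmax, NA_real_)
    for (k in seq_len(nrow(fr))) {
      i <- fr$read_idx[k]
      if (!is.na(frag_best[k]) &&
          (is.na(best[i]) || frag_best[k] > best[i])) best[i] <- frag_best[k]
    }
  }
  out <- reads[!is.na(best), , drop = FALSE]
  out$stage1_identity <- best[!is.na(best)]
  rownames(out) <- NULL
  out
}

#' Assign candidate reads to a gene group against the full panel
#'
#' Candidates are aligned (same translated-fragment scheme) against the full
#' reference panel, nitrogenase references plus decoy homologs. The group of
#' the best-identity reference wins (ties: higher alignment score, then
#' lexicographic reference id); reads whose best identity falls below
#' `stage2_min_identity`, or whose best reference is a decoy, get `none`.
#'
#' @param candidates data.frame `read_id, seq` ([screen_stage1()] output).
#' @param panel Named character vector of reference proteins.
#' @param panel_groups Group per reference: `nifH`, `nifD_like`, `nifK_like`
#'   or `decoy`.
#' @param config A [nif_config()].
#' @return data.frame `read_id, seq, assigned_gene, best_identity, best_ref`.
#' @export
assign_gene <- function(candidates, panel, panel_groups, config = nif_config()) {
  stopifnot(length(panel) == length(panel_groups),
            all(panel_groups %in% c("nifH", "nifD_like", "nifK_like", "decoy")))
  nc <- nrow(candidates)
  out <- data.frame(read_id = candidates$read_id, seq = candidates$seq,
                    assigned_gene = rep("none", nc),
                    best_identity = rep(NA_real_, nc),
                    best_ref = rep(NA_character_, nc),
                    stringsAsFactors = FALSE)
  if (nc == 0) return(out)
  ord <- order(names(panel))  # lexicographic id for deterministic tie-break
  panel <- panel[ord]; panel_groups <- panel_groups[ord]
  fr <- read_fragments(candidates$seq, config$min_orf_aa)
  if (nrow(fr) == 0) return(out)
  am <- alignment_matrix(fr$fragment, panel, config$gap_open, config$gap_extend)
  rows_by_read <- split(seq_len(nrow(fr)), fr$read_idx)
  for (i in seq_len(nrow(candidates))) {
    rows <- rows_by_read[[as.character(i)]]
    if (is.null(rows)) next
    idm <- am$identity[rows, , drop = FALSE]
    scm <- am$score[rows, , drop = FALSE]
    best_id <- max(idm)
    if (best_id < config$stage2_min_identity) next
    cand <- which(idm == best_id, arr.ind = TRUE)
    if (nrow(cand) > 1) {  # tie on identity: higher score, then ref id
      sc <- scm[cand]
      cand <- cand[order(-sc, cand[, 2]), , drop = FALSE]
    }
    ref_j <- cand[1, 2]
    out$best_identity[i] <- best_id
    out$best_ref[i] <- names(panel)[ref_j]
    grp <- panel_groups[ref_j]
    out$assigned_gene[i] <- if (grp == "decoy") "none" else grp
  }
  out
}

# retained-hit mask given identities and the retention rule
retained_hits <- function(identities, best, config) {
  cutoff <- if (config$retention_mode == "multiplicative") {
    config$hit_retention_factor * best
  } else {
    best - (1 - config$hit_retention_factor)
  }
  identities >= cutoff
}

#' Classify a nifH read as true, pseudo or ambiguous
#'
#' The read's translated fragments are aligned to the typed full-length NifH
#' references; hits (identity at least `stage2_min_identity`) within
#' `hit_retention_factor` of the best identity are retained. Verdicts follow
#' the trichotomy: only T1/T2 references retained = `true_nifH`; only T3 =
#' `pseudo_nifH`; both = `ambiguous`.
#'
#' @param read_seq Merged read sequence (DNA string).
#' @param typed_refs Named character vector of full-length NifH proteins.
#' @param ref_types `T1`/`T2`/`T3` per reference.
#' @param config A [nif_config()].
#' @return `list(verdict, retained, best_identity)`; `verdict` is `n/a` (with
#'   a warning) when no reference reaches the hit floor.
#' @export
classify_nifh_read <- function(read_seq, typed_refs, ref_types,
                               config = nif_config()) {
  stopifnot(length(typed_refs) == length(ref_types),
            all(ref_types %in% c("T1", "T2", "T3")))
  fr <- orf_fragments(translate_6frames(read_seq), config$min_orf_aa)
  if (length(fr) == 0) {
    warning("read has no translatable fragment; verdict n/a")
    return(list(verdict = "n/a", retained = character(0),
                best_identity = NA_real_))
  }
  am <- alignment_matrix(fr, typed_refs, config$gap_open, config$gap_extend)
  per_ref <- apply(am$identity, 2, max)
  v <- verdict_from_identities(per_ref, ref_types, config)
  if (v$verdict == "n/a") warning("nifH read with no reference hit; verdict n/a")
  list(verdict = v$verdict, retained = names(typed_refs)[v$retained],
       best_identity = v$best_identity)
}

# verdict from per-reference best identities (shared by the single-read API
# and the batched screen)
verdict_from_identities <- function(per_ref, ref_types, config) {
  hits <- per_ref >= config$stage2_min_identity
  if (!any(hits)) {
    return(list(verdict = "n/a", retained = integer(0),
                best_identity = if (length(per_ref)) max(per_ref) else NA_real_))
  }
  best <- max(per_ref[hits])
  keep <- hits & retained_hits(per_ref, best, config)
  types <- unique(ref_types[keep])
  verdict <- if (all(types %in% c("T1", "T2"))) "true_nifH"
             else if (all(types == "T3")) "pseudo_nifH"
             else "ambiguous"
  list(verdict = verdict, retained = which(keep), best_identity = best)
}

# batched version of classify_nifh_read over many reads (one translation and
# one alignment call)
nifh_verdicts_batch <- function(seqs, typed_refs, ref_types, config) {
  verdict <- rep("n/a", length(seqs))
  if (length(seqs) == 0) return(verdict)
  fr <- read_fragments(seqs, config$min_orf_aa)
  if (nrow(fr) == 0) return(verdict)
  am <- alignment_matrix(fr$fragment, typed_refs, config$gap_open,
                         config$gap_extend)
  rows_by_read <- split(seq_len(nrow(fr)), fr$read_idx)
  for (nm in names(rows_by_read)) {
    rows <- rows_by_read[[nm]]
    per_ref <- apply(am$identity[rows, , drop = FALSE], 2, max)
    verdict[as.integer(nm)] <-
      verdict_from_identities(per_ref, ref_types, config)$verdict
  }
  verdict
}

#' Overestimation factor of nifH abundance
#'
#' Reciprocal of the proportion of nifH reads classified as true:
#' `(true + pseudo + ambiguous) / true`. Undefined (NA, with a message) when
#' no read is classified true.
#'
#' @param verdict_counts Named counts with entries `true_nifH, pseudo_nifH,
#'   ambiguous`.
#' @return The factor (>= 1), or `NA` when undefined.
#' @export
overestimation_factor <- function(verdict_counts) {
  tr <- verdict_counts[["true_nifH"]]
  tot <- tr + verdict_counts[["pseudo_nifH"]] + verdict_counts[["ambiguous"]]
  if (tot == 0) stop("no classified nifH reads")
  if (tr == 0) {
    message("no true-nifH reads: overestimation factor undefined")
    return(NA_real_)
  }
  tot / tr
}

#' Exact Poisson confidence interval
#'
#' Chi-square form of the exact interval for a Poisson count:
#' lower = chisq(alpha/2, 2x)/2 (0 when x = 0),
#' upper = chisq(1 - alpha/2, 2x + 2)/2.
#'
#' @param x Count (non-negative integer).
#' @param level Confidence level.
#' @return `c(lower, upper)`.
#' @export
poisson_ci <- function(x, level = 0.99) {
  stopifnot(x >= 0, level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qchisq(alpha / 2, 2 * x) / 2
  upper <- qchisq(1 - alpha / 2, 2 * x + 2) / 2
  c(lower = lower, upper = upper)
}

#' Gene-length proportionality test for two read counts
#'
#' Tests whether counts of two genes are consistent with proportionality to
#' their full gene lengths: each count gets an exact Poisson CI at `ci_level`,
#' and the pair deviates when the CI rectangle does not intersect the line
#' through the origin with slope `len_b / len_a` in (a, b) space.
#'
#' @param count_a,count_b Read counts.
#' @param len_a,len_b Full gene lengths (bp).
#' @param ci_level Confidence level (default 0.99).
#' @return `list(verdict, ci_a, ci_b, slope)` with verdict `consistent` or
#'   `deviating`.
#' @export
proportionality_test <- function(count_a, count_b, len_a, len_b,
                                 ci_level = 0.99) {
  stopifnot(count_a >= 0, count_b >= 0, len_a > 0, len_b > 0)
  ci_a <- poisson_ci(count_a, ci_level)
  ci_b <- poisson_ci(count_b, ci_level)
  slope <- len_b / len_a
  # the line b = slope * a crosses the rectangle iff these hold
  consistent <- slope * ci_a[["upper"]] >= ci_b[["lower"]] &&
    slope * ci_a[["lower"]] <= ci_b[["upper"]]
  list(verdict = if (consistent) "consistent" else "deviating",
       ci_a = ci_a, ci_b = ci_b, slope = slope)
}

#' Run the full metagenome screen on one sample
#'
#' [qc_reads()] then [screen_stage1()] then [assign_gene()], then
#' [classify_nifh_read()] for every nifH-assigned read, and finally
#' [summarize_sample()].
#'
#' @param r1,r2 Paired FASTQ paths or in-memory reads.
#' @param refs Named character vector of nitrogenase reference proteins
#'   (stage 1 panel).
#' @param ref_groups `nifH`/`nifD_like`/`nifK_like` per reference.
#' @param ref_types `T1`/`T2`/`T3` for the nifH references (named by
#'   reference id), e.g. from the genome census.
#' @param decoys Optional named character vector of decoy homolog proteins
#'   added to the stage-2 panel.
#' @param config A [nif_config()].
#' @param sample_id Sample label.
#' @return `list(summary, per_read, qc_stats)`.
#' @export
screen_metagenome <- function(r1, r2, refs, ref_groups, ref_types,
                              decoys = character(0), config = nif_config(),
                              sample_id = "sample") {
  stopifnot(length(refs) == length(ref_groups))
  reads <- qc_reads(r1, r2, config)
  cand <- screen_stage1(reads, refs, config)
  panel <- c(refs, decoys)
  panel_groups <- c(ref_groups, rep("decoy", length(decoys)))
  assigned <- assign_gene(cand, panel, panel_groups, config)
  nifh_refs <- refs[ref_groups == "nifH"]
  types <- ref_types[names(nifh_refs)]
  verdicts <- rep(NA_character_, nrow(assigned))
  is_h <- which(assigned$assigned_gene == "nifH")
  verdicts[is_h] <- nifh_verdicts_batch(assigned$seq[is_h], nifh_refs, types,
                                        config)
  assigned$verdict <- verdicts
  summary <- summarize_sample(assigned, config, sample_id)
  list(summary = summary, per_read = assigned, qc_stats = attr(reads, "stats"))
}

#' Summarize a screened sample
#'
#' Tabulates assigned-gene counts, true/pseudo/ambiguous proportions, the
#' overestimation factor and the three pairwise gene-length proportionality
#' verdicts.
#'
#' @param assigned Per-read data.frame from [screen_metagenome()] (columns
#'   `assigned_gene` and, for nifH reads, `verdict`).
#' @param config A [nif_config()].
#' @param sample_id Sample label.
#' @return One-row data.frame.
#' @export
summarize_sample <- function(assigned, config = nif_config(),
                             sample_id = "sample") {
  n_H <- sum(assigned$assigned_gene == "nifH")
  n_D <- sum(assigned$assigned_gene == "nifD_like")
  n_K <- sum(assigned$assigned_gene == "nifK_like")
  vc <- c(true_nifH = sum(assigned$verdict == "true_nifH", na.rm = TRUE),
          pseudo_nifH = sum(assigned$verdict == "pseudo_nifH", na.rm = TRUE),
          ambiguous = sum(assigned$verdict == "ambiguous", na.rm = TRUE))
  n_classified <- sum(vc)
  props <- if (n_classified > 0) vc / n_classified else rep(NA_real_, 3)
  factor <- if (n_classified > 0 && vc[["true_nifH"]] > 0) {
    overestimation_factor(vc)
  } else NA_real_
  pt <- function(a, b, la, lb) {
    proportionality_test(a, b, la, lb, config$ci_level)$verdict
  }
  data.frame(sample_id = sample_id,
             n_nifH = n_H, n_nifD_like = n_D, n_nifK_like = n_K,
             n_true = vc[["true_nifH"]], n_pseudo = vc[["pseudo_nifH"]],
             n_ambiguous = vc[["ambiguous"]],
             prop_true = props[[1]], prop_pseudo = props[[2]],
             prop_ambiguous = props[[3]],
             overestimation_factor = factor,
             prop_D_vs_H = pt(n_D, n_H, config$gene_length_D, config$gene_length_H),
             prop_K_vs_H = pt(n_K, n_H, config$gene_length_K, config$gene_length_H),
             prop_D_vs_K = pt(n_D, n_K, config$gene_length_D, config$gene_length_K),
             row.names = NULL, stringsAsFactors = FALSE)
}
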