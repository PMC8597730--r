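# Confusability of short NifH fragments: can 40-100 aa pieces of true (T1/2)
# and pseudo (T3) NifH be told apart? Two instruments: (1) random fragments of
# clustered full-length representatives mapped back to all representatives at
# an identity threshold; (2) similarity networks over fixed MSA windows.

#' Greedy incremental sequence clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length (descending;
#' ties by id) and each joins the first existing cluster whose representative
#' it matches at `threshold` or higher global identity, otherwise it founds a
#' new cluster. Intended to be run separately per label.
#'
#' @param seqs Named character vector of protein sequences.
#' @param threshold Identity threshold (default 0.95).
#' @param config A [nif_config()] (gap parameters).
#' @return data.frame `rep_id, size, members` (members `;`-separated), in
#'   founding order.
#' @export
cluster_greedy <- function(seqs, threshold = 0.95, config = nif_config()) {
  if (length(seqs) == 0) {
    return(data.frame(rep_id = character(0), size = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (id in names(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (global_identity(seqs[[id]], seqs[[reps[k]]],
                          config$gap_open, config$gap_extend) >= threshold) {
        members[[k]] <- c(members[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  data.frame(rep_id = reps, size = lengths(members),
             members = vapply(members, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Random fragments of a full-length sequence
#'
#' Draws `n_per_length` fragments at uniformly random start positions for each
#' requested length; lengths exceeding the sequence are skipped with a
#' warning. Deterministic under `seed`.
#'
#' @param seq Protein sequence (single string).
#' @param seq_id Identifier used to build fragment ids.
#' @param lengths Fragment lengths in aa.
#' @param n_per_length Fragments per length.
#' @param seed Integer seed.
#' @return data.frame `query_id, source_id, length, start, sequence`.
#' @export
sample_subsequences <- function(seq, seq_id = "seq",
                                lengths = c(40L, 60L, 80L, 100L),
                                n_per_length = 10L, seed = 1L) {
  stopifnot(all(lengths > 0))
  L <- nchar(seq)
  usable <- lengths[lengths <= L]
  if (length(usable) < length(lengths)) {
    warning(sprintf("%s: skipping fragment length(s) %s > sequence length %d",
                    seq_id, paste(setdiff(lengths, usable), collapse = ", "), L))
  }
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(usable, function(len) {
      starts <- sample.int(L - len + 1L, n_per_length, replace = TRUE)
      data.frame(query_id = sprintf("%s|L%d|%02d", seq_id, len, seq_len(n_per_length)),
                 source_id = seq_id, length = len, start = starts,
                 sequence = substr(rep(seq, n_per_length), starts, starts + len - 1L),
                 stringsAsFactors = FALSE)
    }))
  })
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), source_id = character(0),
                      length = integer(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Map partial sequences onto full-length references
#'
#' Every query is globally aligned to every reference; a reference is a hit
#' when identity (terminal gaps excluded from the denominator, so short
#' queries are scored over their aligned span) reaches `threshold`. Verdicts:
#' `incorrect` when any hit carries the opposite label, `unmapped` when there
#' is no hit at all, `correct` otherwise.
#'
#' @param queries data.frame with `query_id, sequence` and an `origin` column
#'   (`T12`/`T3`), e.g. [sample_subsequences()] output plus labels.
#' @param references Named character vector of full-length sequences.
#' @param ref_labels Labels (`T12`/`T3`) parallel to `references`.
#' @param threshold Identity threshold.
#' @param config A [nif_config()].
#' @param identity Optional precomputed identity matrix
#'   (queries x references) to avoid realigning.
#' @return data.frame `query_id, origin, length, n_hits, n_opposite, verdict,
#'   threshold`.
#' @export
map_partials <- function(queries, references, ref_labels, threshold,
                         config = nif_config(), identity = NULL) {
  stopifnot(length(references) == length(ref_labels),
            all(c("query_id", "sequence", "origin") %in% names(queries)))
  if (is.null(identity)) {
    identity <- alignment_matrix(setNames(queries$sequence, queries$query_id),
                                 references, config$gap_open,
                                 config$gap_extend)$identity
  }
  hits <- identity >= threshold
  n_hits <- rowSums(hits)
  n_opp <- vapply(seq_len(nrow(queries)), function(i) {
    sum(hits[i, ] & ref_labels != queries$origin[i])
  }, numeric(1))
  verdict <- ifelse(n_hits == 0, "unmapped",
                    ifelse(n_opp > 0, "incorrect", "correct"))
  data.frame(query_id = queries$query_id, origin = queries$origin,
             length = if ("length" %in% names(queries)) queries$length
                      else nchar(queries$sequence),
             n_hits = as.integer(n_hits), n_opposite = as.integer(n_opp),
             verdict = verdict, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Incorrect-mapping rate by fragment length and threshold
#'
#' `incorrect / (correct + incorrect)` per (length, threshold) cell; unmapped
#' queries are excluded from the denominator and reported separately. Cells
#' with no mapped query get `NA`, not zero.
#'
#' @param results data.frame of [map_partials()] output (possibly several
#'   thresholds rbind-ed together).
#' @return data.frame `length, threshold, n_mapped, n_incorrect, n_unmapped,
#'   rate`.
#' @export
incorrect_mapping_rate <- function(results) {
  cells <- unique(results[, c("length", "threshold")])
  cells <- cells[order(cells$length, cells$threshold), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$length == cells$length[i] &
                   results$threshold == cells$threshold[i], ]
    mapped <- sum(sub$verdict != "unmapped")
    inc <- sum(sub$verdict == "incorrect")
    data.frame(length = cells$length[i], threshold = cells$threshold[i],
               n_mapped = mapped, n_incorrect = inc,
               n_unmapped = sum(sub$verdict == "unmapped"),
               rate = if (mapped > 0) inc / mapped else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full fragment-mapping experiment on a labeled protein family
#'
#' Clusters each label separately at `config$cluster_identity`, samples
#' fragments from every representative (`config$subseq_lengths` x
#' `config$subseqs_per_length`), aligns all fragments to all representatives
#' once, and tabulates incorrect-mapping rates at every
#' `config$identity_thresholds`.
#'
#' @param family data.frame `seq_id, sequence, label` with labels `T12`/`T3`
#'   (e.g. [gen_protein_family()] output).
#' @param config A [nif_config()].
#' @param seed Integer seed for fragment sampling.
#' @return `list(rates, results, representatives)`.
#' @export
partial_mapping_experiment <- function(family, config = nif_config(), seed = 1L) {
  stopifnot(all(c("seq_id", "sequence", "label") %in% names(family)))
  reps_by_label <- lapply(split(family, family$label), function(sub) {
    cl <- cluster_greedy(setNames(sub$sequence, sub$seq_id),
                         config$cluster_identity, config)
    cl$rep_id
  })
  rep_ids <- unlist(reps_by_label, use.names = FALSE)
  refs <- setNames(family$sequence[match(rep_ids, family$seq_id)], rep_ids)
  ref_labels <- family$label[match(rep_ids, family$seq_id)]
  queries <- do.call(rbind, lapply(seq_along(rep_ids), function(k) {
    q <- sample_subsequences(refs[[k]], rep_ids[k], config$subseq_lengths,
                             config$subseqs_per_length, seed = seed + k)
    q$origin <- ref_labels[k]
    q
  }))
  identity <- alignment_matrix(setNames(queries$sequence, queries$query_id),
                               refs, config$gap_open, config$gap_extend)$identity
  results <- do.call(rbind, lapply(config$identity_thresholds, function(th) {
    map_partials(queries, refs, ref_labels, th, config, identity = identity)
  }))
  list(rates = incorrect_mapping_rate(results), results = results,
       representatives = data.frame(rep_id = rep_ids, label = ref_labels,
                                    stringsAsFactors = FALSE))
}

#' Extract degapped subsequences from MSA windows
#'
#' Cuts fixed windows out of a protein multiple sequence alignment, removes
#' gap characters per row, and keeps rows with at least
#' `config$min_window_residues` residues (gappier rows are excluded and
#' counted). Windows extending past the alignment are skipped with a warning.
#'
#' @param msa Named character vector of aligned (equal-length) rows, or an
#'   `AAStringSet`.
#' @param config A [nif_config()] (`msa_window`, `msa_starts`,
#'   `min_window_residues`).
#' @return Named list (one element per window start) of data.frames
#'   `seq_id, subseq, n_residues`, with attribute `n_excluded` per window.
#' @export
msa_windows <- function(msa, config = nif_config()) {
  msa <- setNames(as.character(msa), names(msa))
  stopifnot(length(msa) > 0, !is.null(names(msa)))
  width <- unique(nchar(msa))
  if (length(width) != 1) stop("MSA rows must have equal length")
  out <- list()
  for (s in config$msa_starts) {
    e <- s + config$msa_window - 1L
    if (e > width) {
      warning(sprintf("window %d-%d extends past alignment width %d; skipped",
                      s, e, width))
      next
    }
    sub <- gsub("-", "", substr(msa, s, e), fixed = TRUE)
    n_res <- nchar(sub)
    keep <- n_res >= config$min_window_residues
    df <- data.frame(seq_id = names(msa)[keep], subseq = unname(sub[keep]),
                     n_residues = unname(n_res[keep]), stringsAsFactors = FALSE)
    attr(df, "n_excluded") <- sum(!keep)
    out[[sprintf("%d-%d", s, e)]] <- df
  }
  out
}

#' Similarity-network classification of window subsequences
#'
#' Builds the all-pairs identity network over one window's subsequences
#' (edge iff identity at or above `threshold`) and classifies each node as
#' `confusing` when it is directly connected to a node of the opposite label,
#' `distinct` otherwise.
#'
#' @param subseqs data.frame `seq_id, subseq` (one MSA window).
#' @param labels Labels (`T12`/`T3`) parallel to rows of `subseqs`.
#' @param threshold Identity threshold.
#' @param config A [nif_config()].
#' @return `list(nodes, edges, proportions)`: per-node class, the edge list,
#'   and the per-label proportion of confusing nodes.
#' @export
window_confusion <- function(subseqs, labels, threshold, config = nif_config()) {
  stopifnot(nrow(subseqs) == length(labels))
  if (length(unique(labels)) < 2) {
    warning("single-label input: confusing proportions defined as 0")
  }
  seqs <- setNames(subseqs$subseq, subseqs$seq_id)
  idm <- alignment_matrix(seqs, seqs, config$gap_open, config$gap_extend)$identity
  # use the canonical orientation of each pair (as global_identity does) so
  # the network is exactly symmetric even on knife-edge traceback ties
  canon <- outer(unname(seqs), unname(seqs), `<=`)
  idm <- ifelse(canon, idm, t(idm))
  adj <- idm >= threshold
  diag(adj) <- FALSE
  confusing <- vapply(seq_along(seqs), function(i) {
    any(adj[i, ] & labels != labels[i])
  }, logical(1))
  nodes <- data.frame(seq_id = names(seqs), label = labels,
                      class = ifelse(confusing, "confusing", "distinct"),
                      stringsAsFactors = FALSE)
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = names(seqs)[ij[, 1]], to = names(seqs)[ij[, 2]],
                      identity = idm[ij], stringsAsFactors = FALSE)
  proportions <- vapply(sort(unique(labels)), function(lb) {
    n <- sum(labels == lb)
    if (n == 0) 0 else sum(confusing[labels == lb]) / n
  }, numeric(1))
  list(nodes = nodes, edges = edges, proportions = proportions)
}

#' MSA-window confusability profile
#'
#' Runs [msa_windows()] and [window_confusion()] at each configured identity
#' threshold, returning the per-window, per-label proportions of confusing
#' sequences.
#'
#' @param msa Aligned rows (named character vector or `AAStringSet`).
#' @param labels Named label vector (`T12`/`T3`) covering all MSA row names.
#' @param config A [nif_config()].
#' @return data.frame `window, threshold, label, n, prop_confusing,
#'   n_excluded`.
#' @export
window_confusion_profile <- function(msa, labels, config = nif_config()) {
  wins <- msa_windows(msa, config)
  out <- do.call(rbind, lapply(names(wins), function(w) {
    df <- wins[[w]]
    if (nrow(df) == 0) return(NULL)
    lb <- labels[df$seq_id]
    do.call(rbind, lapply(config$identity_thresholds, function(th) {
      wc <- window_confusion(df, lb, th, config)
      data.frame(window = w, threshold = th,
                 label = names(wc$proportions),
                 n = as.integer(table(lb)[names(wc$proportions)]),
                 prop_confusing = unname(wc$proportions),
                 n_excluded = attr(df, "n_excluded"),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
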