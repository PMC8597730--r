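#' @importFrom Biostrings readAAStringSet readDNAStringSet writeXStringSet
#'   DNAStringSet AAStringSet DNAString reverseComplement translate subseq
#'   quality PhredQuality QualityScaledDNAStringSet
NULL

# BLOSUM62 with X (and any unknown residue) made score-neutral: fragments may
# carry X from ambiguous codons, and these columns should neither reward nor
# penalize.
.subst_env <- new.env(parent = emptyenv())

nif_scoring_matrix <- function() {
  if (is.null(.subst_env$blosum62x)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    storage.mode(m) <- "integer"
    .subst_env$blosum62x <- m
  }
  .subst_env$blosum62x
}

check_protein <- function(x, arg = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("'%s' must be a single non-empty protein sequence", arg))
  }
  toupper(x)
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Exact global alignment under BLOSUM62 with affine gap costs (a gap of
#' length L costs `gap_open + L * gap_extend`). Traceback tie-breaking is
#' deterministic: diagonal, then up (gap in `b`), then left. Identity is the
#' fraction of matching columns among all alignment columns excluding terminal
#' gap runs (internal gap columns count in the denominator), so a short query
#' aligned inside a long reference is scored over its aligned span only.
#'
#' @param a,b Protein sequences (single strings). `X` is tolerated and scored
#'   neutrally (0 against everything).
#' @param gap_open,gap_extend Affine gap parameters (negative).
#' @param scoring Integer substitution matrix with single-letter dimnames;
#'   defaults to BLOSUM62 with X made neutral.
#' @return A list of class `nif_alignment`: `aligned_a`, `aligned_b`, `score`,
#'   `identity`, `columns`, `interior_columns`, `matches`.
#' @examples
#' aln <- needleman_wunsch("MKRIAFYGKGGIGKST", "MKRIAFYGKGGIGKSA")
#' aln$identity
#' @export
needleman_wunsch <- function(a, b, gap_open = -11L, gap_extend = -1L,
                             scoring = nif_scoring_matrix()) {
  a <- check_protein(a, "a")
  b <- check_protein(b, "b")
  # canonical pair order so that tie-breaking (and hence identity) is exactly
  # symmetric in the arguments; the alignment is transposed back afterwards
  swapped <- a > b
  out <- if (swapped) {
    nw_align_cpp(b, a, scoring, as.integer(gap_open), as.integer(gap_extend))
  } else {
    nw_align_cpp(a, b, scoring, as.integer(gap_open), as.integer(gap_extend))
  }
  if (swapped) {
    out[c("aligned_a", "aligned_b")] <- out[c("aligned_b", "aligned_a")]
  }
  structure(out, class = "nif_alignment")
}

#' @export
print.nif_alignment <- function(x, ...) {
  cat(sprintf("<nif_alignment> score %d, identity %.3f over %d columns\n",
              x$score, x$identity, x$interior_columns))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Global alignment identity between two protein sequences
#'
#' Identity of the optimal global alignment, with terminal gap columns
#' excluded from the denominator (see [needleman_wunsch()]). Symmetric in its
#' arguments.
#'
#' @inheritParams needleman_wunsch
#' @return Identity fraction in \[0, 1\].
#' @export
global_identity <- function(a, b, gap_open = -11L, gap_extend = -1L,
                            scoring = nif_scoring_matrix()) {
  needleman_wunsch(a, b, gap_open, gap_extend, scoring)$identity
}

#' All-vs-all global alignment statistics
#'
#' Aligns every query against every reference and returns identity, score and
#' non-terminal-gap column-count matrices. This is the batch primitive behind
#' fragment mapping, similarity networks and the metagenome screen.
#'
#' @param queries,refs Character vectors of protein sequences (names kept as
#'   dimnames).
#' @inheritParams needleman_wunsch
#' @return List of matrices `identity`, `score`, `interior_columns`
#'   (queries in rows, references in columns).
#' @export
alignment_matrix <- function(queries, refs, gap_open = -11L, gap_extend = -1L,
                             scoring = nif_scoring_matrix()) {
  stopifnot(length(queries) > 0, length(refs) > 0)
  q <- toupper(as.character(queries))
  r <- toupper(as.character(refs))
  if (any(!nzchar(q)) || any(!nzchar(r))) stop("empty sequence in input")
  out <- nw_batch_cpp(q, r, scoring, as.integer(gap_open), as.integer(gap_extend))
  dn <- list(names(queries), names(refs))
  dimnames(out$identity) <- dn
  dimnames(out$score) <- dn
  dimnames(out$interior_columns) <- dn
  out
}

#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames under the standard
#' genetic code. Stop codons are emitted as `*`; codons containing `N`
#' translate to `X`. Frames `-1..-3` read the reverse complement.
#'
#' @param dna A DNA sequence (single string over A/C/G/T/N).
#' @return Named character vector of six peptides
#'   (`F1,F2,F3,R1,R2,R3`).
#' @export
translate_6frames <- function(dna) {
  stopifnot(length(dna) == 1L, !is.na(dna))
  fr <- translate_frames_set(dna)
  setNames(vapply(fr, identity, character(1)), names(fr))
}

# Vectorized six-frame translation of many sequences at once (one Biostrings
# translate call per frame, not per read). Returns a list of six character
# vectors F1,F2,F3,R1,R2,R3, each parallel to `seqs`.
translate_frames_set <- function(seqs) {
  seqs <- toupper(seqs)
  if (!all(grepl("^[ACGTN]*$", seqs))) stop("DNA must be over A/C/G/T/N")
  fwd <- Biostrings::DNAStringSet(seqs)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (dir in c("F", "R")) {
    set <- if (dir == "F") fwd else rev
    for (off in 0:2) {
      w <- Biostrings::width(set) - off
      w <- pmax(w - w %% 3L, 0L)
      sub <- Biostrings::subseq(set, start = off + 1L, width = w)
      out[[paste0(dir, off + 1L)]] <-
        as.character(suppressWarnings(Biostrings::translate(sub,
                                                            if.fuzzy.codon = "X")))
    }
  }
  out
}

# Split peptides at stop codons, keep fragments >= min_aa.
orf_fragments <- function(peptides, min_aa = 20L) {
  frags <- unlist(strsplit(peptides, "*", fixed = TRUE), use.names = FALSE)
  frags[nchar(frags) >= min_aa]
}

#' Merge a read pair by overlap
#'
#' Merges a forward/reverse read pair USEARCH-style: `r2` is
#' reverse-complemented and slid along `r1`. Among qualifying overlaps (at
#' least `merge_min_overlap` bases, at most `merge_max_diffs` mismatches) the
#' one with the fewest mismatches wins, ties broken by longest overlap; with
#' no qualifying overlap the pair is rejected.
#' Staggered (read-through) overlaps are allowed when configured, with
#' overhangs trimmed. At agreeing overlap positions the merged quality is the
#' higher Phred score; at conflicts the higher-quality base (and its quality)
#' is kept.
#'
#' @param r1,r2 Reads as `list(seq = <string>, qual = <integer Phred vector>)`;
#'   `r2` in sequencing orientation.
#' @param config A [nif_config()].
#' @return On success `list(merged = TRUE, seq, qual, overlap, diffs, offset)`;
#'   otherwise `list(merged = FALSE)` (a rejection, not an error).
#' @export
merge_pairs <- function(r1, r2, config = nif_config()) {
  stopifnot(nzchar(r1$seq), nzchar(r2$seq),
            nchar(r1$seq) == length(r1$qual),
            nchar(r2$seq) == length(r2$qual))
  merge_pair_cpp(toupper(r1$seq), as.integer(r1$qual),
                 toupper(r2$seq), as.integer(r2$qual),
                 config$merge_max_diffs, config$merge_min_overlap,
                 config$allow_merge_stagger)
}

#' Expected-error trimming
#'
#' Returns the longest contiguous window of a read whose summed per-base error
#' probability `p = 10^(-Q/10)` is strictly below `max_ee` (leftmost window on
#' ties; possibly empty).
#'
#' @param read `list(seq, qual)` as in [merge_pairs()].
#' @param max_ee Expected-error ceiling (strict); default 0.5.
#' @return `list(seq, qual, start, end)`; `start = 0`, zero-length `seq` when
#'   no base qualifies.
#' @export
expected_error_trim <- function(read, max_ee = 0.5) {
  stopifnot(nchar(read$seq) == length(read$qual))
  w <- ee_window_cpp(as.integer(read$qual), max_ee)
  if (w[1] == 0L) {
    return(list(seq = "", qual = integer(0), start = 0L, end = -1L))
  }
  list(seq = substr(read$seq, w[1], w[2]),
       qual = read$qual[w[1]:w[2]],
       start = w[1], end = w[2])
}

#' Reverse complement of a DNA string
#' @param dna DNA sequence (single string).
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(dna) revcomp_cpp(toupper(dna))
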