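# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-formulations (exhaustive enumeration, quadratic
# scans, coordinate counting) kept separate from the package's own
# implementations.

# Exhaustive affine-gap global alignment score by recursive enumeration of
# every monotone alignment path (no memoization): feasible for short
# sequences only.
oracle_align_enum <- function(a, b, sub, open = -11, ext = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= n) {
      cost <- ext + if (identical(last, "U")) 0 else open
      best <- max(best, cost + rec(i + 1L, j, "U"))
    }
    if (j <= m) {
      cost <- ext + if (identical(last, "L")) 0 else open
      best <- max(best, cost + rec(i, j + 1L, "L"))
    }
    best
  }
  rec(1L, 1L, "S")
}

# Quadratic oracle for expected-error trimming: scan all substrings, return
# c(start, end) of the longest (leftmost on ties) with sum(p) strictly below
# max_ee, or c(0, -1).
oracle_ee_trim <- function(qual, max_ee = 0.5) {
  p <- 10^(-qual / 10)
  n <- length(qual)
  best <- c(0L, -1L); best_len <- 0L
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + p[j]
      if (s < max_ee && (j - i + 1L) > best_len) {
        best <- c(i, j); best_len <- j - i + 1L
      }
    }
  }
  best
}

# Brute-force nifH typing by direct coordinate counting: for every
# nifH x D/K-like pair on the same replicon and strand, the same-strand
# offset is 1 + the number of same-strand CDSs strictly between them.
oracle_classify_nifh <- function(annotation, radius = 10L) {
  r <- annotation$records
  role <- pseudonif:::nif_role(r$gene_symbol, r$product)
  h_idx <- which(!is.na(role) & role == "H")
  dk_idx <- which(!is.na(role) & role %in% c("D", "K"))
  if (length(h_idx) == 0) {
    return(data.frame(locus_tag = character(0), nifh_type = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(h_idx, function(i) {
    nb <- integer(0)
    for (j in dk_idx) {
      if (r$replicon_id[j] != r$replicon_id[i] ||
          r$strand[j] != r$strand[i]) next
      lo <- min(r$start[i], r$start[j]); hi <- max(r$start[i], r$start[j])
      between <- sum(r$replicon_id == r$replicon_id[i] &
                     r$strand == r$strand[i] &
                     r$start > lo & r$start < hi)
      if (between + 1L <= radius) nb <- c(nb, j)
    }
    gh <- setdiff(dk_idx, nb)
    type <- if (length(nb)) "T1" else if (length(gh)) "T2" else "T3"
    data.frame(locus_tag = r$locus_tag[i], nifh_type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Independent per-node "confusing" recomputation for a similarity network:
# pairwise global identities one call at a time, direct double loop.
oracle_confusing <- function(seqs, labels, threshold) {
  n <- length(seqs)
  conf <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || labels[i] == labels[j]) next
      if (global_identity(seqs[[i]], seqs[[j]]) >= threshold) {
        conf[i] <- TRUE
        break
      }
    }
  }
  conf
}
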