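# Synthetic NifH protein families (two diverged clades standing for true
# T1/2 and pseudo T3 NifH) and paired-end metagenomes drawn from them with
# known origin labels.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Specification of a two-clade synthetic protein family
#'
#' Sequences are generated by mutating a random root along a two-clade star
#' topology: each clade ancestor diverges from the root and each sequence
#' diverges from its clade ancestor, so that expected pairwise divergence is
#' `within_clade_divergence` inside a clade and about
#' `between_clade_divergence` across clades.
#'
#' @param n_true,n_pseudo Number of T1/2- and T3-labeled sequences.
#' @param root_length Root sequence length in residues (default 300; must be
#'   at least 120 so that 100-aa fragments exist).
#' @param within_clade_divergence,between_clade_divergence Expected
#'   substitutions per site (between must be at least within).
#' @param seed Integer seed.
#' @return A `sim_family_spec` list.
#' @export
sim_family_spec <- function(n_true = 20L, n_pseudo = 20L, root_length = 300L,
                            within_clade_divergence = 0.05,
                            between_clade_divergence = 0.10, seed = 1L) {
  stopifnot(n_true >= 0, n_pseudo >= 0, root_length >= 120,
            within_clade_divergence >= 0,
            between_clade_divergence >= within_clade_divergence)
  structure(list(n_true = as.integer(n_true), n_pseudo = as.integer(n_pseudo),
                 root_length = as.integer(root_length),
                 within_clade_divergence = within_clade_divergence,
                 between_clade_divergence = between_clade_divergence,
                 seed = as.integer(seed)),
            class = "sim_family_spec")
}

# substitute each site with probability 1 - exp(-d), to a uniform other residue
mutate_protein <- function(chars, d) {
  p <- 1 - exp(-d)
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1),
                         character(1))
  }
  chars
}

#' Generate a two-clade labeled protein family
#'
#' @param spec A [sim_family_spec()].
#' @return data.frame `seq_id, sequence, label` with labels `T12` and `T3`.
#'   With a fixed spec the output is byte-identical across runs. When the
#'   clades are set to diverge, the generated set is checked empirically:
#'   mean within-clade identity must exceed mean between-clade identity
#'   (warning otherwise).
#' @export
gen_protein_family <- function(spec) {
  stopifnot(inherits(spec, "sim_family_spec"))
  out <- withr::with_seed(spec$seed, {
    root <- sample(AA20, spec$root_length, replace = TRUE)
    # leaf branches carry within/2; ancestor branches the remainder so that
    # cross-clade pairs accumulate ~between substitutions per site
    anc_d <- max(0, spec$between_clade_divergence - spec$within_clade_divergence) / 2
    leaf_d <- spec$within_clade_divergence / 2
    anc1 <- mutate_protein(root, anc_d)
    anc2 <- mutate_protein(root, anc_d)
    mk <- function(anc, n, prefix) {
      if (n == 0) return(NULL)
      data.frame(seq_id = sprintf("%s_%03d", prefix, seq_len(n)),
                 sequence = vapply(seq_len(n), function(i) {
                   paste(mutate_protein(anc, leaf_d), collapse = "")
                 }, character(1)),
                 label = if (prefix == "T12") "T12" else "T3",
                 stringsAsFactors = FALSE)
    }
    rbind(mk(anc1, spec$n_true, "T12"), mk(anc2, spec$n_pseudo, "T3"))
  })
  rownames(out) <- NULL
  if (spec$between_clade_divergence > spec$within_clade_divergence &&
      spec$n_true > 1 && spec$n_pseudo > 1) {
    m <- do.call(rbind, strsplit(out$sequence, ""))
    idm <- function(i, j) mean(m[i, ] == m[j, ])
    t12 <- which(out$label == "T12"); t3 <- which(out$label == "T3")
    within <- c(utils::combn(t12, 2, function(p) idm(p[1], p[2])),
                utils::combn(t3, 2, function(p) idm(p[1], p[2])))
    between <- outer(t12, t3, Vectorize(idm))
    if (mean(within) <= mean(between)) {
      warning("generated family: mean within-clade identity does not exceed between-clade identity")
    }
  }
  out
}

# codon lists per amino acid, standard genetic code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Back-translate a protein with uniformly random synonymous codons
#'
#' @param protein Protein sequence (single string over the 20 residues).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein) {
  tab <- codon_table()
  aa <- strsplit(toupper(protein), "")[[1]]
  bad <- setdiff(aa, names(tab))
  if (length(bad)) stop(sprintf("cannot back-translate residue(s): %s",
                                paste(unique(bad), collapse = ", ")))
  paste(vapply(aa, function(a) {
    cs <- tab[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

SIM_READ_CLASSES <- c("true_nifH", "pseudo_nifH", "nifD", "nifK", "background")

#' Specification of a synthetic paired-end metagenome
#'
#' @param n_read_pairs Number of read pairs.
#' @param read_length Read length in bases.
#' @param mix Named proportions over `true_nifH, pseudo_nifH, nifD, nifK,
#'   background`, summing to 1.
#' @param quality_mean,quality_decay Mean Phred score at the first cycle and
#'   linear per-cycle decay.
#' @param insert_length Insert length in bases (must be at least
#'   `read_length`).
#' @param seed Integer seed.
#' @return A `sim_metagenome_spec` list.
#' @export
sim_metagenome_spec <- function(n_read_pairs = 10000L, read_length = 150L,
                                mix = c(true_nifH = 0.2, pseudo_nifH = 0.1,
                                        nifD = 0, nifK = 0, background = 0.7),
                                quality_mean = 35, quality_decay = 0.02,
                                insert_length = 250L, seed = 1L) {
  stopifnot(n_read_pairs >= 1, read_length >= 1)
  if (!setequal(names(mix), SIM_READ_CLASSES)) {
    stop(sprintf("mix must be named over: %s",
                 paste(SIM_READ_CLASSES, collapse = ", ")))
  }
  mix <- mix[SIM_READ_CLASSES]
  if (abs(sum(mix) - 1) > 1e-9) stop("mix proportions must sum to 1")
  if (any(mix < 0)) stop("mix proportions must be non-negative")
  if (read_length > insert_length) {
    stop("read_length must not exceed insert_length")
  }
  structure(list(n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length), mix = mix,
                 quality_mean = quality_mean, quality_decay = quality_decay,
                 insert_length = as.integer(insert_length),
                 seed = as.integer(seed)),
            class = "sim_metagenome_spec")
}

#' Generate a paired-end metagenome with known read origins
#'
#' Source proteins are back-translated with uniformly random synonymous
#' codons, fragmented at uniform random positions into inserts, and
#' "sequenced" from both ends with substitution errors drawn from the
#' per-cycle quality model (error probability `10^(-Q/10)`; no indels,
#' emulating Illumina chemistry). Background read pairs come from random DNA.
#' Every pair's origin class and source sequence are recorded in a truth
#' table.
#'
#' @param spec A [sim_metagenome_spec()].
#' @param sources Named list with character vectors of source proteins for
#'   each nonzero non-background mix class (`true_nifH, pseudo_nifH, nifD,
#'   nifK`).
#' @param dir Optional output directory (writes `reads_R1.fastq`,
#'   `reads_R2.fastq`, `truth_reads.tsv`, `manifest.json`).
#' @return `list(r1, r2, truth)` with `r1`/`r2` as `list(ids, seqs, quals)`.
#' @export
gen_metagenome <- function(spec, sources = list(), dir = NULL) {
  stopifnot(inherits(spec, "sim_metagenome_spec"))
  nonzero <- names(spec$mix)[spec$mix > 0 & names(spec$mix) != "background"]
  for (cls in nonzero) {
    if (is.null(sources[[cls]]) || length(sources[[cls]]) == 0) {
      stop(sprintf("mix class '%s' is nonzero but has no source sequences", cls))
    }
  }
  out <- withr::with_seed(spec$seed, {
    # one DNA realization per source protein
    dna_pool <- lapply(sources[nonzero], function(prots) {
      vapply(prots, back_translate, character(1), USE.NAMES = TRUE)
    })
    for (cls in nonzero) {
      if (any(nchar(dna_pool[[cls]]) < spec$insert_length)) {
        stop(sprintf("source in '%s' shorter than insert_length after back-translation", cls))
      }
    }
    n <- spec$n_read_pairs
    rl <- spec$read_length
    classes <- sample(SIM_READ_CLASSES, n, replace = TRUE, prob = spec$mix)
    qual <- pmin(41L, pmax(2L, as.integer(round(
      spec$quality_mean - spec$quality_decay * (seq_len(rl) - 1L)))))
    perr <- 10^(-qual / 10)
    sequencer <- function(template) {
      chars <- strsplit(template, "")[[1]]
      hit <- runif(length(chars)) < perr
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      paste(chars, collapse = "")
    }
    ids <- sprintf("read_%06d", seq_len(n))
    seqs1 <- character(n); seqs2 <- character(n)
    src_ids <- character(n)
    for (i in seq_len(n)) {
      cls <- classes[i]
      if (cls == "background") {
        insert <- paste(sample(c("A", "C", "G", "T"), spec$insert_length,
                               replace = TRUE), collapse = "")
        src_ids[i] <- "random"
      } else {
        pool <- dna_pool[[cls]]
        j <- sample.int(length(pool), 1)
        src_ids[i] <- names(pool)[j]
        start <- sample.int(nchar(pool[[j]]) - spec$insert_length + 1L, 1)
        insert <- substr(pool[[j]], start, start + spec$insert_length - 1L)
      }
      seqs1[i] <- sequencer(substr(insert, 1L, rl))
      seqs2[i] <- sequencer(revcomp_cpp(
        substr(insert, spec$insert_length - rl + 1L, spec$insert_length)))
    }
    quals <- rep(list(qual), n)
    list(r1 = list(ids = ids, seqs = seqs1, quals = quals),
         r2 = list(ids = ids, seqs = seqs2, quals = quals),
         truth = data.frame(read_id = ids, class = classes,
                            source_id = src_ids, stringsAsFactors = FALSE))
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(out$r1$ids, out$r1$seqs, out$r1$quals,
                file.path(dir, "reads_R1.fastq"))
    write_fastq(out$r2$ids, out$r2$seqs, out$r2$quals,
                file.path(dir, "reads_R2.fastq"))
    write_tsv_commented(out$truth, file.path(dir, "truth_reads.tsv"))
    manifest <- list(generator = "gen_metagenome", seed = spec$seed,
                     n_read_pairs = spec$n_read_pairs,
                     read_length = spec$read_length,
                     insert_length = spec$insert_length,
                     mix = as.list(spec$mix))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
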