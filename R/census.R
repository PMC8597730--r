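# Genome census: nitrogenase copy counts, copy-balance categories, and
# T1/T2/T3 typing of every nifH CDS.
#
# T1: a nifD/K-like gene lies within `neighborhood_radius` positions of nifH
#     in the ordered list of same-strand CDSs on the same replicon.
# T2: no such neighbor, but a D/K-like gene exists elsewhere on the genome
#     (any strand, any replicon, plasmids included).
# T3: the genome carries no D/K-like gene at all ("stand-alone" nifH).
# T3 is mutually exclusive with T1/T2 by construction.

#' Nitrogenase gene copy counts for one genome
#'
#' Counts nifH copies, D-like copies (nifD + vnfD + anfD) and K-like copies
#' (nifK + vnfK + anfK), by normalized gene symbol with a product-string
#' fallback for symbol-less rows.
#'
#' @param genome A `genome_annotation`.
#' @return Named integer vector `c(n_H, n_Dlike, n_Klike)`.
#' @export
nitrogenase_copy_counts <- function(genome) {
  role <- nif_role(genome$records$gene_symbol, genome$records$product)
  c(n_H = sum(role == "H", na.rm = TRUE),
    n_Dlike = sum(role == "D", na.rm = TRUE),
    n_Klike = sum(role == "K", na.rm = TRUE))
}

#' Copy-balance category of a genome's nitrogenase counts
#'
#' Partitions a nitrogenase-bearing genome into exactly one category:
#' `EQUAL` (all three counts equal), `H_EXCESS` (more nifH copies than either
#' D-like or K-like), `NO_H` (no nifH at all), or `OTHER_IMBALANCE`. The
#' `only_H` flag (a sub-flag of `H_EXCESS`) marks genomes with nifH and no
#' D/K-like gene whatsoever.
#'
#' @param counts Named vector from [nitrogenase_copy_counts()].
#' @return `list(category, only_H)`.
#' @export
copy_balance_category <- function(counts) {
  h <- counts[["n_H"]]; d <- counts[["n_Dlike"]]; k <- counts[["n_Klike"]]
  stopifnot(h >= 0, d >= 0, k >= 0)
  if (h + d + k == 0) {
    stop("copy_balance_category requires a genome with at least one nitrogenase gene")
  }
  category <-
    if (h == d && h == k) "EQUAL"
    else if (h == 0) "NO_H"
    else if (h > d && h > k) "H_EXCESS"
    else "OTHER_IMBALANCE"
  list(category = category, only_H = h >= 1 && d == 0 && k == 0)
}

#' Classify every nifH CDS in a genome as T1, T2 or T3
#'
#' For each nifH CDS, builds the coordinate-ordered list of CDSs on the same
#' strand and replicon (opposite-strand CDSs do not consume neighborhood
#' distance) and records every D/K-like gene within
#' `config$neighborhood_radius` positions as a neighborhood hit. D/K-like
#' genes anywhere else on the genome are genome hits. Type follows:
#' neighborhood hit present = T1; none, but genome hit present = T2; neither =
#' T3.
#'
#' @param genome A `genome_annotation` (after [filter_genomes()]).
#' @param config A [nif_config()].
#' @return data.frame with one row per nifH CDS: `genome_id, locus_tag,
#'   replicon_id, strand, nifh_type, n_neighborhood_hits, neighborhood_hits,
#'   genome_hits` (hits encoded as `locus_tag:symbol:offset` strings separated
#'   by `;`).
#' @export
classify_nifh <- function(genome, config = nif_config()) {
  r <- genome$records
  role <- nif_role(r$gene_symbol, r$product)
  h_idx <- which(!is.na(role) & role == "H")
  dk_idx <- which(!is.na(role) & role %in% c("D", "K"))
  out <- data.frame(genome_id = character(0), locus_tag = character(0),
                    replicon_id = character(0), strand = character(0),
                    nifh_type = character(0), n_neighborhood_hits = integer(0),
                    neighborhood_hits = character(0), genome_hits = character(0),
                    stringsAsFactors = FALSE)
  if (length(h_idx) == 0) return(out)
  for (i in h_idx) {
    same <- which(r$replicon_id == r$replicon_id[i] & r$strand == r$strand[i])
    # records are coordinate-ordered, so rank within `same` is the position
    pos_i <- match(i, same)
    nb <- intersect(same, dk_idx)
    offs <- match(nb, same) - pos_i
    in_radius <- abs(offs) <= config$neighborhood_radius
    nb_hits <- nb[in_radius]
    nb_offs <- offs[in_radius]
    genome_hits <- setdiff(dk_idx, nb_hits)
    type <- if (length(nb_hits)) "T1" else if (length(genome_hits)) "T2" else "T3"
    out <- rbind(out, data.frame(
      genome_id = genome$genome_id,
      locus_tag = r$locus_tag[i],
      replicon_id = r$replicon_id[i],
      strand = r$strand[i],
      nifh_type = type,
      n_neighborhood_hits = length(nb_hits),
      neighborhood_hits = paste(sprintf("%s:%s:%+d", r$locus_tag[nb_hits],
                                        tolower(r$gene_symbol[nb_hits]), nb_offs),
                                collapse = ";"),
      genome_hits = paste(r$locus_tag[genome_hits], collapse = ";"),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Per-genome nifH type flags
#'
#' @param calls data.frame of nifH calls (rbind of [classify_nifh()] output).
#' @param genome_ids Optional full genome-id vector so that genomes without a
#'   nifH call appear with all-FALSE flags.
#' @return data.frame `genome_id, has_T1, has_T2, has_T3`.
#' @export
genome_type_flags <- function(calls, genome_ids = NULL) {
  ids <- if (is.null(genome_ids)) unique(calls$genome_id) else genome_ids
  flag <- function(type) {
    vapply(ids, function(g) any(calls$genome_id == g & calls$nifh_type == type),
           logical(1))
  }
  data.frame(genome_id = ids, has_T1 = flag("T1"), has_T2 = flag("T2"),
             has_T3 = flag("T3"), row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage with reproducible rounding
#'
#' `100 * part / whole`, rounded half-to-even at the requested number of
#' decimal places.
#'
#' @param part,whole Counts with `0 <= part <= whole`, `whole > 0`.
#' @param digits Decimal places (default 1).
#' @return Rounded percentage.
#' @examples
#' percentage(1457, 6529)      # 22.3
#' percentage(96, 1457, 2)     # 6.59
#' @export
percentage <- function(part, whole, digits = 1L) {
  stopifnot(length(part) == 1, length(whole) == 1)
  if (whole <= 0) stop("'whole' must be positive")
  if (part < 0 || part > whole) stop("'part' must lie in [0, whole]")
  round(100 * part / whole, digits = digits)
}

#' Census summary over a set of classified genomes
#'
#' Produces the genome-level census: copy-balance category counts (with the
#' only-nifH sub-flag), per-type genome counts (T1; T2 but not T1; T3), and a
#' per-genus breakdown of each nifH type, with percentages.
#'
#' @param annotations Named list of `genome_annotation` objects (the census
#'   set from [filter_genomes()]).
#' @param config A [nif_config()].
#' @return `list(balance, types, taxonomy, calls, flags)` of data.frames.
#' @export
census_summary <- function(annotations, config = nif_config()) {
  if (length(annotations) == 0) {
    balance <- data.frame(category = c("EQUAL", "H_EXCESS", "NO_H",
                                       "OTHER_IMBALANCE", "only_H"),
                          n_genomes = 0L, pct_of_unbalanced = NA_real_,
                          stringsAsFactors = FALSE)
    types <- data.frame(type = c("T1", "T2_not_T1", "T3"), n_genomes = 0L,
                        stringsAsFactors = FALSE)
    return(list(balance = balance, types = types,
                taxonomy = data.frame(genus = character(0), type = character(0),
                                      n_genomes = integer(0)),
                calls = data.frame(), flags = data.frame()))
  }
  counts <- lapply(annotations, nitrogenase_copy_counts)
  cats <- lapply(counts, copy_balance_category)
  cat_v <- vapply(cats, function(x) x$category, character(1))
  only_h <- vapply(cats, function(x) x$only_H, logical(1))
  n_unbal <- sum(cat_v != "EQUAL")
  balance <- data.frame(
    category = c("EQUAL", "H_EXCESS", "NO_H", "OTHER_IMBALANCE", "only_H"),
    n_genomes = c(sum(cat_v == "EQUAL"), sum(cat_v == "H_EXCESS"),
                  sum(cat_v == "NO_H"), sum(cat_v == "OTHER_IMBALANCE"),
                  sum(only_h)),
    stringsAsFactors = FALSE)
  balance$pct_of_unbalanced <- c(NA_real_, vapply(balance$n_genomes[-1],
    function(n) if (n_unbal > 0) percentage(n, n_unbal) else NA_real_,
    numeric(1)))
  calls <- do.call(rbind, lapply(annotations, classify_nifh, config = config))
  if (is.null(calls)) calls <- classify_nifh(annotations[[1]], config)[0, ]
  flags <- genome_type_flags(calls, names(annotations))
  types <- data.frame(
    type = c("T1", "T2_not_T1", "T3"),
    n_genomes = c(sum(flags$has_T1), sum(flags$has_T2 & !flags$has_T1),
                  sum(flags$has_T3)),
    stringsAsFactors = FALSE)
  genus <- vapply(annotations, function(a) a$genus, character(1))
  tax <- do.call(rbind, lapply(c("T1", "T2", "T3"), function(tp) {
    g <- genus[flags[[paste0("has_", tp)]]]
    if (length(g) == 0) return(NULL)
    tb <- table(g, useNA = "ifany")
    data.frame(genus = names(tb), type = tp, n_genomes = as.integer(tb),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tax)) {
    tax <- data.frame(genus = character(0), type = character(0),
                      n_genomes = integer(0), stringsAsFactors = FALSE)
  }
  rownames(tax) <- NULL
  list(balance = balance, types = types, taxonomy = tax,
       calls = calls, flags = flags)
}

#' Write census outputs as commented TSV files
#'
#' @param summary Result of [census_summary()].
#' @param dir Output directory (created if absent).
#' @param config The [nif_config()] echoed into the file headers.
#' @return The directory, invisibly.
#' @export
write_census <- function(summary, dir, config = nif_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- config_echo(config)
  write_tsv_commented(summary$calls, file.path(dir, "nifh_calls.tsv"), cm)
  write_tsv_commented(summary$balance, file.path(dir, "copy_balance.tsv"), cm)
  write_tsv_commented(summary$types, file.path(dir, "nifh_types.tsv"), cm)
  write_tsv_commented(summary$taxonomy, file.path(dir, "taxonomy.tsv"), cm)
  invisible(dir)
}
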