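# Phenotype crosswalk: match genome taxa against a curated diazotrophy table
# (genus + species records; a record with an empty species acts as a
# genus-level wildcard) and tabulate reported/unreported diazotrophs per nifH
# type.

#' Read a diazotrophy phenotype table
#'
#' @param path TSV with columns `genus, species, diazotroph, source`
#'   (`species` may be empty for genus-level records).
#' @return data.frame with normalized (lower-case, trimmed) names.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("genus", "species", "diazotroph") %in% names(df)))
  if (!"source" %in% names(df)) df$source <- ""
  normalize_phenotype_table(df)
}

normalize_phenotype_table <- function(table) {
  table$genus <- tolower(trimws(as.character(table$genus)))
  sp <- as.character(table$species)
  sp[is.na(sp)] <- ""
  table$species <- tolower(trimws(sp))
  table$diazotroph <- as.logical(table$diazotroph)
  if (any(!nzchar(table$genus))) stop("phenotype record with empty genus")
  table
}

#' Look up whether a taxon is a reported diazotroph
#'
#' A taxon is `reported` iff the table contains a diazotroph-positive record
#' for the exact (genus, species) pair, or a genus-level record (empty
#' species) for its genus. Lookup is case-insensitive and independent of
#' record order.
#'
#' @param genus,species Taxon names (species may be empty).
#' @param table Phenotype data.frame (see [read_phenotype_table()]).
#' @return `"reported"` or `"not_reported"`.
#' @export
lookup_diazotrophy <- function(genus, species, table) {
  table <- normalize_phenotype_table(table)
  genus <- tolower(trimws(genus))
  if (!nzchar(genus) || is.na(genus)) stop("empty genus")
  species <- tolower(trimws(ifelse(is.na(species), "", species)))
  pos <- table[table$diazotroph, , drop = FALSE]
  hit <- any(pos$genus == genus & pos$species == "") ||
    (nzchar(species) && any(pos$genus == genus & pos$species == species))
  if (hit) "reported" else "not_reported"
}

#' Tabulate reported/unreported diazotrophs per nifH type
#'
#' Partitions nifH-bearing genomes into three disjoint rows — harboring T1;
#' harboring T2 but not T1; harboring T3 — and splits each row into strains
#' with and without a prior diazotrophy report in the phenotype table.
#' Resolution is species level (strain suffixes are not consulted): when
#' strains of one reported species fall into different type rows, every
#' strain of that species is flagged in the `n_conflict` column, since the
#' species-level report cannot distinguish them.
#'
#' @param flags data.frame with columns `genome_id, genus, species, has_T1,
#'   has_T2, has_T3` (e.g. [genome_type_flags()] joined with taxa).
#' @param table Phenotype data.frame.
#' @return `list(table, per_genome)`: the three-row summary
#'   (`type, n_reported, n_not_reported, n_conflict`) and the per-genome
#'   assignments behind it.
#' @export
tabulate_by_type <- function(flags, table) {
  req <- c("genome_id", "genus", "species", "has_T1", "has_T2", "has_T3")
  stopifnot(all(req %in% names(flags)))
  table <- normalize_phenotype_table(table)
  row_of <- ifelse(flags$has_T1, "T1",
            ifelse(flags$has_T2, "T2_not_T1",
            ifelse(flags$has_T3, "T3", NA_character_)))
  keep <- !is.na(row_of)
  flags <- flags[keep, , drop = FALSE]
  row_of <- row_of[keep]
  reported <- vapply(seq_len(nrow(flags)), function(i) {
    lookup_diazotrophy(flags$genus[i], flags$species[i], table)
  }, character(1)) == "reported"
  # species whose strains land in different type rows while the species is
  # reported: the phenotype record cannot be attributed to a single type
  sp_key <- paste(tolower(trimws(flags$genus)), tolower(trimws(flags$species)))
  conflict <- vapply(seq_along(sp_key), function(i) {
    reported[i] && length(unique(row_of[sp_key == sp_key[i]])) > 1
  }, logical(1))
  per_genome <- data.frame(genome_id = flags$genome_id, type_row = row_of,
                           reported = reported, conflict = conflict,
                           stringsAsFactors = FALSE)
  rows <- c("T1", "T2_not_T1", "T3")
  out <- data.frame(
    type = rows,
    n_reported = vapply(rows, function(r) sum(reported[row_of == r]), integer(1)),
    n_not_reported = vapply(rows, function(r) sum(!reported[row_of == r]), integer(1)),
    n_conflict = vapply(rows, function(r) sum(conflict[row_of == r]), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(table = out, per_genome = per_genome)
}
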