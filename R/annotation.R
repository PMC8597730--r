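# Genome annotations are plain ordered CDS tables: one data.frame per genome
# with columns replicon_id, start, end, strand, locus_tag, gene_symbol,
# product, is_pseudo, sorted by (replicon_id, start). Coordinates are 1-based
# inclusive throughout (the native convention of feature tables and GFF3).

FT_COLUMNS <- c("replicon", "start", "end", "strand", "feature", "gene",
                "locus_tag", "product", "pseudo")

new_genome_annotation <- function(genome_id, records,
                                  genus = NA_character_,
                                  species = NA_character_,
                                  completeness = NA_real_) {
  ord <- order(records$replicon_id, records$start, records$end, records$locus_tag)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  if (anyDuplicated(records$locus_tag)) {
    stop(sprintf("genome '%s': duplicated locus_tag", genome_id))
  }
  structure(list(genome_id = genome_id, genus = genus, species = species,
                 completeness = completeness, records = records),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%s %s), completeness %s, %d CDS on %d replicon(s)\n",
              x$genome_id, x$genus, x$species,
              ifelse(is.na(x$completeness), "NA", format(x$completeness)),
              nrow(x$records), length(unique(x$records$replicon_id))))
  invisible(x)
}

empty_cds_records <- function() {
  data.frame(replicon_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), locus_tag = character(0),
             gene_symbol = character(0), product = character(0),
             is_pseudo = logical(0), stringsAsFactors = FALSE)
}

#' Parse a tab-delimited CDS feature table
#'
#' Reads the tab-separated per-genome CDS table dialect used throughout this
#' package (and emitted by [gen_genomes()]): columns `replicon, start, end,
#' strand, feature, gene, locus_tag, product, pseudo`, with an optional header
#' line. Only `CDS` features are retained. Pseudogene-flagged records are kept
#' but marked (`is_pseudo`); filtering them is [filter_genomes()]'s job.
#' Records are normalized to coordinate order per replicon.
#'
#' @param path File path.
#' @param genome_id Genome identifier (defaults to the file name sans
#'   extension).
#' @param genus,species,completeness Optional genome metadata.
#' @return A `genome_annotation` object.
#' @export
parse_feature_table <- function(path, genome_id = NULL,
                                genus = NA_character_, species = NA_character_,
                                completeness = NA_real_) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L || all(!nzchar(lines))) {
    warning(sprintf("empty feature table: %s", path))
    return(new_genome_annotation(genome_id, empty_cds_records(),
                                 genus, species, completeness))
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- identical(tolower(first[1]), "replicon")
  body <- if (has_header) lines[-1] else lines
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != length(FT_COLUMNS))
  if (length(bad)) {
    stop(sprintf("malformed feature-table row at line %d of %s (%d fields, expected %d)",
                 bad[1] + if (has_header) 1L else 0L, path, nf[bad[1]],
                 length(FT_COLUMNS)))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- FT_COLUMNS
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  df <- df[df$feature == "CDS", , drop = FALSE]
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  if (nrow(df) && (anyNA(start) || anyNA(end))) {
    stop(sprintf("non-numeric coordinates in %s", path))
  }
  if (any(start > end)) stop(sprintf("start > end in %s", path))
  if (nrow(df) && !all(df$strand %in% c("+", "-"))) {
    stop(sprintf("strand must be '+' or '-' in %s", path))
  }
  rec <- data.frame(replicon_id = df$replicon, start = start, end = end,
                    strand = df$strand, locus_tag = df$locus_tag,
                    gene_symbol = df$gene, product = df$product,
                    is_pseudo = tolower(df$pseudo) %in% c("true", "t", "1", "yes"),
                    stringsAsFactors = FALSE)
  new_genome_annotation(genome_id, rec, genus, species, completeness)
}

#' Parse a GFF3 file into the same annotation model
#'
#' Reads CDS features from a GFF3 file via `rtracklayer` and returns the same
#' `genome_annotation` model as [parse_feature_table()] (1-based inclusive
#' coordinates). A CDS lacking a `locus_tag` attribute gets one synthesized
#' from its coordinates, with a warning. A file with no CDS features yields an
#' empty record set with a warning.
#'
#' @inheritParams parse_feature_table
#' @return A `genome_annotation` object.
#' @export
parse_gff3 <- function(path, genome_id = NULL,
                       genus = NA_character_, species = NA_character_,
                       completeness = NA_real_) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) {
    warning(sprintf("no CDS features in %s", path))
    return(new_genome_annotation(genome_id, empty_cds_records(),
                                 genus, species, completeness))
  }
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(nm) {
    if (nm %in% colnames(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  locus <- get_attr("locus_tag")
  miss <- is.na(locus) | !nzchar(locus)
  if (any(miss)) {
    warning(sprintf("%d CDS without locus_tag in %s; synthesized from coordinates",
                    sum(miss), path))
    locus[miss] <- sprintf("cds_%s_%d_%d",
                           as.character(GenomicRanges::seqnames(gr))[miss],
                           GenomicRanges::start(gr)[miss],
                           GenomicRanges::end(gr)[miss])
  }
  gene <- get_attr("gene")
  gene[is.na(gene)] <- ""
  product <- get_attr("product")
  product[is.na(product)] <- ""
  pseudo_attr <- if ("pseudo" %in% colnames(mc)) {
    p <- mc$pseudo
    if (is.logical(p)) !is.na(p) & p else !is.na(as.character(p)) &
      tolower(as.character(p)) %in% c("true", "t", "1", "yes", "")
  } else rep(FALSE, length(gr))
  rec <- data.frame(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = locus, gene_symbol = gene, product = product,
    is_pseudo = pseudo_attr, stringsAsFactors = FALSE)
  if (any(!rec$strand %in% c("+", "-"))) {
    stop(sprintf("CDS with unstranded feature in %s", path))
  }
  new_genome_annotation(genome_id, rec, genus, species, completeness)
}

#' Write a genome annotation as a tab-delimited feature table
#' @param annotation A `genome_annotation`.
#' @param path Output file.
#' @export
write_feature_table <- function(annotation, path) {
  r <- annotation$records
  df <- data.frame(replicon = r$replicon_id, start = r$start, end = r$end,
                   strand = r$strand, feature = "CDS", gene = r$gene_symbol,
                   locus_tag = r$locus_tag, product = r$product,
                   pseudo = ifelse(r$is_pseudo, "true", "false"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- gene identification ----------------------------------------------------

NIF_H_SYMBOLS <- "nifh"
NIF_D_SYMBOLS <- c("nifd", "vnfd", "anfd")
NIF_K_SYMBOLS <- c("nifk", "vnfk", "anfk")

# Role of a CDS in the nitrogenase census: "H", "D", "K" or NA.
# Primary key is the normalized gene symbol; rows without a symbol fall back
# to a product-string match (annotation pipelines sometimes drop the symbol
# but keep the canonical product name).
nif_role <- function(gene_symbol, product) {
  sym <- tolower(trimws(gene_symbol))
  role <- rep(NA_character_, length(sym))
  role[sym %in% NIF_H_SYMBOLS] <- "H"
  role[sym %in% NIF_D_SYMBOLS] <- "D"
  role[sym %in% NIF_K_SYMBOLS] <- "K"
  no_sym <- is.na(role) & !nzchar(sym)
  if (any(no_sym)) {
    prod <- tolower(product[no_sym])
    r <- rep(NA_character_, sum(no_sym))
    r[grepl("nitrogenase iron protein", prod) &
        !grepl("molybdenum|vanadium", prod)] <- "H"
    r[grepl("nitrogenase molybdenum-iron protein alpha", prod)] <- "D"
    r[grepl("nitrogenase molybdenum-iron protein beta", prod)] <- "K"
    role[no_sym] <- r
  }
  role
}

has_nitrogenase_gene <- function(annotation) {
  r <- annotation$records
  any(!is.na(nif_role(r$gene_symbol, r$product)))
}

#' Filter genomes by completeness and drop pseudogene CDSs
#'
#' Applies the census inclusion rules: genomes with completeness below
#' `completeness_min` (or with missing completeness) are excluded with a
#' warning; pseudogene-flagged CDSs are removed from the survivors; and
#' genomes that retain no nitrogenase gene afterwards are dropped from the
#' census set. The completeness boundary is inclusive (a genome at exactly
#' the minimum is kept).
#'
#' @param annotations List of `genome_annotation` objects.
#' @param metadata Optional data.frame with columns `genome_id, genus,
#'   species, completeness`, used to fill in missing per-annotation metadata.
#' @param config A [nif_config()].
#' @return Named list of surviving `genome_annotation` objects, with
#'   attributes `excluded_completeness` and `excluded_no_nitrogenase`
#'   (character vectors of genome ids).
#' @export
filter_genomes <- function(annotations, metadata = NULL, config = nif_config()) {
  if (length(annotations) == 0) return(structure(list(),
    excluded_completeness = character(0),
    excluded_no_nitrogenase = character(0)))
  ids <- vapply(annotations, function(a) a$genome_id, character(1))
  names(annotations) <- ids
  if (!is.null(metadata)) {
    stopifnot(all(c("genome_id", "completeness") %in% names(metadata)))
    idx <- match(ids, metadata$genome_id)
    for (k in seq_along(annotations)) {
      if (!is.na(idx[k])) {
        a <- annotations[[k]]
        if (is.na(a$completeness)) a$completeness <- metadata$completeness[idx[k]]
        if (is.na(a$genus) && "genus" %in% names(metadata))
          a$genus <- metadata$genus[idx[k]]
        if (is.na(a$species) && "species" %in% names(metadata))
          a$species <- metadata$species[idx[k]]
        annotations[[k]] <- a
      }
    }
  }
  compl <- vapply(annotations, function(a) a$completeness, numeric(1))
  missing_c <- is.na(compl)
  if (any(missing_c)) {
    warning(sprintf("excluding %d genome(s) with missing completeness: %s",
                    sum(missing_c), paste(ids[missing_c], collapse = ", ")))
  }
  low <- !missing_c & compl < config$completeness_min
  excl_compl <- ids[missing_c | low]
  keep <- annotations[!(missing_c | low)]
  # drop pseudogene CDSs from survivors
  keep <- lapply(keep, function(a) {
    a$records <- a$records[!a$records$is_pseudo, , drop = FALSE]
    rownames(a$records) <- NULL
    a
  })
  has_nif <- vapply(keep, has_nitrogenase_gene, logical(1))
  excl_nonif <- names(keep)[!has_nif]
  structure(keep[has_nif],
            excluded_completeness = excl_compl,
            excluded_no_nitrogenase = excl_nonif)
}
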