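# Synthetic annotated genomes with configurable nif operon layouts, so the
# census logic can be exercised with known ground truth. Layouts:
#   T1_operon     nifH with nifD/nifK within the same-strand neighborhood
#   T2_split      nifH with its D partner >= 11 same-strand CDSs away (or on
#                 another replicon)
#   T1_plus_T2    a full operon plus a distant stand-alone extra nifH
#   T3_standalone nifH and no D/K-like gene anywhere
#   no_nif        decoys only

SIM_LAYOUTS <- c("T1_operon", "T2_split", "T1_plus_T2", "T3_standalone", "no_nif")

# fixed non-nif decoy vocabulary: neighborhood counting must skip arbitrary
# genes, including symbol-less rows with generic products
DECOY_GENES <- data.frame(
  gene = c("dnaA", "recA", "gyrB", "rpoB", "ftsZ", "secA", "groL", "rplB",
           "atpD", "tuf", "glnA", "fixJ", "bchX", "mtrA", ""),
  product = c("chromosomal replication initiator protein DnaA",
              "recombinase RecA", "DNA gyrase subunit B",
              "DNA-directed RNA polymerase subunit beta",
              "cell division protein FtsZ", "preprotein translocase SecA",
              "chaperonin GroEL", "50S ribosomal protein L2",
              "ATP synthase subunit beta", "elongation factor Tu",
              "glutamine synthetase", "response regulator FixJ",
              "chlorophyllide reductase iron protein subunit X",
              "tetrahydromethanopterin S-methyltransferase subunit A",
              "hypothetical protein"),
  stringsAsFactors = FALSE)

#' Specification of one synthetic genome
#'
#' @param genome_id Unique identifier.
#' @param layout One of `"T1_operon"`, `"T2_split"`, `"T1_plus_T2"`,
#'   `"T3_standalone"`, `"no_nif"`.
#' @param n_decoy_cds Number of decoy (non-nif) CDSs.
#' @param replicons Number of replicons (chromosome + plasmids).
#' @param genus,species Taxon names.
#' @param completeness Completeness fraction in \[0, 1\].
#' @return A `sim_genome_spec` list.
#' @export
sim_genome_spec <- function(genome_id, layout = "T1_operon", n_decoy_cds = 30L,
                            replicons = 1L, genus = "Simulibacter",
                            species = "fictus", completeness = 1.0) {
  layout <- match.arg(layout, SIM_LAYOUTS)
  stopifnot(n_decoy_cds >= 0, replicons >= 1,
            completeness >= 0, completeness <= 1)
  structure(list(genome_id = genome_id, layout = layout,
                 n_decoy_cds = as.integer(n_decoy_cds),
                 replicons = as.integer(replicons),
                 genus = genus, species = species,
                 completeness = completeness),
            class = "sim_genome_spec")
}

# sample a decoy CDS row (symbol + product), random strand
sample_decoys <- function(n, strand = NULL) {
  if (n == 0) return(cbind(DECOY_GENES[0, ], strand = character(0)))
  idx <- sample.int(nrow(DECOY_GENES), n, replace = TRUE)
  out <- DECOY_GENES[idx, , drop = FALSE]
  out$strand <- if (is.null(strand)) sample(c("+", "-"), n, replace = TRUE)
                else rep(strand, n)
  rownames(out) <- NULL
  out
}

NIF_PRODUCTS <- c(nifH = "nitrogenase iron protein",
                  nifD = "nitrogenase molybdenum-iron protein alpha chain",
                  nifK = "nitrogenase molybdenum-iron protein beta chain")

nif_row <- function(symbol) {
  data.frame(gene = symbol,
             product = unname(NIF_PRODUCTS[symbol]),
             strand = "+", stringsAsFactors = FALSE)
}

# Build one genome's gene plan (ordered rows of gene/product/strand per
# replicon) realizing the layout under same-strand distance counting. nif
# genes sit on '+'; decoys inserted between them are forced to '+' so the
# intended same-strand offsets hold exactly, while flanking decoys have
# random strands.
plan_genome <- function(spec, radius = 10L) {
  inner <- function(sym_block) do.call(rbind, lapply(sym_block, nif_row))
  blocks <- switch(spec$layout,
    T1_operon = {
      # 0..3 same-strand decoys between nifH and nifD (within radius)
      k <- sample(0:3, 1)
      list(rbind(nif_row("nifH"), sample_decoys(k, "+"), nif_row("nifD"),
                 nif_row("nifK")))
    },
    T2_split = {
      # >= radius + 1 same-strand CDSs between nifH and nifD
      k <- radius + 1L + sample(1:4, 1)
      if (spec$replicons > 1 && runif(1) < 0.5) {
        list(nif_row("nifH"), plasmid = nif_row("nifD"))
      } else {
        list(rbind(nif_row("nifH"), sample_decoys(k, "+"), nif_row("nifD")))
      }
    },
    T1_plus_T2 = {
      k <- radius + 1L + sample(1:4, 1)
      list(rbind(nif_row("nifH"), nif_row("nifD"), nif_row("nifK"),
                 sample_decoys(k, "+"), nif_row("nifH")))
    },
    T3_standalone = list(nif_row("nifH")),
    no_nif = list(NULL))
  blocks
}

# expected truth types per layout
layout_truth <- function(layout) {
  switch(layout,
    T1_operon = "T1", T2_split = "T2", T1_plus_T2 = "T1;T2",
    T3_standalone = "T3", no_nif = "")
}

build_genome <- function(spec, radius = 10L) {
  blocks <- plan_genome(spec, radius)
  # distribute decoys: flanks of the nif block on the chromosome, the rest
  # spread over remaining replicons
  n_extra <- spec$n_decoy_cds
  n_rep <- spec$replicons
  rep_ids <- c("chr", if (n_rep > 1) sprintf("plasmid%d", seq_len(n_rep - 1L)))
  per_rep <- if (n_rep == 1) n_extra else {
    v <- as.vector(rmultinom(1, n_extra, rep(1 / n_rep, n_rep)))
    v
  }
  rows_by_rep <- vector("list", n_rep)
  names(rows_by_rep) <- rep_ids
  chr_block <- blocks[[1]]
  n_chr <- if (n_rep == 1) n_extra else per_rep[1]
  pre <- sample.int(n_chr + 1L, 1) - 1L
  rows_by_rep[["chr"]] <- rbind(sample_decoys(pre), chr_block,
                                sample_decoys(n_chr - pre))
  if (n_rep > 1) {
    for (j in 2:n_rep) {
      extra <- sample_decoys(per_rep[j])
      blk <- if (!is.null(blocks$plasmid) && j == 2) blocks$plasmid else NULL
      rows_by_rep[[rep_ids[j]]] <- rbind(extra, blk)
    }
  }
  # lay out coordinates and locus tags
  recs <- list()
  tag_i <- 0L
  for (rid in rep_ids) {
    rows <- rows_by_rep[[rid]]
    if (is.null(rows) || nrow(rows) == 0) next
    pos <- 1L
    for (i in seq_len(nrow(rows))) {
      len <- 3L * sample(250:550, 1)
      tag_i <- tag_i + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        replicon_id = rid, start = pos, end = pos + len - 1L,
        strand = rows$strand[i],
        locus_tag = sprintf("%s_%04d", spec$genome_id, tag_i),
        gene_symbol = rows$gene[i], product = rows$product[i],
        is_pseudo = FALSE, stringsAsFactors = FALSE)
      pos <- pos + len + sample(50:200, 1)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_cds_records()
  new_genome_annotation(spec$genome_id, records, spec$genus, spec$species,
                        spec$completeness)
}

#' Generate synthetic annotated genomes with known nifH typing
#'
#' Builds one annotated genome per spec (pure function of specs + seed),
#' optionally writing a feature table per genome, a metadata TSV, a truth TSV
#' and a run manifest.
#'
#' @param specs List of [sim_genome_spec()] objects with unique ids.
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @param config A [nif_config()] (neighborhood radius used to realize
#'   layouts).
#' @return `list(annotations, truth, metadata)`; `truth` has one row per
#'   genome with the intended nifH types (`;`-separated, empty for none).
#' @export
gen_genomes <- function(specs, seed = 1L, dir = NULL, config = nif_config()) {
  if (inherits(specs, "sim_genome_spec")) specs <- list(specs)
  ids <- vapply(specs, function(s) s$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate genome_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  annotations <- withr::with_seed(seed, {
    lapply(specs, build_genome, radius = config$neighborhood_radius)
  })
  names(annotations) <- ids
  truth <- data.frame(
    genome_id = ids,
    layout = vapply(specs, function(s) s$layout, character(1)),
    nifh_types = vapply(specs, function(s) layout_truth(s$layout), character(1)),
    stringsAsFactors = FALSE)
  metadata <- data.frame(
    genome_id = ids,
    genus = vapply(specs, function(s) s$genus, character(1)),
    species = vapply(specs, function(s) s$species, character(1)),
    completeness = vapply(specs, function(s) s$completeness, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (a in annotations) {
      write_feature_table(a, file.path(dir, paste0(a$genome_id, ".tsv")))
    }
    write_tsv_commented(metadata, file.path(dir, "metadata.tsv"))
    write_tsv_commented(truth, file.path(dir, "truth_genomes.tsv"))
    manifest <- list(generator = "gen_genomes", seed = seed,
                     n_genomes = length(specs),
                     layouts = as.list(table(truth$layout)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(annotations = annotations, truth = truth, metadata = metadata)
}

#' Generate a synthetic diazotrophy phenotype table
#'
#' @param taxa data.frame with columns `genus, species` (species may be empty
#'   for genus-level records).
#' @param diazotroph_flags Logical vector parallel to `taxa`.
#' @param path Optional TSV output path.
#' @return Phenotype data.frame (`genus, species, diazotroph, source`).
#' @export
gen_phenotype_table <- function(taxa, diazotroph_flags, path = NULL) {
  stopifnot(is.data.frame(taxa), all(c("genus", "species") %in% names(taxa)),
            nrow(taxa) == length(diazotroph_flags))
  out <- data.frame(genus = taxa$genus, species = taxa$species,
                    diazotroph = as.logical(diazotroph_flags),
                    source = rep("synthetic", nrow(taxa)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv_commented(out, path)
  out
}
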