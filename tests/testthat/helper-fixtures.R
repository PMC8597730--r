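# Fixture builders: compact in-code construction of genome annotations,
# random CDS tables for fuzzing, and small reference panels.

AA_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

rand_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                                  collapse = "")

# Build a genome_annotation from a compact gene plan: a data.frame (or list
# of rows) with columns gene, strand, and optionally replicon, product,
# pseudo. Coordinates are laid out sequentially per replicon.
make_genome <- function(genome_id, plan, genus = "Testus", species = "toyi",
                        completeness = 1.0) {
  plan$replicon <- if (is.null(plan$replicon)) "chr" else plan$replicon
  plan$product <- if (is.null(plan$product)) "" else plan$product
  plan$pseudo <- if (is.null(plan$pseudo)) FALSE else plan$pseudo
  recs <- NULL
  tag <- 0L
  for (rep_id in unique(plan$replicon)) {
    rows <- plan[plan$replicon == rep_id, , drop = FALSE]
    pos <- 1L
    for (k in seq_len(nrow(rows))) {
      len <- 900L
      tag <- tag + 1L
      recs <- rbind(recs, data.frame(
        replicon_id = rep_id, start = pos, end = pos + len - 1L,
        strand = rows$strand[k],
        locus_tag = sprintf("%s_%03d", genome_id, tag),
        gene_symbol = rows$gene[k], product = rows$product[k],
        is_pseudo = rows$pseudo[k], stringsAsFactors = FALSE))
      pos <- pos + len + 100L
    }
  }
  pseudonif:::new_genome_annotation(genome_id, recs, genus, species,
                                    completeness)
}

# Random CDS table for fuzz tests: arbitrary mixtures of nif genes and decoys
# over 1-2 replicons with random strands. Independent of gen_genomes.
random_fuzz_genome <- function(genome_id) {
  n <- sample(5:40, 1)
  genes <- sample(c("nifH", "nifD", "nifK", "vnfD", "vnfK", "anfD", "anfK",
                    "recA", "gyrB", "rpoB", "ftsZ", ""),
                  n, replace = TRUE,
                  prob = c(0.12, 0.06, 0.06, 0.02, 0.02, 0.02, 0.02,
                           0.17, 0.17, 0.17, 0.12, 0.05))
  plan <- data.frame(
    gene = genes,
    strand = sample(c("+", "-"), n, replace = TRUE),
    replicon = sample(c("chr", "plasmid1"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  plan <- plan[order(plan$replicon), , drop = FALSE]
  make_genome(genome_id, plan)
}

# Small typed reference panel + sources built from a well-separated two-clade
# family; used by the screen tests.
make_screen_panel <- function(seed = 11L, n_per_clade = 6L) {
  fam <- gen_protein_family(sim_family_spec(n_per_clade, n_per_clade, 300,
                                            0.02, 0.50, seed = seed))
  true_seqs <- setNames(fam$sequence[fam$label == "T12"],
                        fam$seq_id[fam$label == "T12"])
  pseudo_seqs <- setNames(fam$sequence[fam$label == "T3"],
                          fam$seq_id[fam$label == "T3"])
  refD <- setNames(rand_protein(298), "nifD_ref")
  refK <- setNames(rand_protein(298), "nifK_ref")
  decoys <- setNames(c(rand_protein(290), rand_protein(310)),
                     c("decoy_bchX", "decoy_hyp"))
  refs <- c(true_seqs, pseudo_seqs, refD, refK)
  groups <- c(rep("nifH", 2 * n_per_clade), "nifD_like", "nifK_like")
  types <- setNames(c(rep(c("T1", "T2"), length.out = n_per_clade),
                      rep("T3", n_per_clade)),
                    c(names(true_seqs), names(pseudo_seqs)))
  list(family = fam, true_seqs = true_seqs, pseudo_seqs = pseudo_seqs,
       refs = refs, groups = groups, types = types, decoys = decoys)
}
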