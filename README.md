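# pseudonif

Detection of "pseudo" *nifH* genes — *nifH* homologs unlikely to take part in
nitrogen fixation — in prokaryotic genomes and shotgun metagenomes.

## Why

*nifH* (nitrogenase reductase) is the conventional marker gene for
diazotrophs, but NifH does not fix nitrogen by itself: it reduces the
catalytic NifD/NifK subunits. Public databases contain hundreds of *nifH*
homologs on genomes that carry no *nifD* or *nifK* anywhere — stand-alone
*nifH* that cannot function as part of a nitrogenase. Treating every *nifH*
hit as a nitrogen fixer overestimates diazotroph abundance, in extreme cases
severalfold.

`pseudonif` is for microbial ecologists and bioinformaticians who want to
quantify that problem in their own data. It provides:

* **Genome census** (`parse_feature_table()`, `parse_gff3()`,
  `filter_genomes()`, `classify_nifh()`, `census_summary()`) — every *nifH*
  CDS is typed by operon context:
  * **T1** — a D/K-like gene (*nifD/K*, *vnfD/K*, *anfD/K*) within 10
    same-strand CDS positions of *nifH* (operonic);
  * **T2** — D/K-like genes elsewhere on the genome (plasmids included) but
    not in the neighborhood;
  * **T3** — no D/K-like gene on the genome at all: the pseudo-*nifH*
    candidate. T3 is mutually exclusive with T1/T2.
* **Phenotype crosswalk** (`lookup_diazotrophy()`, `tabulate_by_type()`) —
  genomes vs a curated diazotrophy table (genus/species, genus-level
  wildcards).
* **Confusability** (`cluster_greedy()`, `partial_mapping_experiment()`,
  `window_confusion_profile()`) — can 40–100 aa NifH fragments be attributed
  to the true (T1/2) or pseudo (T3) clade at 90/95% identity? Exact global
  alignment (affine-gap Needleman–Wunsch in C++), identity over
  non-terminal-gap columns.
* **Metagenome screen** (`qc_reads()`, `screen_stage1()`, `assign_gene()`,
  `classify_nifh_read()`, `screen_metagenome()`) — paired-end reads are
  merged (≤ 5 mismatches, ≥ 20-base overlap), trimmed to expected errors
  < 0.5, length-filtered (≥ 200 bases), capped at 2.5 M reads, screened
  against a nitrogenase panel in six translated frames, and *nifH* reads are
  classified true / pseudo / ambiguous by retaining hits within 95% of the
  best identity. Includes the overestimation factor (reciprocal of the true
  fraction) and an exact-Poisson (99% CI) test of read-count proportionality
  to gene lengths (*nifD*:*nifH* = 894:1497 bp, ratio 0.597).
* **Synthetic data** (`gen_genomes()`, `gen_protein_family()`,
  `gen_metagenome()`, `gen_phenotype_table()`) — annotated genomes with
  configurable *nif* layouts, two-clade NifH families, and paired-end
  metagenomes with truth labels, so the whole pipeline is testable without
  any database download.

## Worked example

```r
library(pseudonif)

specs <- list(
  sim_genome_spec("G01", "T1_operon",     genus = "Clostridium",        species = "acetobutylicum"),
  sim_genome_spec("G02", "T2_split",      genus = "Bradyrhizobium",     species = "diazoefficiens", replicons = 2),
  sim_genome_spec("G03", "T3_standalone", genus = "Methanobrevibacter", species = "smithii"),
  sim_genome_spec("G04", "no_nif",        genus = "Escherichia",        species = "coli"))
g    <- gen_genomes(specs, seed = 101)
kept <- filter_genomes(g$annotations, g$metadata)
cs   <- census_summary(kept)
cs$calls[, c("genome_id", "locus_tag", "nifh_type", "n_neighborhood_hits")]
#>     genome_id locus_tag nifh_type n_neighborhood_hits
#> G01       G01  G01_0025        T1                   2
#> G02       G02  G02_0009        T2                   0
#> G03       G03  G03_0012        T3                   0
```

The operonic *nifH* (G01) has two D/K-like neighbors; the split genome (G02)
has its partner subunits out of the neighborhood; the stand-alone *nifH*
(G03) is the pseudo-*nifH* candidate; G04 never enters the census. Crossing
the census against a phenotype table separates reported diazotrophs by type:

```r
tb <- gen_phenotype_table(
  data.frame(genus = c("Clostridium", "Bradyrhizobium"),
             species = c("acetobutylicum", "")),   # genus-level wildcard
  c(TRUE, TRUE))
fl <- merge(cs$flags, g$metadata, by = "genome_id")
tabulate_by_type(fl, tb)$table
#>        type n_reported n_not_reported n_conflict
#> 1        T1          1              0          0
#> 2 T2_not_T1          1              0          0
#> 3        T3          0              1          0
```

Only the T3 strain has no diazotrophy report — the signature that motivates
calling it pseudo-*nifH*. Census arithmetic and the count-proportionality
test work the same way on real tallies:

```r
percentage(1457, 6529)                                # 22.3  (% of genomes with unequal copy numbers)
proportionality_test(300, 520, 894, 1497)$verdict     # "consistent" with the 0.597 length ratio
```

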