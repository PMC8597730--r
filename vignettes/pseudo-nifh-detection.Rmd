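---
title: "Detecting pseudo-nifH in genomes and metagenomes: methods and design"
author: "pseudonif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pseudo-nifH in genomes and metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudonif)
```

## The problem

The *nifH* gene, encoding the nitrogenase reductase (Fe protein), is the
standard marker for biological nitrogen fixation in amplicon and shotgun
surveys. NifH, however, does not cleave N~2~ itself — it delivers electrons to
the catalytic NifD/NifK subunits — and public databases contain many *nifH*
homologs on genomes that carry no *nifD* or *nifK* at all (in methanogens,
for instance, some of these homologs turn out to be coenzyme F430 biosynthesis
genes). Counting such "pseudo-*nifH*" sequences as diazotroph evidence
inflates the apparent abundance of nitrogen fixers.

`pseudonif` implements a genome-context test for this problem and follows its
consequences through to metagenomic read classification:

1. **Genome census** — type every *nifH* CDS by operon context:

   * **T1**: a *nifD/nifK*-like gene (including the alternative-nitrogenase
     *vnfD/K*, *anfD/K*) lies within 10 positions of *nifH* in the ordered
     list of *same-strand* CDSs on the same replicon;
   * **T2**: no such neighbor, but a D/K-like gene exists elsewhere on the
     genome (any strand, any replicon, plasmids included);
   * **T3**: the genome carries no D/K-like gene at all — the stand-alone,
     presumed-pseudo *nifH*. T3 is mutually exclusive with T1/T2 by
     construction.

2. **Phenotype crosswalk** — compare types against a curated diazotrophy
   table keyed by genus/species.

3. **Confusability** — ask whether short NifH fragments (40–100 aa, the range
   covered by Illumina read lengths) can even be attributed to the true or the
   pseudo clade.

4. **Metagenome screen** — classify *nifH*-like reads of a paired-end sample
   as true / pseudo / ambiguous and test whether *nifH*, *nifD*, *nifK* read
   counts are proportional to gene lengths.

## Genome census

Annotations enter as tab-delimited CDS tables (`parse_feature_table()`; the
dialect is `replicon, start, end, strand, feature, gene, locus_tag, product,
pseudo`) or as GFF3 (`parse_gff3()`, via `rtracklayer`). Coordinates are
1-based inclusive end to end — the native convention of both formats and of
R/Bioconductor containers; only the *ordering* of CDSs matters for typing, so
no coordinate arithmetic crosses that boundary.

`filter_genomes()` applies the census inclusion rules: completeness ≥ 0.95
(inclusive boundary; genomes with missing completeness are excluded loudly,
not kept silently), pseudogene-flagged CDSs dropped, and genomes left without
any nitrogenase gene removed from the census set.

Gene identification is by normalized (lower-cased) gene symbol — `nifH`;
D-like = `nifD, vnfD, anfD`; K-like = `nifK, vnfK, anfK` — with a
product-string fallback for symbol-less rows ("nitrogenase iron protein",
"nitrogenase molybdenum-iron protein alpha/beta chain"). Neighborhood
distance is counted in positions within the same-strand sub-list, i.e.
opposite-strand CDSs do not consume distance; the neighborhood never spans
replicons. A D-like gene within range of two *nifH* copies is evidence for
both. `classify_nifh()` is verified against a brute-force enumerator that
recounts distances directly from coordinates on 1,000 random genomes.

`percentage()` rounds half-to-even at the requested precision so that summary
tables are reproducible.

## Pairwise alignment and identity

All sequence comparison is exact global alignment (Needleman–Wunsch with
affine gaps, Gotoh's three-state recursion, BLOSUM62, gap open −11 / extend
−1). Local alignment is deliberately avoided: short high-scoring local hits
are exactly the artifact the fragment experiments must not admit. `X` is
scored 0 against everything — fragments translated across ambiguous bases
should be neither rewarded nor penalized.

**Identity** is matches divided by alignment columns *excluding terminal gap
runs* (internal gap columns count). This makes a 40-aa fragment aligned
inside a 300-aa reference scoreable at up to 100% identity, which the
fragment-mapping design requires; with an all-columns denominator such a
query could never reach the 90–95% thresholds. The denominator convention is
a config choice.

Two numerical details matter here:

* **Tie-breaking.** Among co-optimal alignments the traceback prefers gap
  states (and gap-run continuation) over the diagonal on exact score ties.
  With the opposite preference, a co-optimal traceback can "snap" a
  fragment's terminal residue onto a distant identical residue in the
  reference, converting a terminal gap run into an internal one and
  collapsing the identity of an exact substring from 1.0 to ~0.3. The score
  is unaffected by tie-breaking — it still equals the exhaustive-enumeration
  optimum — but identity is only well-behaved with gap-preferring ties.
* **Symmetry.** `needleman_wunsch()` canonicalizes the argument order
  internally (and transposes the result back), so
  `global_identity(a, b) == global_identity(b, a)` holds exactly, including
  on knife-edge ties; the similarity networks use the same canonical
  orientation per pair.

Six-frame translation uses the standard genetic code via `Biostrings`
(stops as `*`, codons containing `N` as `X`); translated fragments are split
at stops and fragments shorter than 20 aa discarded, mirroring translated-
search practice without frameshift-aware alignment.

## Read quality control

`merge_pairs()` merges a read pair by sliding the reverse-complemented mate
along the forward read. Among qualifying overlaps (≥ 20 bases, ≤ 5
mismatches — both config values) the fewest-mismatch overlap wins, ties going
to the longer overlap; staggered (read-through) overlaps are accepted and
their overhangs trimmed. Restricting the competition to qualifying overlaps
is essential: otherwise a trivial one-base error-free overlap would always
outcompete the true overlap whenever the latter contains a sequencing error.
Merged qualities take the higher Phred score where the reads agree and the
higher-quality base (with its quality) at conflicts — a deliberately simple
rule; posterior-style quality arithmetic is out of scope.

`expected_error_trim()` returns the longest contiguous window whose summed
error probability $\sum 10^{-Q/10}$ is *strictly* below 0.5 (leftmost on
ties), computed by an O(n) two-pointer scan that the tests compare against
the quadratic all-substrings oracle. Thresholds phrased as "X or higher"
elsewhere are inclusive; "below X" is strict — each rule is applied literally.

After merging and trimming, reads shorter than 200 bases are dropped and the
first 2,500,000 survivors are kept (samples ending below the cap are
flagged).

## Fragment confusability

`partial_mapping_experiment()` reproduces the fragment-mapping design:
full-length sequences of each label are first collapsed by greedy clustering
at 95% identity (length-descending insertion order, ties by id — the CD-HIT
scheme), then 10 fragments each of 40/60/80/100 aa are cut at uniform random
positions from every representative and globally aligned to all
representatives. A fragment whose hit set (identity ≥ threshold) contains the
opposite label is an *incorrect* mapping; fragments with no hits are
*unmapped* and excluded from the rate denominator (the correct/incorrect
dichotomy is defined only over mapped queries).

`window_confusion_profile()` is the MSA-window variant: 40-column windows at
starts 31, 71, …, 271 are cut from a protein MSA, degapped per row (rows
retaining < 20 residues are excluded — a floor that prevents degenerate
few-residue alignments; config-exposed), and an identity network is built per
window. A node directly connected to the opposite label is *confusing*.

### Calibrating the synthetic family

The generator (`gen_protein_family()`) uses a two-clade star topology — the
only properties the experiments need are controlled within- and between-clade
divergence — with per-site substitution probability $1 - e^{-d}$ per branch.
Defaults are 20 + 20 sequences of 300 aa, within-clade divergence 0.05 and
between-clade divergence **0.10** expected substitutions per site. The
between-clade value was chosen so that cross-clade full-length identity
(~0.90) straddles the 0.90/0.95 mapping thresholds, which is the regime
real true/pseudo NifH pairs occupy: substantial incorrect mapping at the 90%
threshold, markedly less at 95%, and rates that fall as fragments lengthen.
At a between-clade divergence of 0.3 or more the clades sit near 74%
identity, no fragment crosses either threshold, and every rate is zero — a
regime that says nothing about marker specificity. Divergences are
config-exposed for users who want other regimes.

## Metagenome screen

The two-stage screen mirrors translated-homology practice at desk scale:

1. **Stage 1** aligns every translated fragment against a small nitrogenase
   panel (nifH true/pseudo representatives plus nifD/nifK); a read is a
   candidate when any fragment reaches 50% identity over ≥ 30
   non-terminal-gap columns.
2. **Stage 2** re-aligns candidates against the full panel including decoy
   homologs (e.g. chlorophyllide-reductase-like sequences); the
   best-identity reference's group wins (ties: higher score, then reference
   id), with a 60% identity floor.

E-value cutoffs are replaced by these identity/length thresholds by design: a
desk-scale reference panel invalidates database-size-dependent E-value
statistics. The floors are conservative and config-exposed.

Reads assigned to *nifH* are then classified against the typed full-length
NifH references: hits within 95% of the best identity (multiplicative,
inclusive; a subtractive variant is available in config) are retained, and
the verdict is **true** if only T1/T2 references remain, **pseudo** if only
T3, **ambiguous** otherwise. T2 counts as a true anchor alongside T1. The
**overestimation factor** is (true + pseudo + ambiguous) / true — the factor
by which *nifH*-based diazotroph abundance would be inflated; it is undefined
when no read is true.

**Proportionality test.** If two genes are equally represented per genome,
their read counts should be proportional to gene lengths (defaults: *nifH*
1,497 bp, *nifD* 894 bp — ratio 0.597; *nifK* is not printed in the source
material and defaults to a typical 1,560 bp, config-exposed). Each count gets
an exact Poisson CI at level 0.99 (`lower = χ²(α/2; 2x)/2`, zero at x = 0;
`upper = χ²(1−α/2; 2x+2)/2`), and a sample *deviates* when the CI rectangle
misses the through-origin line with slope `len_b/len_a`. Under
length-proportional Poisson simulation the deviation rate is far below the
nominal 2% bound (two 99% intervals).

## The synthetic-data generator

`gen_genomes()` emits annotated genomes realizing five layouts (operonic T1,
split T2 — including a partner on a plasmid, T1 + extra distant T2 copy,
stand-alone T3, and no-nif), with decoy CDSs drawn from a fixed non-nif
vocabulary and random strands; decoys inserted between nif genes are forced
onto the nif strand so the intended same-strand offsets hold exactly.
`gen_metagenome()` back-translates source proteins with uniform synonymous
codons (codon bias is irrelevant to the amino-acid-space computations
downstream), fragments them into fixed-length inserts, and sequences both
ends with substitution errors drawn from a linear-decay Phred model —
substitutions only, emulating Illumina chemistry, since frameshifting
platforms are out of scope. Every generator is a pure function of its spec
and seed, and every emitted record carries a truth label.

What the generator does **not** emulate: realistic community abundance
distributions, chimeras, platform-specific error profiles, indels,
within-operon gene order variation beyond the five layouts, and annotation
noise (wrong symbols/products). Passing recovery tests therefore demonstrate
the pipeline's logic, not robustness to real annotation or sequencing
pathology.

## Problem sizes and verification

The shipped tests and the acceptance script run at sizes chosen for quick,
deterministic verification: 1,000 fuzzed genomes for the typing oracle, 100
random ≤ 8-mer pairs against exhaustive alignment enumeration (plus an
independent cross-check of scores against `Biostrings::pairwiseAlignment`),
200 reads against the quadratic trimming oracle, three seeds of the 20 + 20
fragment experiment, a 10,000-pair metagenome with design mix
true 0.2 / pseudo 0.1 / background 0.7 from well-separated clades
(within 0.02 / between 0.50), and 10,000 Poisson draws for CI calibration.

## Known limitations

* Taxonomy is genus/species strings; there is no taxonomy-tree resolution,
  and the phenotype crosswalk supports genus-level wildcards only (no
  family-and-above records).
* The aligner is exact O(nm) dynamic programming with no heuristic seeding;
  it is meant for desk-scale panels, not database-scale search.
* Merge quality arithmetic at conflicts keeps the winning base's quality
  rather than a posterior estimate.
* HMM reannotation, structure prediction and assembly-based operon
  reconstruction are out of scope; a second annotation column can be supplied
  but is not searched.
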