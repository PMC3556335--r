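# DeNovoTriage

Post-assembly inference for cultivar transcriptomics. When the transcriptome
of a grapevine cultivar (or any crop accession) is assembled de novo and then
compared against a reference genome, the interesting biology lives in the
disagreements: transcripts whose exon–intron structure differs from the
annotation, loci transcribed in non-annotated regions, genes private to the
cultivar and absent from the reference, and polymorphisms that disrupt
annotated proteins. `DeNovoTriage` implements the full decision chain that
turns aligner, variant-caller and BLAST output into those classifications,
together with berry-development expression profiling, and ships a seeded
synthetic-study generator with machine-readable planted truth so every
decision rule is testable end to end.

## What it computes

**Variant filtering and coding-effect projection.** Called polymorphisms are
kept iff read depth ≥ 5, call quality ≥ 80 and alternative-allele frequency
≥ 0.75 (all inclusive). Kept variants are classified by genomic region
(splice site > CDS > UTR > intron > intergenic) and, within CDS, by
translating the mutated coding sequence: synonymous, missense, stop gain,
stop loss, frameshift or in-frame indel. Gene-level roll-up distinguishes
proteins *potentially changed* (substitutions only) from *potentially
destroyed* (frameshift, premature stop, stop loss, splice-site mutation).

**Contig triage.** Assembled contigs are greedily clustered (identity > 90%
over 100% of the shorter sequence, longest representative retained), gated on
spliced-alignment identity and coverage (≥ 90% each), split away as chimeras
when two segments ≥ 20% of the query land on different chromosomes, strands,
or > 1 Mb apart, stripped of single exons, exon fragments and partial introns,
and assigned to annotated loci by maximal exonic overlap — detecting adjacent
genes *merged* by read-through transcripts. Within each locus, the
fraction-of-major-isoform (FMI) filter discards contigs expressed below 5% of
the locus's major isoform as incompletely spliced pre-mRNA. Survivors are
compared to the annotation by their intron chain: an exactly matching chain is
an *identical isoform*, anything else a *novel isoform*.

**Novel loci and private genes.** Contigs in non-annotated regions descend a
decision tree: transposon-protein similarity → transposon-like; positive
coding potential (a transparent ORF-fraction + codon-bias heuristic standing
in for an SVM classifier) → coding with full or partial ORF; protein
homology → homology-supported; RNA-family hit → RNA-family-like; else
putative ncRNA. Unmapped contigs are triaged by homology evidence (E ≤ 1e-5,
query coverage ≥ 20%): a non-plant best protein hit marks a contaminant; a
match to the reference's raw sequencing reads marks a gap in the reference
assembly rather than a truly private gene; plant-database matches nominate
private-gene candidates, which are clustered into putative private genes by
shared subjects and mutual similarity.

**Expression profiling.** FPKM with count-scale confidence intervals and the
expressed rule (CI lower bound > 0 and FPKM > 0.001); median-of-ratios size
factors; an exact-style negative-binomial test between adjacent berry stages
(post fruit-set → pre-ripening → post-harvest withering) with
method-of-moments dispersion and across-feature sharing; moderated fold
changes; assignment of significant genes (FDR ≤ 0.05, |log2FC| ≥ 1) to four
development profiles — repressed, transiently repressed, transiently induced,
induced — and hypergeometric term enrichment per profile with
Benjamini–Hochberg control.

## Worked example

```r
library(DeNovoTriage)

# mate spacer geometry for a 310 bp library sequenced with 100 bp reads
estimateInsertGeometry(310, 189, 100)
#> $spacer_mean
#> [1] 110
#> $spacer_sd
#> [1] 189

# a complete synthetic study with planted truth, then full contig triage
cfg <- simulationConfig(seed = 1)
study <- simulateStudy(cfg, "study")
tr <- triageContigs(names(study$contigs$contigs), study$contigs$alignments,
                    study$annotation, study$contigs$expression)
tr$class_counts
#> identical_isoform     novel_isoform pre_mrna_filtered  fragment_removed
#>                23                13                 8                 5
#>  chimera_excluded     repeat_region       novel_locus          unmapped
#>                 5                 3                16                22

um <- triageUnmapped(
  study$contigs$contigs[tr$calls$contig_id[tr$calls$class == "unmapped"]],
  study$contigs$hits)
table(um$class)
#>                  contaminant        missing_from_assembly
#>                            6                            2
#> missing_from_assembly_coding                  no_evidence
#>                            3                            3
#>            private_candidate
#>                            8
```

The 95 simulated contigs partition into the eight triage classes; the 13
novel isoforms include the 3 read-through contigs that merge adjacent genes
(flagged in `tr$calls$merged`), and the 22 unmapped contigs split into
contaminants, reference-assembly gaps, private-gene candidates and
evidence-free sequences — matching the generator's planted truth exactly.

A shell front end with the same stages is installed at
`inst/scripts/triage.R` (subcommands `simulate`, `variants`, `contigs`,
`unmapped`, `express`, `run`).

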