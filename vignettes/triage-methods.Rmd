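---
title: "Methods: contig triage, variant projection and expression profiling"
author: "DeNovoTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contig triage, variant projection and expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
tunable parameters have the defaults they have, what the synthetic-data
generator does and does not emulate, and where the design was genuinely open.

## The setting

A cultivar's transcriptome is assembled de novo from RNA-seq reads and then
confronted with the reference genome of the species. Three families of
question follow. First, *sequence variation*: which called polymorphisms are
trustworthy, and what do they do to annotated proteins? Second, *structural
novelty*: which assembled contigs reproduce annotated transcripts, which are
novel isoforms, which are assembly artifacts (chimeras, fragments,
incompletely spliced pre-mRNA), which sit in non-annotated regions, and which
cannot be placed on the reference at all — contamination, gaps in the
reference assembly, or genuinely cultivar-private genes? Third, *expression
dynamics*: how do genes, including the novel and private ones, behave across
berry development and post-harvest withering?

The package implements the complete inference chain downstream of the heavy
external tools. Read alignment, assembly, spliced alignment, variant calling
and BLAST searches are consumed as files in their standard formats
(FASTA, GFF3, BED12 with two extension columns, VCF 4.x, tabular hits);
nothing here re-implements an aligner.

## Coordinate conventions

Internally all features are 1-based closed `GRanges`/`IRanges`, the
Bioconductor convention; interval arithmetic (overlap, set difference,
coverage) is delegated to `IRanges`, which is exactly the machinery that
makes off-by-one errors a non-issue. Converters at the I/O boundary respect
each format's native convention: GFF3 and VCF are 1-based closed on disk,
BED12 half-open 0-based. Read-then-write round-trips are identities on
canonical records, and every reader reports how many records were read, kept
and rejected — nothing is dropped silently.

## Variant filtering and effect projection

`filterVariants()` keeps a record iff depth ≥ 5, call quality ≥ 80 and
alternative-allele frequency ≥ 0.75, all inclusive — the thresholds under
which the study's variant set was defined. The frequency comes from the
caller's `AF` field when present, else `AO/(AO+RO)`; the caller-reported
value is authoritative.

`classifyVariantRegion()` resolves each variant against every overlapping
transcript. A position inside an intron within 2 bp of either boundary is a
splice-site variant: the window is the canonical donor/acceptor dinucleotide
(GT..AG), a choice the category name implies but no printed value fixes.
When several transcripts of a gene disagree, the most severe region wins
(splice site > CDS > UTR > intron). Exonic positions of CDS-less transcripts
are treated as span-level (intron-tier) hits, since none of the coding
region classes applies.

`annotateCodingEffect()` projects substitutions by translating the reference
and mutated spliced CDS and comparing proteins: a new in-frame stop before
the terminal codon is a stop gain, loss of the terminal stop a stop loss,
any other amino-acid change missense, none synonymous. Length-changing
alleles are classified arithmetically: length difference not divisible by 3
is a frameshift, otherwise an in-frame indel. Multi-nucleotide substitutions
are decomposed per base and the most severe consequence reported. A
reference CDS whose spliced length is not a multiple of 3 raises an error:
that is an annotation fault, not a variant property. Gene-level impact
takes the most severe consequence over all transcripts: frameshift, stop
gain/loss or splice-site → *potentially destroyed*; else missense or
in-frame indel → *changed*.

## Contig triage

**Clustering.** Assembly redundancy is removed greedily: contigs sorted by
length descending (ties by id), each joining the first representative that
aligns with identity strictly above 0.90 over 100% of the shorter sequence.
A shared-31-mer pre-screen skips hopeless pairs; at these thresholds a
qualifying alignment of any sequence long enough to matter shares a 31-mer
with its representative, and the test suite checks equality with the
un-screened quadratic algorithm.

**Gating and chimeras.** A contig maps iff its best single alignment segment
reaches 90% identity and 90% query coverage (inclusive). The chimera rule is
explicit and reproducible where the original relied on an aligner-internal
flag: at least two segments, each covering ≥ 20% of the query, on different
chromosomes, different strands, or more than 1 Mb apart.

**Structure filter.** Multi-block alignments are retained. Single blocks are
removed as *single exons* (match an annotated exon within ±10 bp per end —
slack absorbing assembly end errors), *exon fragments* (inside an exon), or
*partial introns* (> 50% of the block inside an annotated intron); a single
block in a non-annotated region survives as a potential novel single-exon
locus only at ≥ 200 bp, the assembler's minimum contig length. "Exon
fragment" and "partial intron" are workflow terms with no standard
operational definition; these rules are the package's explicit stand-ins.

**Loci.** Contigs attach to the annotated gene with maximal exonic overlap on
the same strand (any strand for unstranded alignments). Overlapping exons of
two or more genes creates a synthetic merged locus — the read-through
signature by which adjacent genes erroneously split in an annotation are
found. Gene-less contigs overlapping annotated repeats are repeat-region
calls; the rest group into novel loci by single-linkage span overlap.

**FMI.** Within a locus, any contig expressed strictly below 5% of the
locus's most-expressed contig is discarded as pre-mRNA; the major isoform is
always kept, and 5.0% exactly survives ("fell below" read literally).
The threshold is configurable because raising it to 10–15% measurably hurts
recovery of protein-coding genes. Per-contig expression is consumed as an
externally supplied FPKM table; how reads are reassigned across isoforms is
upstream of this package.

**Isoform comparison.** The intron chain — the ordered intron intervals
implied by the alignment blocks — is compared exactly against each reference
transcript at the locus: equality means identical structure, anything else a
novel isoform. Single-block contigs at multi-exon loci are novel isoforms;
at a single-exon locus both chains are empty and the contig is identical.

## Novel loci and the unmapped set

Coding potential replaces an SVM classifier with a transparent two-signal
heuristic: the fraction of the sequence covered by the longest ORF
(6-frame scan; ORFs are *full* with ATG and in-frame stop, else partial;
minimum 33 codons ≈ 100 nt, the common convention) and the codon-usage bias
of that ORF, measured as KL divergence from uniform with the small-sample
expectation `(k-1)/(2N ln 2)` subtracted so random sequences score near
zero. The score is `0.6·min(1, orfFrac/0.8) + 0.4·min(1, KLadj/0.5)`; coding
means score ≥ 0.5 with a qualifying ORF. The decision tree, not the
classifier internals, is the scientific content; the tree itself is:
transposon hit → transposon-like (checked first, so transposon evidence
outranks an ORF); coding → full/partial ORF coding (full wins if *any*
qualifying full ORF exists — chance stop-free partial frames on the opposite
strand can be longer than a genuine ORF); protein homology → homology
supported; RNA-family hit → RNA-family-like; default → putative ncRNA.

Unmapped contigs are triaged in a fixed order on hits pre-filtered at
E ≤ 1e-5 and query coverage ≥ 20%: (1) best protein-database hit with taxon
outside Viridiplantae → contaminant, with equal-best conflicts resolved
conservatively to contaminant; (2) match to the reference's raw read pool →
missing-from-assembly (a reference gap, *not* a private gene), sub-classed
coding when the coding call is positive; (3) plant-database match → private
candidate; (4) otherwise no evidence. Private candidates cluster by single
linkage over two edge types — shared best subject, or direct alignment at
identity > 0.9 over ≥ 80% of the shorter — because private genes were defined
by similarity to expressed-sequence and plant-protein databases, and either
route establishes that two contigs describe one gene.

## Expression profiling

FPKM = count / (exon-model kb × mapped millions), with a 95% CI built on the
count scale (`count ± 1.96√count`, floored at 0; a zero count receives the
upper bound 1.96² so absence still has an interval) and rescaled. A feature
is expressed iff the CI lower bound is strictly positive and FPKM > 0.001.

Differential expression re-implements a documented, simplified NB pipeline —
parity with any specific package's numbers is not claimed; calibration is
established by simulation instead. Size factors are median-of-ratios over
features nonzero in all samples. Dispersion is a pooled within-group
method-of-moments estimate floored at 1e-8; because at 2–3 replicates that
estimate is extremely noisy and its low tail makes an exact test
anti-conservative, each feature's value is additionally floored at the
across-feature median (the "maximum" sharing rule long used at low
replication) whenever at least 20 expressed features are available. The test
itself conditions on the total: the two group sums are modelled as NB with
moment-matched mean and size under the null of equal normalized means, and
the two-sided p sums the probabilities of all splits at most as probable as
the observed one. Measured on 1000 null features (dispersion 0.1, 3 vs 3)
the type-I error is ≈ 5–6.5% at nominal 5%, and power for 8-fold changes at
mean 200 exceeds 95% — both re-measured by `scripts/acceptance.R` at run
time.

Fold changes for clustering are moderated by a shifted log —
`mean log2(normalized + 8)` per group, differenced — playing the role of a
variance-stabilizing transformation: it damps low-count fold changes and
converges to the raw log-ratio at high counts. The two adjacent-stage
contrasts (PFS→PR, PR→PHWII) drive profile assignment via signed
significance (FDR ≤ 0.05 and |log2FC| ≥ 1): down/down, down/flat, flat/down
are *repressed*; down/up *transiently repressed*; up/down *transiently
induced*; up/up, up/flat, flat/up *induced*; flat/flat unclustered. The
default FDR threshold is 5% (0.05); workflows of this kind are sometimes run
at a far stricter 0.05%, and the threshold is configurable for that reading.
The census of
"modulated in at least one sample" may additionally consult the PFS→PHWII
contrast, but cluster assignment never does — the four patterns are defined
on the two adjacent steps. Enrichment is the one-sided hypergeometric upper
tail per (profile, term), BH-adjusted within profile, enriched iff adjusted
p < 0.05; the term map is used as given, with no ontology-graph propagation.

## The synthetic study

The generator emits a complete study from one seed: identical runs are
byte-identical. Defaults: 2 chromosomes × 500 kb, 60 genes of 3–5 exons with
valid ATG…stop CDS (length divisible by 3, GT..AG introns, both strands,
codon usage drawn from a skewed distribution so planted coding sequence
carries the bias real coding sequence has); per triage class, planted
contigs (15 identical isoforms, 10 exon-skipping novel isoforms, 8 pre-mRNA
pairs at 2% of their major isoform, 5 cross-chromosome chimeras, 3
read-through merged pairs, 5 fragments cycling the three removal rules, 3
repeat copies, 16 novel loci across the five tree leaves, 8 private
candidates in 5 clusters, 5 reference-gap genes with a tiling raw-read pool,
6 contaminants at the observed taxon mix, 3 evidence-free contigs); 25
variants of each of the 8 effect classes engineered at the codon level
(genetic-code facts, independent of the projection code under test) plus 18
sub-threshold records each failing exactly one filter, with the first
variant of each class carrying the exact inclusive boundary (5 / 80 / 0.75);
NB counts for 3 stages × 3 replicates at mean 200 and dispersion 0.05, with
profile patterns realized as ×8 / ×⅛ stage multipliers. The default contig
substitution error rate is 1%; alignments are emitted from generative truth
(the aligner is out of scope — triage logic, not alignment, is under test),
so substitution noise perturbs sequences and the identity column but not
block coordinates, and an optional edge-jitter mode perturbs block ends to
exercise the ±10 bp structural tolerance.

What passing therefore shows: the decision rules are implemented exactly as
specified, recover planted truth perfectly when evidence is clean, and
tolerate sequence-level noise. What it does not show: behavior under real
aligner artifacts (soft-clips, misplaced splice junctions), real coverage
biases, polymorphism between cultivar and reference beyond engineered sites,
or real databases' taxonomies — the generator's homology evidence is
schematic (one label per hit), and its expression table for the FMI filter
is planted rather than quantified from reads.

## Problem sizes and runtime choices

The shipped test-and-acceptance sizes were chosen so a complete run is
comfortable on one CPU: the default study (95 contigs, 218 variants, 60
genes) exercises every class; predicate fuzzing uses 10⁴ records; NB
calibration uses 1000 null features and a 500-feature power set; brute-force
oracles (quadratic clustering, per-base coverage counting, exhaustive
six-frame ORF scans) run on instances of at most a few hundred units, the
scale at which exhaustive computation is still exact and fast.

## Known limitations

Structural tolerances (±10 bp, 50% intron overlap, 200 bp novel minimum) are
explicit stand-ins where the original workflow delegated to tool internals.
The coding-potential heuristic is deliberately simple; sequences with weak
codon bias and mid-length ORFs near the 0.5 score boundary will be called
inconsistently with a trained classifier. The NB test shares dispersion
across features by a global median rather than a fitted mean–dispersion
trend, adequate at these scales but crude for strongly
expression-dependent dispersion. MNV decomposition evaluates each base
independently, so a codon changed at two positions is classified by the more
severe single-base path, not by the joint codon substitution.
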