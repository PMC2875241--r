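---
title: "Remapping microarray probes to the transcriptome: methods and design"
author: "ProbeRemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remapping microarray probes to the transcriptome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProbeRemap)
```

## The problem

Expression microarrays report hybridization signal from short
oligonucleotide probes, typically 25 nt. Vendors group probes into
"probesets" and most analyses treat probesets as synonyms of genes, but
genome annotation moves on: gene models are merged and split,
transcripts and noncoding RNAs are added, and a probe designed years ago
may today sit in an intron, span an exon-exon junction, cross-hybridize
with several loci, or measure a noncoding RNA that the probeset label
never mentions. ProbeRemap re-derives the probe-to-entity assignment
from sequence alone: every probe is matched full length, with zero
mismatches, against the spliced transcriptome and downstream targets,
placed back onto the genome, and regrouped into summarization units at
gene, transcript, exon and ncRNA level.

## The mapping cascade

Matching is exact and full length throughout — a 25-mer either occurs
verbatim in a target or it does not. This is deliberately stricter than
heuristic alignment: perfect-match-only semantics make seed-and-extend
machinery unnecessary, and an exact hash index over target k-mers
(`buildIndex()`) returns the identical hit set a naive scan would, which
the test suite verifies against an independent `matchPattern()` oracle.
Both orientations are searched by default (`searchRevcomp = TRUE`),
because vendor probe-sequence files differ in strand convention;
reverse-complement hits are flagged, so a sense-only analysis can filter
them. Probes containing any ambiguity code (N) can never match.

`classifyProbes()` applies a fixed cascade; a probe enters a stage only
if every earlier stage produced zero hits:

1. **mRNA** — spliced sequences of protein-coding transcripts;
2. **ncRNA (annotation)** — spliced sequences of noncoding-biotype
   transcripts;
3. **ncRNA (external)** — an optional external ncRNA collection;
4. **intron** — pre-mRNA locus sequences, counting only hits that fall
   wholly outside the exons of every transcript of the locus; such
   intron-only probes are classified `intronic_putative_ncRNA`, since
   they may measure putative exons of unannotated isoforms;
5. **NA** — no qualifying hit anywhere.

Known RNAs therefore always take precedence over intronic placement.
The relative order of stages 2–4 is a design choice of this package
(annotation ncRNAs before the external collection, both before
introns); it follows from treating annotated RNAs as stronger evidence
than an external compilation, and either ncRNA source as stronger than
an intron-only placement. Intron detection uses the pre-mRNA locus
sequence rather than a whole-genome scan, so intergenic sequence is
never a mapping target.

Ambiguity is recorded at three levels: `gene_unique` (exactly one gene
locus), `transcript_specific` (exactly one transcript), and
`exon_specific` (exactly one exon, and not junction-spanning). A hit
whose transcript interval crosses an exon boundary projects to more
than one genomic block; such probes get `junction = TRUE`, contribute
no exon ids, but remain evidence for their transcripts. Multiple
occurrences of a probe within one target collapse to a single
membership with a `multi_hit` flag. The four-color display code is a
documented convention of this package (the upstream resource defines
its colors only in help pages): green = gene-unique and
transcript-specific mRNA, yellow = gene-unique but multi-transcript,
red = multi-locus (cross-hybridizing), black = everything that is not
mRNA.

## Coordinates

Internally all intervals live in `GRanges`, i.e. 1-based closed
coordinates, the Bioconductor convention; GTF/GFF3 input (1-based
inclusive) is read without shifts, and all interval arithmetic is
delegated to IRanges/GenomicRanges. Exon `rank` is 1 for the 5'-most
exon in transcript orientation; minus-strand spliced sequences are the
reverse complement of the genomic concatenation. `projectToGenome()`
and `genomeToTranscript()` are exact inverses at single-base
resolution, a property the suite asserts for every base of every
fixture transcript. Locus span is the exon hull (no UTR extension
beyond annotated exons), matching the usual annotation convention.

## Probe sets and statistics

`buildSets()` regroups probes using only unambiguous evidence:
gene-level sets take gene-unique mRNA probes; transcript-level sets let
a probe appear in every transcript of its unique gene that it hits;
exon-level sets take non-junction exon hits; ncRNA-level sets pool
external-collection and annotation ncRNA targets with intron-only
probes keyed by their host locus. `min_probes` defaults to 1 — no
minimum is imposed beyond non-emptiness — and is a configurable knob.
`writeMappingFiles()` emits the flat text analogues of the classic
remapping downloads (probes2genes, probes2transcripts, probesets2genes,
ambigprobes2genes, and one set-definition file per level). A documented
TSV dialect stands in for the binary vendor chip-definition format; the
information content is identical. The probesets2genes file resolves a
vendor probeset to a gene only when all of its gene-unique member
probes agree (unanimity — the strictest reading of "unambiguous");
discordant probesets are dropped and logged.

**Coverage** is the percentage of annotation entities (genes or
transcripts) hit by an array's probes; **efficiency** is the percentage
of an array's probes hitting at least one entity, split into
exactly-one versus more-than-one (ambiguous). "Unique mapped" counts
entities targeted by at least one probe that maps nowhere else at that
level; a strict mode requiring *all* probes of the entity to be
unambiguous is provided (`strict = TRUE`), since published definitions
can be read either way. All percentages are rounded half-up to two
decimals and printed with decimal points (locale-neutral). Intron-only
probes do not mark their locus as covered: they are classified as
putative ncRNAs, not as gene hits.

## Expression summarization

`summarizeSets()` computes, per entity and sample, the log2 of the
arithmetic mean of member-probe intensities on the linear scale — the
literal reading of a "log2 of the mean of all probes" global signal.
The common alternative, mean of per-probe log2 values, is available via
`scale = "log2"`. Means are clipped at a floor (default 1.0, the
smallest intensity treated as signal) before the log so that all-zero
probe vectors stay finite; clipping is logged. Two exact properties
follow and are tested: doubling all intensities of a set adds exactly
1.0 log2 unit, and the result is invariant under probe order and
equivariant under sample permutation.

## The synthetic fixture generator

No public genome-scale inputs are bundled; instead `simulateFixture()`
builds a complete input set — genome FASTA, GTF annotation, external
ncRNA FASTA, probe TSV — with a planted per-probe ground truth, so the
whole pipeline is testable end to end and offline. Seven probe classes
are planted by construction:

- `exonic_unique` — exon interiors of single-transcript loci;
- `junction` — reads across a splice boundary of the spliced sequence;
- `multi_transcript` — interiors of exons shared by several transcripts
  (multi-transcript loci are built by skipping one internal exon per
  alternative transcript);
- `multi_gene` — a probe's genomic sequence copied into an exon of a
  second, dedicated locus;
- `intronic` — intron interiors, wholly outside every transcript's
  exons;
- `ncrna_db` — interiors of the external ncRNA sequences;
- `unmapped` — random sequences rejection-sampled until absent from
  every mapping target in both orientations.

Defaults describe the study conditions used throughout: 20 loci (15%
noncoding), 2–4 transcripts per multi-transcript locus, 4–6 exons of
80–120 nt, introns of 60–200 nt (kept short for desk-scale speed),
25-mer probes, and a 200-probe plan spanning all seven classes.
Nucleotide composition is uniform ACGT. With ~100 kb of target sequence
and a 4^25 sequence space, accidental collisions between planted
25-mers and unrelated targets are vanishingly unlikely; the generator
nevertheless verifies the classes with hard constraints (rejection
sampling for unmapped probes, an explicit collision check for intronic
probes) and fails loudly rather than emit an impure fixture. What the
fixture does *not* emulate: repeats, paralog families beyond the
planted duplications, GC skew, sequencing-style error — so a passing
suite demonstrates correctness of the mapping logic, not robustness to
the full messiness of real genomes.

`simulateIntensities()` supports testing the summarization path: probe
intensity is `baseline * effect * exp(N(0, noiseSd))`, i.e. log-normal
probe noise around an entity mean. At a 2-fold effect and
`noiseSd = 0.2` (log-e units, a realistic probe-level CV of ~20%),
entities with the effect separate from null entities by summarized
signal difference in essentially every seeded run; the acceptance suite
requires at least 95 of 100.

## Numerical and degenerate-input choices

- Percent rounding: half-up (with a 1e-9 guard against binary float
  representation), two decimals for tables, one for quoted fractions.
- Hit ordering: all outputs sorted by probe id, target id, offset and
  orientation, so repeated runs are byte-identical.
- GC content counts G+C over the full sequence length; ambiguous bases
  count in the denominator only.
- Empty target sets, unindexed probe lengths, a missing genome, or a
  total probe count below the mapped count are configuration/validation
  errors, not silent results.
- Probesets whose gene-unique members disagree are dropped from
  probesets2genes (and logged), never resolved by majority.

## Problem sizes

The suite and the acceptance script run the default 20-gene / ~200
probe fixture (about 60 kb of genome), a 100-probe x 50-target oracle
comparison, full-transcriptome round-trip checks (~18,000 bases), and
100 seeded intensity simulations; these sizes were chosen as the
smallest at which every planted class, both strands, junctions and all
ambiguity patterns co-occur.

## Known limitations

- Perfect-match only: no mismatch-tolerant or gapped matching and no
  hybridization thermodynamics, so near-matches that cross-hybridize in
  practice are invisible here.
- The cascade assigns one category per probe; probabilistic
  multi-mapping resolution is out of scope.
- Coverage/efficiency reproduce published genome-scale values only when
  fed the corresponding published counts; recomputing them from raw
  vendor probe files and a full annotation requires those external
  inputs.
- The color code and the stage order within the ncRNA/intron part of
  the cascade are documented conventions of this package, configurable
  where noted.
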