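---
title: "Methods: six-frame search databases, PSM filtering and annotation-relative classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-frame search databases, PSM filtering and annotation-relative classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopept)
```

This vignette documents the models, rules and design choices behind
`genopept`, in the order the pipeline applies them. It is the package's
methodological reference: every rule stated here is the one the code
implements and the test suite checks.

## Coordinates and conventions

All internal coordinates are **1-based closed intervals on the forward
genome strand** — the native convention of IRanges/GenomicRanges and of the
GFF3/GTF inputs, so no conversion happens at parse or write boundaries.
"5′" and "3′" always refer to transcript orientation. Reading-frame numbers
are the 0-based offset of the first translated base on the reading strand;
reverse-strand frames are offsets into the reverse complement, which makes
the coordinate arithmetic of `segment_to_genomic()` symmetric between
strands.

Translation uses the standard genetic code only. The first codon is not
treated as an initiator (an alternative start codon like `TTG` translates
to its plain amino acid: frame translations are not proteins). Any codon
containing an ambiguity (`N`) translates to `X`; stop codons are kept as
`*` in database segments, and peptide matching can never cross one because
accepted peptides are `*`-free by construction.

## The gene model

`parse_gff3()` builds a strand-aware gene model from either of two
annotation dialects. The NCBI-like dialect carries
gene/mRNA/exon/CDS features and UTRs are **derived** as the exonic bases
outside the CDS, split 5′/3′ of the CDS in transcript orientation. The
Ensembl-like dialect may carry explicit `five_prime_UTR`/`three_prime_UTR`
features, which then override the derivation — mirroring the real
difference in how the two annotation pipelines publish UTRs. Three
structural rules are enforced at construction:

* exons of one transcript are stored sorted and must not overlap
  (overlap is an error, not a merge — malformed input should fail loudly);
* the CDS must lie within the exon union;
* CDS reading-frame phases are **recomputed from CDS geometry** by walking
  the spliced CDS 5′→3′ and assigning each base its position within the
  codon (0/1/2). The GFF3 phase column is ignored: recomputation gives a
  single, testable source of truth.

Interval lookups go through `build_interval_index()`, a thin wrapper over
`GenomicRanges::findOverlaps`. Its contract — and the property the tests
enforce on randomized fixtures — is exact agreement with a naive all-pairs
overlap scan.

## The six-frame search database

Genome-scale six-frame searching is impractical for spectrum search
engines both for memory and because E-values are calibrated to database
size. The database is therefore partitioned: each frame translation is cut
into segments of `seg_len` amino acids (default **600**) starting every
`seg_len − overlap` positions (default overlap **60**), and segments are
grouped `per_file` (default **50 000**) entries per FASTA file. The overlap
guarantees that every peptide of up to `overlap` residues occurs intact in
at least one segment; the final segment is emitted whenever it extends
coverage, with no minimum length, so coverage is total. Segment headers
(`sf|chrom|strand|frame|aa_start`) make every database hit reversible to a
genomic interval; the round trip genome → segment → coordinates → genome is
tested as an exact identity.

Decoy databases are **per-entry uniform residue shuffles** (seeded,
deterministic), preserving each entry's length and composition — the
randomized-database decoy appropriate for E-value-scored searches.
Reversal was rejected because a reversed database preserves local
composition statistics less faithfully under tryptic-like matching.

## PSM filtering

The acceptance rules, applied in order:

1. **E-value threshold** `evalue_max = 0.01`, *inclusive* (a match at
   exactly 0.01 is accepted).
2. **Per-spectrum best match**: when one spectrum matches several peptide
   sequences — across database partitions and across the protein and
   genome search spaces — only the lowest-E-value match survives. Ties
   break deterministically (lexicographically smallest peptide, then
   smallest partition id), so filtering is order-independent and
   idempotent. Deduplication is grouped by (decoy flag, engine, tissue,
   spectrum): each engine keeps its own best match per spectrum. Collapsing
   across engines would make the next rule unsatisfiable for
   single-spectrum hits, since a lone surviving PSM carries one engine
   label; the per-engine grouping is what makes "confirmed by both
   engines" observable.
3. **Spectral-count rule**: after aggregation to peptide-level hits,
   single-spectrum identifications are rejected unless identified by at
   least two distinct engines. The engine field is a free label and the
   rule requires ≥ 2 distinct labels. The rule is applied *after* combining
   protein- and genome-search results (the alternative ordering is a
   documented switch point, not a default).

**FDR** is `100 · accepted decoys / accepted targets`, reported to two
decimals. The simplest decoys/targets estimator was chosen over
`2d/(t+d)` because decoy searches run as a separate stream through the
identical filter path and because the estimator admits an exact 0.00%
lower bound. Decoy PSMs never compete with target PSMs for a spectrum
(separate searches), which is why the decoy flag is part of the
deduplication key. Peptide equality is exact string matching throughout —
isoleucine and leucine are **not** collapsed; exactness is testable and
any collapsing convention can be applied upstream.

## Peptide mapping and the ten categories

`map_peptides()` matches peptides against **full-chromosome** frame
translations, not the 600-aa segments: segments are a search-engine
artifact, and matching the full frames guarantees segment boundaries can
hide nothing. Matching is literal character equality (an `X` in the
translation matches only an `X` in the peptide — determinism over
cleverness). Peptides mapping to more than one genomic locus are set aside
by `filter_unique_locus()`; peptides occurring as substrings of either
annotated protein set are "annotated" and leave the novel stream.

Each remaining single-locus novel peptide is classified against each
annotation by the first matching rule in a fixed, most-CDS-proximal-first
priority order:

1. `coding_out_of_frame` — overlaps ≥ 1 CDS base on the same strand with
   mismatched codon phase (an in-frame overlap was already removed
   upstream as annotated);
2. `nter_extension` / `cter_extension` — on the transcript's strand, in
   the CDS reading frame, upstream of the CDS start / downstream of the
   stop, and genomically contiguous with (abutting or overlapping) the CDS
   terminus: a frame-contiguous extension of the annotated protein;
3. `utr5` / `utr3` — wholly within (annotated or derived) UTR exonic
   intervals, not qualifying as a terminal extension;
4. `exon5_extension` / `exon3_extension` — crossing the transcript's
   5′-most / 3′-most boundary (partly inside the terminal exon, partly
   outside the transcript span) without CDS frame contiguity — the
   signature of models missing their termini;
5. `transcript_noncoding` — wholly within the exons of a noncoding
   transcript;
6. `intron` — overlapping an intron (also the conservative fallback for
   genic loci matching no specific rule, a case planted fixtures never
   produce);
7. `intergenic` — no same-strand gene overlap. Antisense-only overlap is
   intergenic: the category vocabulary has no antisense row, and inventing
   one would change the summary's shape.

When several same-strand transcripts overlap a locus, each contributes its
candidate categories and the highest-priority one wins — the most
CDS-proximal interpretation of the locus.

### The cross-annotation summary

`summarize_novelty()` tabulates, per category *c*: `both` = peptides with
category *c* under **both** annotations; `a_only`/`b_only` = peptides with
category *c* under exactly one. Row totals are the three-cell sums; row
percentages are `100·cell/total` rounded **half-up to one decimal**
(`round_half_up()`, since base R's half-to-even would change printed
values); grand totals are column sums. One consequence of this reading is
worth stating: a peptide classified differently by the two annotations
appears in two rows (A-only in one, B-only in another), so the column
grand totals need not be equal and the grand total exceeds the peptide
count by the number of discordant peptides. This is a declared semantic
choice; alternative readings of the "both/one-annotation" columns exist
but are not attempted.

## Transcript classification

Splice junctions anchor transcript identity; terminal-exon ends do not.
Concretely: terminus comparisons use a tolerance of **0 nt on splice
sites** and **unlimited slack on terminal exon ends**, separating isoform
novelty from mere end-length differences (annotations being "short at the
ends" is exactly the failure mode this classifier must not call novel).
The rules, per same-strand reference model, best category winning:

* identical ordered intron chain → `matches_annotated` (single-exon versus
  single-exon compared by exonic overlap, there being no chains);
* shares ≥ 1 intron or ≥ 1 bp same-strand exonic overlap but differs →
  `novel_isoform`, refined to `five_prime_difference` /
  `three_prime_difference` when the two chains share one genomic end and
  differ only at the other (mapped to the transcript 5′/3′ side by
  strand);
* wholly inside one annotated intron → `intronic`;
* no same-strand overlap → `intergenic`.

Novel transcripts receive `CXT.N` identifiers assigned in deterministic
(chromosome, start, end, id) order, stable under input shuffling; the
input is assumed already deduplicated by the upstream assembler/merger.
`exon_stats()` reports plain arithmetic means of exon counts per group
(displayed at one decimal), and `tissue_specificity()` reports the
detected-tissue histogram with the single-tissue fraction. The detection
threshold on abundance defaults to `> 0` and is deliberately a user
parameter: the upstream quantification imposes no cutoff, so the cutoff is
an analysis decision, not a constant.

miRNA name transfer is purely coordinate-based: a predicted feature takes
a known mature miRNA's name when both ends lie within **5 nt** on the same
strand (nearest by `|Δstart| + |Δend|`, ties broken lexicographically), or
a known primary transcript's name on any ≥ 1 bp same-strand overlap;
otherwise it keeps a novel id.

## The synthetic fixture generator

`generate_reference()` emulates the *structure* of the real inputs: a
random genome; coding genes with 3–4 exons, exonic UTR flanks of 63–117 nt
and a stop-terminated CDS whose codons are written into the genome (so
annotated proteins are stop-free); the reading frame is continued
stop-free into the UTR margins flanking the CDS, so in-frame terminal
extensions of each protein exist in the genome and the terminal-extension
categories are realizable for every gene. Dialect B differs from dialect A
by controlled edits — two genes dropped, two genes with trimmed outer
terminal-exon ends, explicit UTR features — so cross-annotation
discordance is exercised with known labels. Wide annotation-free deserts
(≥ 2 kb) between genes host intergenic plants.

`plant_peptides()` places, for each requested category, peptides whose
unique locus satisfies exactly that category's rule under the priority
order, enforcing by rejection sampling: correct length (7–15 residues by
default — tryptic-scale, without enforcing K/R termini, since cleavage
chemistry is irrelevant to mapping and classification logic), no stop or
ambiguity codon, novelty with respect to both protein sets, and exactly
one genome-wide locus. Duplicated plants write one peptide's codons at two
desert locations to exercise the single-locus filter. `simulate_psms()`
builds deliberate scenario groups (multi-spectrum; single-spectrum
dual-engine; single-spectrum single-engine; above-threshold; one spectrum
hit in three partitions) so each row's fate is known by construction
rather than by re-running the filter, and `simulate_null_psms()` draws
equal target and decoy streams from one E-value law (log-uniform over
[1e−6, 1], two spectra per peptide) so the FDR of the filtered result is
100% up to binomial error.

What the fixtures do **not** emulate: real spectra and search-engine score
distributions, homology and repeat structure, splice-junction peptides,
sequencing errors, or annotation errors more subtle than dropped/trimmed
models. Passing tests therefore demonstrate the correctness of the rules
and the arithmetic, not the biological error rates of any instrument or
annotation pipeline.

## Problem sizes and runtime

The default test and acceptance scale — 2 chromosomes × 50 kb, 10 genes,
~30 planted peptides, 10 000 target plus 10 000 decoy PSMs for the null
simulation, a few hundred randomized oracle queries — was chosen so the
entire suite runs in a few minutes on one CPU while every oracle check is
either exhaustive or has hundreds of random cases. Mapping and
classification are O(genome × peptides) at these scales; for real genomes
the same code paths apply unchanged, only slower.

## Known limitations

* Junction-spanning peptides cannot be found by genomic six-frame matching
  and are out of scope; their absence biases against `nter/cter` calls at
  spliced termini in real data.
* Standard genetic code only; no selenocysteine or programmed frameshifts;
  no trans-splicing or circular chromosomes.
* The two annotations are kept fully independent; overlapping gene models
  are not merged into loci.
* The cross-annotation summary's "both" semantics is one declared reading
  (identical category under both annotations); counts under other readings
  are not computed.
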