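---
title: "Profiling the subcellular distribution of small RNAs with srnaloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the subcellular distribution of small RNAs with srnaloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cell fractionation followed by small-RNA deep sequencing yields one library
per compartment — here, nuclear and cytoplasmic. Comparing the two asks a
deceptively simple question with a long list of bookkeeping hazards: for each
distinct small RNA sequence, how abundant is it in each compartment, what
class of RNA did it come from, and is it enriched on one side of the nuclear
envelope?

`srnaloc` implements this analysis as a reusable, tested pipeline:

1. **preprocess** — 3' adapter trimming, contaminant filters, collapsing to
   unique 16–30 nt sequences with per-library counts;
2. **map** — exact all-occurrence genome matching plus rescue stages for
   reads that are real but not genomic substrings;
3. **annotate** — a fixed-priority cascade assigning each mapped sequence
   exactly one RNA class;
4. **trailers** — calling tRNA 3' trailer small RNAs from the 40 nt
   downstream of tRNA genes and aggregating their isotrailers;
5. **quantify** — reads-per-million (RPM) normalization, nuclear/cytoplasmic
   (N/C) enrichment ratios, isomiR grouping, motif association and length
   distributions.

A seeded synthetic-data generator produces a toy genome, a matching
reference bundle and paired libraries with full ground truth, so every stage
is validated against known answers.

## The statistics

**RPM.** Each unique sequence's raw count is normalized by the library's
total *mapped* reads: `rpm = raw / mapped_total * 1e6`. Normalizing by the
mapped total (not the raw sequencing depth) means per-library RPM always sums
to exactly one million, which the tests assert.

**N/C ratio.** For a sequence with positive abundance in both libraries,
`N/C = nuclear_rpm / cytoplasmic_rpm`. Values above 1 indicate nuclear
enrichment. Sequences seen in only one compartment get an exclusivity flag
(`nuclear-only` / `cytoplasmic-only`) rather than 0 or infinity: the two
exclusive categories are biologically distinct (often low-abundance
sequences below the detection floor of one library) and are reported as
separate fractions, never folded into the numeric N/C distribution.

**Eligibility.** Ratio-level summaries are restricted to sequences whose raw
count (never RPM) is *strictly greater than* 10 in at least one library.
"More than 10" is read strictly — a sequence at exactly 10 in both libraries
is excluded — and the threshold is a parameter (`min_count`).

## The mapping contract

The mapper's contract is *every exact occurrence, both strands* — the
behavior of a short-read aligner run with zero mismatches and all-hits
reporting. It is implemented as a 16-mer hash seed with verification
extension rather than an external aligner, because the contract is then
fully specified and testable: the test suite and the acceptance script
compare `map_exact_all()` against a naive both-strand sliding-window scan on
dozens of seeded genomes and require identical hit sets. Minus-strand hits
carry the leftmost (forward-strand) coordinate, so re-extracting the
interval and reverse-complementing reproduces the query.

Genome-unmapped sequences get four rescue chances, in order:

1. exact substring of an rRNA transcription-unit sequence (the rRNA repeat
   is typically absent from genome assemblies);
2. exact substring of an exon–exon junction (flank 29 nt per side, so any
   read of at most 30 nt spanning a junction is a substring);
3. exact substring of a CCA-tailed tRNA (the CCA is added
   post-transcriptionally and is not genomic);
4. substring of a tRNA reference with exactly one mismatch, accommodating
   the heavy base modification of mature tRNAs; such records are pre-labeled
   tRNA.

The rescue order follows the order in which the stages are described in the
methods literature this pipeline models; the stages are substring tests
against disjoint reference sets, so in practice order matters only for
bookkeeping of the `via` tag. An ablation property test asserts that
disabling later stages never changes earlier outcomes.

Sequences still unmapped are checked for 3' untemplated additions: if the
*longest* genomic prefix is at least 17 nt (and shorter than the full read),
the read is split into genomic prefix + untemplated tail and the prefix
re-enters the mapped set. Searching for the longest prefix — not merely any
prefix of at least 17 nt — makes the recorded tail minimal, which matches
how 3' untemplated additions are defined. Prefix occurrence is monotone in
length, so a binary search is exact; the acceptance suite verifies it
against an enumerate-every-prefix oracle on 1,000 seeded reads.

## The annotation cascade

Classes are assigned in a fixed priority order (`CLASS_LABELS`): miRNA,
mitochondrial RNA, rRNA, ITS, ETS, box H/ACA snoRNA, box C/D snoRNA, scaRNA,
tRNA, snRNA, RNaseP, SRP RNA, Xist, 7SK, H19, vRNA, hY RNA, RNaseMRP, mRNA,
tRNA 3' trailer. A sequence is removed from the pool at its first match, so
earlier classes win ties — a read that is a substring of both a miRNA
hairpin and an mRNA is a miRNA. After the sequence-matched classes, records
whose genomic hits overlap a repeat locus by at least 1 nt become `genomic
repeat`; everything else is `unknown`. Two terminal labels are locus- and
elimination-based by construction and never matched against reference
sequences.

Design choices made where the procedure was genuinely open:

- **Match rule.** A sequence matches a class iff it is an exact sense-strand
  substring of any reference sequence of that class. This is the minimal
  reading of annotation-by-alignment for fragments derived from the sense
  strand of known RNAs; antisense-derived sRNA calling is out of scope.
- **mRNA space.** Matching uses spliced transcripts, consistent with the
  junction rescue stage (an exonic read and a junction read should be judged
  in the same sequence space).
- **Trimmed records** are matched through their genomic prefix: the tail is
  untemplated, so only the prefix carries locus information.
- **miscRNA** (7SK, vRNA, RNaseMRP, RNaseP, Xist, H19) is a reporting
  roll-up only (`composition_table(miscrna_rollup = TRUE)`); the cascade
  always uses the individual classes.
- **Composition printing.** Percentages are printed at one decimal, except
  values below 1% which carry two decimals so small classes keep a
  significant figure (0.63%, 0.08%).
- An alternative `rpm_combined` composition mode reports each class's share
  of the pooled two-library RPM; the default and the tests use per-library
  raw shares.

## tRNA 3' trailers

A pre-tRNA's 3' trailer is released by RNase Z cleavage and ends at the RNA
polymerase III terminator, so trailer small RNAs have sharp 5' ends anchored
at the cleavage site and ragged, often uridine-tailed 3' ends. The caller
encodes exactly that: a sequence is a trailer of gene *g* iff it perfectly
matches the 40-nt region downstream of *g* starting at region position 1 or
2. Region extraction is strand-aware — for minus-strand genes the 40 nt
upstream of the genomic start are reverse-complemented — because "downstream
of the gene" is only meaningful on the gene strand. Regions truncated by a
chromosome end are kept and flagged.

Variants from the same gene (isotrailers) are aggregated: a trailer's count
is the total over its isotrailers, the eligibility rule is the same strict
`> 10`, the representative sequence is the most abundant isotrailer in the
cytoplasmic library, and a trailer is U-tailed iff its representative ends
in at least two uridines (formalizing "UU, UUU or UUUU"). A sequence
matching several genes' regions contributes its full count to each gene's
aggregate (the per-gene view) but only once to the class composition — the
only reading consistent with reporting both per-gene trailers and a single
class row. End heterogeneity is summarized per gene as count-weighted
Shannon entropy (bits) of start offsets (support {1,2}) and end offsets.

## isomiRs and miRNA-level analyses

Sequences labeled miRNA are grouped by mature miRNA: each record is located
inside its matched hairpin and assigned to the annotated arm it overlaps
most (ties to the 5' arm). Per library, the representative isomiR is the
most abundant member, ties broken by lexicographically smallest sequence (a
declared, deterministic tie-break; real ties are rare). Groups whose
representatives differ between the libraries are flagged discordant and
excluded from representative-level analyses, since their "expression level"
is ambiguous. The nuclear–cytoplasmic correlation is the squared Pearson
correlation of representative RPM, computed on the raw RPM scale by default
with a log10 option. Terminal-motif association (`motif_nc_association`)
compares N/C between carriers and non-carriers of a 3–7 nt 3'-end motif
using medians and a Wilcoxon rank-sum test — a descriptive screen, not a
calibrated inference procedure.

## The synthetic-data generator

`simulate_experiment()` builds, from one seed:

- a ~50 kb chromosome hosting non-overlapping planted features — 8 miRNA
  hairpins (mature 5' arm + loop + reverse-complement arm), 6 tRNA genes on
  alternating strands each followed by a designed 40-nt trailer region
  (80% with a planted uridine stretch at the cleavage-product 3' end; the
  rest built without any UU so the U-tail call is exactly recoverable),
  snoRNAs, scaRNAs (one ACA45-like), snRNAs, three 3-exon mRNA gene models,
  one repeat unit planted at three loci, and recorded intergenic windows;
- a 2 kb mitochondrial contig with transcript references;
- an rRNA transcription unit (ETS–18S–ITS1–5.8S–ITS2–28S–ETS) present only
  as references, deliberately absent from the assembly so rRNA-derived reads
  must go through the rescue stage;
- paired read libraries at 10^5 expected reads each, with per-feature
  expected-RPM mixing ratios (class ratio × log-normal jitter, σ = 0.5 in
  log2), Poisson counts, isomiR 3'-end offsets (−2..+2), untemplated tails
  constructed to break the genomic match on both strands, CCA-tailed tRNA
  fragments, single-mismatch tRNA reads, trailer prefixes at offsets 1 and
  2, ligated 3' adapters (35-nt reads), and poly-A / 5'-adapter /
  adapter-less contaminants at low configured rates.

Class mixing ratios default to the compartment biology the generator
emulates — box C/D snoRNA 40, ETS 8 (nuclear-retained precursor products),
mitochondrial RNA 0.08 and tRNA 3' trailer 0.05 (cytoplasmic), miRNA 1.5
(imported but cytoplasmically enriched) — and class library shares default
to a miRNA-dominated mixture (50%). The Poisson-at-planted-RPM mixing model
makes the N/C estimator's sampling error analytically checkable, and
feature placement rejects overlaps so cascade priority logic is tested with
separately constructed overlap fixtures rather than accidental ones.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing errors outside the single-mismatch tRNA
channel, quality scores, ligation biases, isomiR 5'-end heterogeneity,
RNA editing, true multi-mapping ambiguity between reference classes, and the
scale of a real genome (the oracle-equivalence suites run on genomes up to
50 kb; the index is exact at any scale but its memory use is linear in
genome size). Problem sizes in the test and acceptance suites — 10^5 reads
per library, 20 oracle genomes, 1,000 trimming cases — were chosen as the
smallest sizes at which every statistic under test is comfortably away from
its sampling noise floor.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based closed internally; BED is parsed 0-based
  half-open, GFF3 1-based closed, each converted at the boundary.
- Report rounding is half away from zero: 2 decimals for miRNA N/C, 5 for
  trailer N/C, 1 for RPM.
- Reads containing N are discarded before trimming (exact matching cannot
  place them); quality scores are ignored (inputs may be FASTA).
- Poly-A contaminants are inserts with ≥ 90% adenine (tolerating one
  sequencing error in a true poly-A artifact); 5'-adapter contaminants carry
  a ≥ 10 nt exact match to the 5' adapter's 3' end anchored at insert
  position 1, which is how adapter-dimer chimeras present after 3' trimming.
  Both thresholds are declared configuration, not inferred biology.
- Leftmost adapter match wins when several positions qualify (shortest
  credible insert); one-mismatch tRNA rescue takes the first reference in
  file order; `nc_ratio(0, 0)` and empty eligible sets are errors, not NAs.

## Worked example

```{r example}
library(srnaloc)

cfg <- sim_config(seed = 1)
sim <- simulate_experiment(cfg)
res <- run_pipeline(list(
  bundle = sim$bundle, reads = sim$reads,
  adapter3 = cfg$adapter3, adapter5 = cfg$adapter5,
  mirna_catalog = sim$truth$mirna_catalog, hairpins = sim$truth$hairpins,
  seed = 1))

res$composition          # per-class counts and percentages per library
render_tables(res)       # composition + top miRNAs by N/C + top trailers
nc_summary(res$nc)       # in-range and exclusivity fractions
```

## Known limitations

- The one-mismatch rescue reports the class only (as the analysis requires),
  not a best-scoring gene assignment.
- `group_isomirs` needs a mature-arm catalog; without one, miRNA-labeled
  sequences are still counted in the composition but not grouped.
- The exclusivity fractions depend on sequencing depth; they are detection
  statements, not biology, and the vignette's generator makes that visible:
  lowering `depth` inflates both exclusive fractions.
- Multi-library designs beyond two compartments run through every stage, but
  N/C statistics always compare exactly two designated libraries.
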