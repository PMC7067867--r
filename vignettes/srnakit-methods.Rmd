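---
title: "srnakit: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnakit: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnakit)
```

srnakit quantifies the small RNA'ome — miRNA, piRNA, snRNA, snoRNA, tRNA
and circRNA fragments, plus microbial RNA among host-unmapped reads — from
small RNA-seq data. This vignette documents the model each stage
implements, the parameters that matter and their defaults, the design
choices made where the design was genuinely open, and what the synthetic
fixtures do and do not establish about real data.

## Quality control

Raw small-RNA libraries from randomized-ligation kits (e.g. NEXTflex) have
the layout `4N + insert + 4N + adapter` inside a fixed-length (here 50 nt)
read. QC applies, in a fixed order:

1. **Adapter trimming.** At each read position the adapter's prefix is
   compared against the read suffix; the read is cut at the *leftmost*
   position whose mismatch fraction is at most `max_mismatch_rate` (default
   0.1) over at least `min_overlap` bases (default 3). These are
   cutadapt-like semantics, chosen because they are deterministic and
   standard; the tolerated mismatches are `floor(overlap × rate)`, so short
   overlaps must match exactly.
2. **Randomized-base removal.** Exactly `n_random_5p`/`n_random_3p` bases
   (default 4/4) are cut from the ends. A read shorter than the sum becomes
   a legal zero-length read. The order matters and is pinned by a
   regression test: the randomized bases sit immediately *inside* the
   adapter, so trimming them first would leave adapter bases in place.
3. **Low-quality end stripping** (`-rh 20 -rt 20`): the maximal run of
   terminal bases with PHRED ≤ threshold is removed from each end; interior
   bases are never touched. Stripping runs (rather than single bases) is
   the interpretation adopted; it is idempotent, which single-base
   stripping would also be, but run-stripping matches how end-quality decay
   actually presents.
4. **Mean-quality filter** (`-rr 20`): reads whose *remaining* bases
   average PHRED ≤ 20 are removed. The boundary is inclusive — a mean of
   exactly 20 is removed — following the printed inequality convention, and
   the mean is evaluated after end-stripping because it is the surviving
   sequence whose quality matters downstream.
5. **Length selection:** a closed interval, default 15–45 nt. Placing
   length selection at the end of QC (rather than after alignment) keeps
   the alignment input minimal; nothing downstream depends on the choice.

Qualities are PHRED+33 on input (modern Illumina; the offset is
configurable), and `U` is normalized to `T` so RNA-alphabet records align
against DNA genomes.

With these defaults a 50 nt adapter-free read loses exactly its 8
randomized bases, giving the characteristic 0–42 nt trimmed-length range:
the 22 nt peak is miRNA, ~30 nt piRNA, and 42 nt the truncation ceiling.

## Alignment

Internally every interval is **0-based half-open**, one convention
everywhere; SAM (1-based) and BED (0-based half-open) are translated at the
boundary. Production alignments come from an external aligner and are
ingested from SAM/BAM: secondary records join their read's multi-map
group, the aligned span on the read is derived from the CIGAR with soft
clips excluded, and mismatch counts come from the `NM` tag. Records
flagged unmapped are collected and can be exported as FASTA for microbial
screening.

For self-contained work at test scale the package includes a micro-aligner:
exhaustive end-to-end matching (Hamming distance, both strands, default at
most 1 mismatch — mirroring the stringent one-mismatch default a production
configuration would use) over genomes of up to ~100 kb. It reports *every*
placement, which the counting rules require, and is verified in the test
suite against an independent brute-force scan over every offset and strand.
It does no soft clipping and no indels; clipped records are the province of
SAM ingestion.

## Annotation

Feature databases are BED6-like text (`chrom`, `start`, `end`, `name`,
`id`, `strand`), each file tagged with a database label and an RNA type. A
molecule is identified by `(rna_type, name)`; one molecule may own many
intervals (multi-locus genes), and identical `(rna_type, name)` records
from different databases merge into one molecule whose `DB` column lists
all supporting sources. Coordinates are taken as supplied — the user is
responsible for giving genome and databases in the same build.

Assignment uses the overlap ratio `R_olp = L_olp / L_read`, with
`min_ratio` defaulting to 1: full containment. Two decisions here were
genuinely open:

* **`L_read` under soft clipping.** `L_read` is the *aligned span* of the
  read, not its full length, so an isomiR whose non-templated end bases
  were clipped by a local aligner can still reach ratio 1. Dividing by the
  full read length instead (available via `use_full_read_length = TRUE`)
  would reject most isomiRs at the default threshold, defeating the point
  of tolerant alignment.
* **Strandedness.** Small-RNA annotations are strand-specific in their
  source databases, so the default requires alignment and feature on the
  same strand (`strand_mode = "same"`); `"ignore"` is available for
  unstranded protocols.

Counting applies two rules, both load-bearing:

* **Count once per molecule:** all alignments of a read are one multi-map
  group; every feature reaching the ratio threshold across the group is
  collected and then deduplicated at the molecule level. This also means a
  read multi-mapped to two *different* molecules of the same type counts
  once for each — deduplication is per molecule, never per type.
* **No type priority:** molecules of different types supported by the same
  read are all retained. Consequently column sums can exceed the number of
  annotated reads; the conserved quantity, asserted property-style in the
  tests, is that a single read contributes at most 1 to any single
  molecule.

Per-type outputs have exactly four columns — `DB`, `Name`, `ID`, `Count` —
and the reads annotated to any one type can be exported as SAM (`-abam`),
with dual-typed reads appearing in every export they belong to.

## Microbial screening

Host-unmapped reads are matched against microbial references; hits arrive
either from an external search in 12-column tabular form or from the
built-in exhaustive micro-matcher (same contract as the micro-aligner,
emitting deterministic identity/score fields). Hits pass a screen of
`max_evalue = 1e-3` and `min_identity = 90` — conventional screening
values, configurable; raw nucleotide-database hits are unusably noisy with
no filter at all. After the screen, **all** supported taxa are kept per
read: no best-hit selection, no lowest-common-ancestor collapse, so
homologous species are all reported. A `best_hit_only` convenience flag
exists but is off by default.

Counts are reported at every rank of the taxonomy ("according to the
phylogenetic tree"): the rollup count of a node is the number of reads
supporting any descendant-or-self, each read counting at most once per
ancestor — a read hitting two species of one genus adds 1, not 2, to the
genus. Counting is integer throughout; fractional (1/n) schemes were
rejected as inconsistent with the one-count-per-molecule semantics used
everywhere else. Output is grouped into archaea, bacteria, fungi and
viruses. Taxonomies load from a 5-column TSV or from NCBI-style
nodes/names dumps.

## Merging, normalization, differential expression

Per-sample four-column tables merge into a molecule × sample matrix (union
of molecules, zeros for absences, columns in input order). Normalization
is counts-per-million: each column is rescaled to sum to 10^6. The library
size defaults to the column sum of the matrix being normalized — a
self-contained choice — with an override for externally determined sizes
(e.g. total qualified reads). Detection is called per sample at a raw read
count of at least 5 (inclusive).

Case/control testing is the two-sided Mann-Whitney U per molecule. The
pipeline default is CpM-then-test; testing raw counts is available
(`normalize = "none"`) since the rank test is invariant to any common
per-column monotone rescaling only when library sizes are equal. The exact
null distribution is used when the smaller group has ≤ 8 samples and the
row has no ties; otherwise the normal approximation with tie-corrected
variance and continuity correction. Rows constant across all samples carry
no rank information and are reported with p = 1 and a flag. Raw p-values
are reported, as is conventional for this pipeline family;
Benjamini-Hochberg adjustment is provided but off by default.

## Synthetic fixtures: what they emulate, and what they do not

The generator builds, from one integer seed (byte-identical outputs per
seed, caller's RNG untouched):

* a random genome (default 20 kb, one chromosome) with planted scenarios:
  a 22-mer copied to 11 loci annotated to one miRNA molecule, and a 22 nt
  miRNA nested at the 5' end of a 30 nt piRNA sharing its sequence — the
  two defining multi-mapper cases — plus non-overlapping random features
  per type, every third on the minus strand;
* 50 nt reads in the `4N + insert + 4N + adapter` layout, drawn from every
  molecule (windows fully inside the feature), from intergenic regions,
  plus low-mean-quality reads (engineered to survive end-trimming so the
  mean filter, specifically, removes them) and non-genomic reads, with a
  truth table recording each read's QC fate and source molecules;
* a ~18-node four-group taxonomy with per-species references and reads
  planted in one or two species;
* count matrices with Poisson null rows and fold-shifted rows for
  calibration and power checks.

Default problem sizes — 20 kb genome, ~30 features, ~200 reads per sample,
100 kb genomes for the aligner-oracle comparison, 1000 null rows for size
calibration — were chosen so that the defining scenarios are each exercised
many times over while the whole suite stays comfortably within a
development iteration loop.

Passing on these fixtures establishes the *counting logic*: truth recovery
shows QC → alignment → annotation reproduces known per-molecule counts
exactly, and the oracle equivalences pin the aligner, the interval index
and the exact rank-sum path. The fixtures do **not** emulate sequencing
indels, position-dependent quality decay, adapter synthesis errors,
repeat-driven multi-mapping at genomic scale, or realistic database sizes
and redundancy — conclusions about accuracy on real libraries still require
real data.

## Numerical choices and degenerate inputs

* Ratio comparisons use `l_olp ≥ min_ratio × l_read − 1e-9`, so the default
  `min_ratio = 1` is exact containment without float surprises.
* All boundary inequalities printed above are inclusive (mean PHRED ≤ 20
  removed; detection ≥ 5 detected; length interval closed).
* Zero-length reads are legal after trimming and removed before
  zero-undefined operations (mean quality); zero-sum libraries are an
  error naming the sample, not a silent NaN.
* Duplicate feature lines are dropped on load with a message; duplicate
  sample names are an error.
* Ties in count data divert the rank-sum test to the corrected
  approximation; completely separated tie-free 6v6 rows sit at the exact
  floor 2/924.

## Known limitations

The micro-aligner and micro-matcher are exhaustive and intended for test
scale (≲100 kb references); real studies should ingest external SAM/BAM
and tabular hits. Spliced alignment, UMI deduplication, paired-end input,
isomiR sub-classification and novel small-RNA discovery are out of scope.
Coordinate-system harmonization across database builds is the user's
responsibility.
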