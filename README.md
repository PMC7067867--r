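# srnakit

A modular R toolkit for quantifying the small RNA'ome — the full complement
of RNA species under ~200 nt — from small RNA sequencing data. It is aimed
at transcriptomics researchers who need more than miRNA profiling: one run
yields per-sample counts for miRNA, piRNA, snRNA, snoRNA, tRNA and circRNA
fragments, taxonomic counts of microbial reads that fail to map to the host
genome, and case/control differential expression, with every stage also
usable on its own (e.g. annotation of externally produced SAM/BAM
alignments).

## The model at the core

A read is assigned to an annotation by its **degree of read support**, the
overlap ratio

```
R_olp = L_olp / L_read
```

where `L_olp` is the number of read bases falling inside the annotation
interval and `L_read` the number of aligned read bases. The default
requirement is `R_olp = 1` (flag `-ann_overlap 1`): the read must lie
completely within the annotation. Reads clipped by a local aligner are
measured over their aligned span, so isomiRs with non-templated ends can
still reach ratio 1.

Two counting rules govern multi-mapped reads:

1. **Count once per molecule.** A read aligned to many loci of one RNA
   molecule (e.g. a mature miRNA encoded by 11 precursor loci) contributes
   exactly 1 to that molecule.
2. **No type priority.** A read lying inside annotations of *different*
   molecules — such as a miRNA nested at the 5' end of a longer piRNA —
   contributes one count to *each* of them. Column sums may therefore
   exceed the number of annotated reads, by design.

Unmapped reads are screened against microbial references; every taxon
supported by a passing hit is retained (no best-hit selection, no
lowest-common-ancestor collapse) and counts are rolled up the phylogenetic
tree, each read counting at most once per ancestor. Sample-level matrices
are normalized to counts-per-million, detection is called at a read-count
threshold of 5, and case/control testing uses the two-sided Mann-Whitney U
(Wilcoxon rank-sum) test.

## Worked example

The package ships a deterministic fixture generator, so a full run needs no
downloads:

```r
library(srnakit)

gf <- make_genome(seed = 42)           # toy genome + feature databases
rd <- make_reads(seed = 42, gf)        # 50 nt reads: 4N + insert + 4N + adapter

qc <- run_qc(rd$reads)                 # adapter/random-base/quality trimming
qc$report$n_qualified
#> [1] 179                              (189 raw reads, 10 low-quality removed)

al <- micro_align(qc$reads, gf$genome, max_mismatch = 1)
q  <- quantify(al$alignments, feature_index(gf$features))
head(q$counts$miRNA)
#>      DB      Name         ID Count
#> 1 mirdb   miRNA-1 ID-miRNA-1    12
#> 2 mirdb   miRNA-2 ID-miRNA-2    10
#> 3 mirdb   miRNA-5 ID-miRNA-5    10
#> 4 mirdb   miR-M11     MI-M11     8
#> 5 mirdb   miRNA-3 ID-miRNA-3     7
#> 6 mirdb let-7a-5p   MI-let7a     6

head(q$counts$piRNA, 3)
#>                DB       Name         ID Count
#> 1 pirdb_a,pirdb_b piR_008113    piR8113    17
#> 2         pirdb_a    piRNA-4 ID-piRNA-4     9
#> 3         pirdb_a    piRNA-3 ID-piRNA-3     8
```

Reading the output: each table is one RNA type; `DB` lists every database
supporting the molecule's annotation (the planted piRNA is carried by two
piRNA databases, hence `pirdb_a,pirdb_b`); `Count` is the number of
distinct qualified reads assigned to the molecule. `miR-M11` is the
fixture's 11-locus molecule — its 8 reads each align to 11 places but count
once apiece. The 6 reads of `let-7a-5p` lie inside the nested piRNA too and
are included in `piR_008113`'s 17.

Merging, normalization and testing follow the same matrix conventions:

```r
m  <- merge_samples(list(s1 = q$counts$miRNA, s2 = q$counts$miRNA))
de <- mann_whitney_de(m, case = "s1", control = "s2")   # CpM then rank-sum
```

A command-line front end with the same stages as subcommands (`qc`,
`align`, `annotate`, `microbe`, `function`, `pipeline`, `fixtures`) is
installed at `system.file("cli", "srnakit.R", package = "srnakit")`.

## Scope

The toolkit reimplements the quantification logic only: production-scale
genome alignment and nucleotide-database searches are delegated to external
tools (their SAM/BAM and 12-column tabular outputs are ingested), and the
public small-RNA databases are represented by a documented BED-like text
schema rather than redistributed. See `vignettes/srnakit-methods.Rmd` for
the full account of the model, parameter defaults and limitations.
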