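# Deterministic synthetic inputs: toy genome with planted small-RNA
# features, structured FASTQ reads with known fate, microbial references
# with a toy taxonomy, and count matrices with known differential rows.
# A single integer seed drives all randomness; the caller's RNG state is
# left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# The mature miRNA / piRNA sequence pair with a shared 5' end (DNA
# alphabet): the 22 nt miRNA is the exact prefix of the 30 nt piRNA, so a
# read of the miRNA lies completely within both annotations.
nested_pair_sequences <- function() {
  mirna <- "TGAGGTAGTAGGTTGTATAGTT"
  list(mirna = mirna, pirna = paste0(mirna, "TTAGGGTC"))
}

#' Generate a synthetic genome with planted small-RNA features
#'
#' Builds a random single-chromosome genome carrying: one 22-mer copied to
#' 11 distinct loci that all annotate to one miRNA molecule (the
#' multi-locus, count-once scenario); one miRNA interval nested at the 5'
#' end of a longer piRNA interval sharing its sequence prefix (the
#' overlapping-molecules, one-count-each scenario — the piRNA record is
#' carried by two databases to exercise multi-database support); and
#' further non-overlapping random features of each requested RNA type,
#' every third one on the minus strand.
#'
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param genome_len chromosome length in bases (>= 1000).
#' @param n_features named integer vector: extra random features per type.
#' @return a list with `genome` (a `DNAStringSet`, one chromosome `chr1`)
#'   and `features` (a feature data frame, see [load_feature_db()]).
#' @export
make_genome <- function(seed = 1L, genome_len = 20000L,
                        n_features = c(miRNA = 6, piRNA = 4, snRNA = 2,
                                       snoRNA = 2, tRNA = 3, circRNA = 2)) {
  stopifnot(genome_len >= 1000)
  with_seed(seed, {
    g <- strsplit(random_dna(genome_len), "")[[1]]
    occupied <- matrix(numeric(0), ncol = 2)
    claim <- function(width) {
      # non-overlapping placement with a 10 bp margin, rejection sampling
      for (try in 1:2000) {
        s <- sample.int(genome_len - width - 20L, 1) + 10L  # 0-based start
        e <- s + width
        if (nrow(occupied) == 0 ||
            all(e + 10 <= occupied[, 1] | s - 10 >= occupied[, 2])) {
          occupied <<- rbind(occupied, c(s, e))
          return(c(s, e))
        }
      }
      stop("could not place feature; genome too small")
    }
    plant <- function(seq, at) {
      g[(at + 1):(at + nchar(seq))] <<- strsplit(seq, "")[[1]]
    }
    feats <- list()
    add_feat <- function(db, rna_type, name, id, start, end, strand) {
      feats[[length(feats) + 1L]] <<- data.frame(
        db = db, rna_type = rna_type, name = name, id = id, chrom = "chr1",
        start = start, end = end, strand = strand, stringsAsFactors = FALSE)
    }

    # multi-locus scenario: one 22-mer at 11 loci, one molecule
    multi_seq <- random_dna(22)
    for (k in 1:11) {
      pos <- claim(22L)
      plant(multi_seq, pos[1])
      add_feat("mirdb", "miRNA", "miR-M11", "MI-M11", pos[1], pos[2], "+")
    }

    # nested scenario: miRNA prefix of a piRNA, piRNA in two databases
    np <- nested_pair_sequences()
    pos <- claim(nchar(np$pirna))
    plant(np$pirna, pos[1])
    add_feat("mirdb", "miRNA", "let-7a-5p", "MI-let7a",
             pos[1], pos[1] + nchar(np$mirna), "+")
    add_feat("pirdb_a", "piRNA", "piR_008113", "piR8113", pos[1], pos[2], "+")
    add_feat("pirdb_b", "piRNA", "piR_008113", "piR8113", pos[1], pos[2], "+")

    widths <- c(miRNA = 22L, piRNA = 29L, snRNA = 80L, snoRNA = 70L,
                tRNA = 72L, circRNA = 120L)
    dbs <- c(miRNA = "mirdb", piRNA = "pirdb_a", snRNA = "ncdb",
             snoRNA = "ncdb", tRNA = "trnadb", circRNA = "circdb")
    counter <- 0L
    for (tp in names(n_features)) {
      for (k in seq_len(n_features[[tp]])) {
        counter <- counter + 1L
        pos <- claim(widths[[tp]])
        strand <- if (counter %% 3 == 0) "-" else "+"
        add_feat(dbs[[tp]], tp, paste0(tp, "-", k), paste0("ID-", tp, "-", k),
                 pos[1], pos[2], strand)
      }
    }

    genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
    names(genome) <- "chr1"
    features <- do.call(rbind, feats)
    rownames(features) <- NULL
    list(genome = genome, features = features)
  })
}

# Assemble one raw 50 nt read: n5 random bases + insert + n3 random bases +
# adapter, padded with random filler / truncated to read_len.
assemble_raw_read <- function(insert, adapter, n5 = 4L, n3 = 4L,
                              read_len = 50L) {
  s <- paste0(random_dna(n5), insert, random_dna(n3), adapter)
  if (nchar(s) < read_len) s <- paste0(s, random_dna(read_len - nchar(s)))
  substr(s, 1, read_len)
}

good_qual <- function(n) {
  pmin(40L, pmax(28L, as.integer(round(stats::rnorm(n, 36, 2)))))
}

# Low mean quality across the insert but high-quality bases at the insert
# boundaries (raw positions n5+1 and n5+insert_len for a 4N+insert+4N+adapter
# layout), so after adapter/random-base trimming the read survives
# end-trimming and is removed by the mean-quality filter specifically.
bad_qual <- function(n, insert_len, n5 = 4L) {
  q <- pmin(20L, pmax(2L, as.integer(round(stats::rnorm(n, 15, 2)))))
  q[c(n5 + 1L, n5 + insert_len)] <- 30L
  q
}

#' Generate synthetic raw reads with a truth table
#'
#' Emulates the library structure of randomized-ligation small-RNA kits:
#' each 50 nt raw read is 4 random bases + genomic insert + 4 random bases
#' + adapter (padded/truncated to 50 nt). Reads are drawn from every
#' feature molecule (windows fully inside the feature, reverse-complemented
#' for minus-strand features), from the multi-locus and nested planted
#' scenarios, plus intergenic reads, low-mean-quality reads and
#' non-genomic (microbial-like) reads. The truth table records each read's
#' QC fate, mappability and source molecule set, so expected per-molecule
#' counts are known by construction.
#'
#' @param seed integer seed.
#' @param genome_fixture result of [make_genome()].
#' @param adapter adapter appended to inserts (QC must use the same).
#' @param reads_per_molecule count range (inclusive) of good reads drawn
#'   per molecule.
#' @param n_intergenic,n_bad,n_microbial counts of the extra scenarios.
#' @return a list with `reads` (raw `srna_reads`) and `truth` (data frame:
#'   `id`, `scenario`, `qc_pass`, `mapped`, `molecules` — a
#'   `;`-separated list of `type:name` labels).
#' @export
make_reads <- function(seed = 1L, genome_fixture,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       reads_per_molecule = c(5L, 12L),
                       n_intergenic = 10L, n_bad = 10L, n_microbial = 8L) {
  genome <- genome_fixture$genome
  features <- genome_fixture$features
  gstr <- as.character(genome[["chr1"]])
  with_seed(seed + 1L, {
    ids <- character(0); seqs <- character(0); quals <- list()
    truth <- list()
    nread <- 0L
    emit <- function(insert, scenario, qc_pass, mapped, molecules,
                     qual = NULL) {
      nread <<- nread + 1L
      id <- sprintf("read_%04d", nread)
      ids <<- c(ids, id)
      seqs <<- c(seqs, assemble_raw_read(insert, adapter))
      quals[[length(quals) + 1L]] <<- if (is.null(qual)) good_qual(50L) else qual
      truth[[length(truth) + 1L]] <<- data.frame(
        id = id, scenario = scenario, qc_pass = qc_pass, mapped = mapped,
        molecules = molecules, stringsAsFactors = FALSE)
    }
    # molecules containing a genomic window, strand-aware
    containing <- function(start, end, strand) {
      hit <- features$chrom == "chr1" & features$start <= start &
        features$end >= end & features$strand == strand
      f <- features[hit, , drop = FALSE]
      u <- unique(paste(f$rna_type, f$name, sep = ":"))
      paste(sort(u), collapse = ";")
    }

    mol_keys <- unique(paste(features$rna_type, features$name, sep = "\r"))
    for (mk in mol_keys) {
      parts <- strsplit(mk, "\r")[[1]]
      frows <- features[features$rna_type == parts[1] &
                          features$name == parts[2], , drop = FALSE]
      n <- sample(seq(reads_per_molecule[1], reads_per_molecule[2]), 1)
      for (k in seq_len(n)) {
        row <- frows[sample.int(nrow(frows), 1), , drop = FALSE]
        w <- min(row$end - row$start, sample(20:32, 1))
        off <- sample.int(row$end - row$start - w + 1L, 1) - 1L
        s0 <- row$start + off; e0 <- s0 + w
        insert <- substr(gstr, s0 + 1, e0)
        if (row$strand == "-") insert <- revcomp(insert)
        emit(insert, scenario = paste0("feature:", parts[2]), qc_pass = TRUE,
             mapped = TRUE, molecules = containing(s0, e0, row$strand))
      }
    }

    for (k in seq_len(n_intergenic)) {
      repeat {
        w <- sample(20:30, 1)
        s0 <- sample.int(nchar(gstr) - w, 1)
        insert <- substr(gstr, s0 + 1, s0 + w)
        if (!nzchar(containing(s0, s0 + w, "+")) &&
            !nzchar(containing(s0, s0 + w, "-"))) break
      }
      emit(insert, "intergenic", TRUE, TRUE, "")
    }

    for (k in seq_len(n_bad)) {
      w <- sample(20:30, 1)
      s0 <- sample.int(nchar(gstr) - w, 1)
      emit(substr(gstr, s0 + 1, s0 + w), "low_quality", FALSE, FALSE, "",
           qual = bad_qual(50L, insert_len = w))
    }

    for (k in seq_len(n_microbial)) {
      repeat {
        insert <- random_dna(sample(24:30, 1))
        pat <- Biostrings::DNAString(insert)
        hits <- Biostrings::countPattern(pat, genome[[1]], max.mismatch = 1) +
          Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                   genome[[1]], max.mismatch = 1)
        if (hits == 0) break
      }
      emit(insert, "microbial", TRUE, FALSE, "")
    }

    list(
      reads = srna_reads(ids, seqs, phred_encode(quals)),
      truth = do.call(rbind, truth)
    )
  })
}

#' Expected per-molecule counts implied by a truth table
#'
#' Tallies, over QC-passing reads, how many reads list each molecule —
#' the counts [quantify()] must reproduce on the fixture.
#'
#' @param truth the `truth` element of [make_reads()].
#' @return data frame `rna_type`, `name`, `count`.
#' @export
truth_counts <- function(truth) {
  t2 <- truth[truth$qc_pass & nzchar(truth$molecules), , drop = FALSE]
  mols <- unlist(strsplit(t2$molecules, ";", fixed = TRUE))
  if (length(mols) == 0) {
    return(data.frame(rna_type = character(0), name = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(mols)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  out <- data.frame(rna_type = vapply(parts, `[`, character(1), 1),
                    name = vapply(parts, `[`, character(1), 2),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$rna_type, out$name), , drop = FALSE]
}

#' Generate a microbial reference, taxonomy and planted unmapped reads
#'
#' Builds a small taxonomy spanning the four microbial groups (archaea,
#' bacteria, fungi, viruses) with family/genus/species structure, one
#' random reference sequence per species, and reads planted in one or two
#' species to exercise the all-potential-taxa semantics (a read present in
#' two species of one genus must count once, not twice, at the genus).
#'
#' @param seed integer seed.
#' @return a list with `refs` (`DNAStringSet` named by accession),
#'   `taxonomy` (taxonomy data frame), `acc2taxid` (data frame), `reads`
#'   (planted `srna_reads`) and `truth` (named list: expected taxid set
#'   per read).
#' @export
make_microbe_fixture <- function(seed = 1L) {
  with_seed(seed + 2L, {
    tx <- data.frame(
      taxid = c(1L, 2L, 3L, 4L, 5L,
                30L, 31L, 32L, 33L, 34L, 35L,
                20L, 21L,
                40L, 41L, 42L,
                50L, 51L),
      parent = c(1L, 1L, 1L, 1L, 1L,
                 3L, 30L, 31L, 31L, 30L, 34L,
                 2L, 20L,
                 4L, 40L, 40L,
                 5L, 50L),
      rank = c("root", "superkingdom", "superkingdom", "kingdom",
               "superkingdom",
               "family", "genus", "species", "species", "genus", "species",
               "genus", "species",
               "genus", "species", "species",
               "genus", "species"),
      name = c("root", "Archaea", "Bacteria", "Fungi", "Viruses",
               "Bacfamily", "Bacgenus1", "Bacsp1", "Bacsp2", "Bacgenus2",
               "Bacsp3",
               "Arcgenus", "Arcsp1",
               "Fungenus", "Funsp1", "Funsp2",
               "Virgenus", "Virsp1"),
      group = c("other", "archaea", "bacteria", "fungi", "viruses",
                "bacteria", "bacteria", "bacteria", "bacteria", "bacteria",
                "bacteria",
                "archaea", "archaea",
                "fungi", "fungi", "fungi",
                "viruses", "viruses"),
      stringsAsFactors = FALSE)
    tree <- load_taxonomy(tx)
    species <- tree[tree$rank == "species", , drop = FALSE]
    refs <- Biostrings::DNAStringSet(
      vapply(seq_len(nrow(species)), function(i) random_dna(300), character(1)))
    names(refs) <- paste0("ACC_", species$name)
    acc2taxid <- data.frame(accession = names(refs), taxid = species$taxid,
                            stringsAsFactors = FALSE)

    plant_in <- function(seq, accs) {
      for (acc in accs) {
        r <- strsplit(as.character(refs[[acc]]), "")[[1]]
        at <- sample.int(length(r) - nchar(seq), 1)
        r[at:(at + nchar(seq) - 1L)] <- strsplit(seq, "")[[1]]
        refs[[acc]] <- Biostrings::DNAString(paste(r, collapse = ""))
      }
      refs
    }
    s1 <- random_dna(24)  # shared by two species of one genus
    refs <- plant_in(s1, c("ACC_Bacsp1", "ACC_Bacsp2"))
    s2 <- random_dna(26)
    refs <- plant_in(s2, "ACC_Funsp1")
    s3 <- random_dna(25)
    refs <- plant_in(s3, "ACC_Virsp1")
    s4 <- random_dna(26)  # planted nowhere

    reads <- srna_reads(
      id = c("mb_read_1", "mb_read_2", "mb_read_3", "mb_read_4"),
      seq = c(s1, s2, s3, s4),
      qual = phred_encode(list(rep(38L, 24), rep(38L, 26), rep(38L, 25),
                               rep(38L, 26))))
    truth <- list(
      mb_read_1 = sort(species$taxid[species$name %in% c("Bacsp1", "Bacsp2")]),
      mb_read_2 = species$taxid[species$name == "Funsp1"],
      mb_read_3 = species$taxid[species$name == "Virsp1"],
      mb_read_4 = integer(0))
    list(refs = refs, taxonomy = tree, acc2taxid = acc2taxid,
         reads = reads, truth = truth)
  })
}

#' Generate a count matrix with known null and shifted rows
#'
#' Null rows draw every sample from one Poisson distribution; shifted rows
#' multiply the case mean by `fold_change`. The truth flags which rows are
#' shifted, enabling type-I-error and power checks of the rank-sum test.
#'
#' @param seed integer seed.
#' @param n_null,n_shift row counts.
#' @param n_case,n_control group sizes (>= 3).
#' @param base_mean Poisson mean of null rows and of shifted controls.
#' @param fold_change multiplicative case shift for shifted rows.
#' @return list with `table` (merged-format data frame), `case`/`control`
#'   sample names, and `truth` (logical vector, `TRUE` for shifted rows).
#' @export
make_de_fixture <- function(seed = 1L, n_null = 1000L, n_shift = 50L,
                            n_case = 6L, n_control = 6L,
                            base_mean = 500, fold_change = 4) {
  stopifnot(n_case >= 3, n_control >= 3)
  with_seed(seed + 3L, {
    case <- paste0("case_", seq_len(n_case))
    control <- paste0("ctrl_", seq_len(n_control))
    n <- n_null + n_shift
    shifted <- c(rep(FALSE, n_null), rep(TRUE, n_shift))
    m <- matrix(0L, nrow = n, ncol = n_case + n_control,
                dimnames = list(NULL, c(case, control)))
    for (i in seq_len(n)) {
      mu_case <- if (shifted[i]) base_mean * fold_change else base_mean
      m[i, ] <- c(stats::rpois(n_case, mu_case),
                  stats::rpois(n_control, base_mean))
    }
    tab <- cbind(data.frame(DB = "sim", Name = sprintf("mol_%04d", seq_len(n)),
                            ID = sprintf("SIM%04d", seq_len(n)),
                            stringsAsFactors = FALSE),
                 as.data.frame(m))
    list(table = tab, case = case, control = control, truth = shifted)
  })
}

#' Write the feature table of a genome fixture as per-database BED-like files
#'
#' @param features a feature data frame.
#' @param dir output directory.
#' @return data frame `path`, `db`, `rna_type` describing the written
#'   files, invisibly usable as a pipeline database manifest.
#' @export
write_feature_dbs <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- unique(features[, c("db", "rna_type")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    f <- features[features$db == combos$db[i] &
                    features$rna_type == combos$rna_type[i], , drop = FALSE]
    p <- file.path(dir, paste0(combos$db[i], "_", combos$rna_type[i], ".bed"))
    utils::write.table(
      f[, c("chrom", "start", "end", "name", "id", "strand")], p,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    data.frame(path = p, db = combos$db[i], rna_type = combos$rna_type[i],
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, out))
}
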