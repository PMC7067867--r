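mk_aln <- function(read_id, chrom, start, end, strand = "+",
                   read_start = 0L, read_len = end - start) {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, n_mismatch = 0L, read_start = read_start,
             read_end = read_start + (end - start), read_len = read_len,
             seq = strrep("A", read_len), stringsAsFactors = FALSE)
}

mk_feat <- function(name, start, end, rna_type = "miRNA", db = "db1",
                    chrom = "chr1", strand = "+", id = paste0("ID-", name)) {
  data.frame(db = db, rna_type = rna_type, name = name, id = id,
             chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("overlap ratio follows l_olp / l_read with half-open intervals", {
  a <- mk_aln("r1", "chr1", 104, 126)
  f <- mk_feat("m1", 100, 130)
  r <- compute_overlap_ratio(a, f)
  expect_equal(r$r_olp, 1.0)
  expect_equal(r$l_olp, 22L)
  expect_equal(r$l_read, 22L)

  expect_equal(compute_overlap_ratio(mk_aln("r", "chr1", 10, 30),
                                     mk_feat("m", 200, 260))$r_olp, 0)
  expect_equal(compute_overlap_ratio(mk_aln("r", "chr1", 10, 30),
                                     mk_feat("m", 10, 30, chrom = "chr2"))$r_olp,
               0)

  part <- compute_overlap_ratio(mk_aln("r", "chr1", 100, 120),
                                mk_feat("m", 110, 140))
  expect_equal(part$l_olp, 10L)
  expect_equal(part$l_read, 20L)
  expect_equal(part$r_olp, 0.5)

  # soft-clip aware: l_read is the aligned span by default
  clipped <- mk_aln("r", "chr1", 100, 118, read_start = 4L, read_len = 22L)
  expect_equal(compute_overlap_ratio(clipped, mk_feat("m", 95, 125))$r_olp, 1)
  expect_equal(compute_overlap_ratio(clipped, mk_feat("m", 95, 125),
                                     use_full_read_length = TRUE)$r_olp,
               18 / 22)

  zero <- mk_aln("r", "chr1", 100, 100)
  expect_error(compute_overlap_ratio(zero, mk_feat("m", 0, 10)),
               "zero-length")
})

test_that("feature database loading validates the BED-like dialect", {
  p <- tempfile(fileext = ".bed")
  writeLines(character(0), p)
  expect_equal(nrow(load_feature_db(p, "db", "miRNA")), 0)

  writeLines(c("track name=x",
               "chr1\t100\t130\tm1\tID1\t+",
               "chr2\t5\t40\tm2\tID2\t-",
               "chr1\t900\t925\tm3\tID3\t+"), p)
  f <- load_feature_db(p, "mydb", "miRNA")
  expect_equal(nrow(f), 3)
  expect_equal(f$start, c(100, 5, 900))   # BED already 0-based half-open
  expect_equal(f$end, c(130, 40, 925))
  expect_equal(unique(f$db), "mydb")

  writeLines(c("chr1\t100\t130\tm1\tID1\t+",
               "chr1\t50\t50\tz\tIDz\t+"), p)
  expect_error(load_feature_db(p, "db", "miRNA"), "line 2.*start >= end")
  writeLines("chr1\t100\t130\tm1\tID1", p)
  expect_error(load_feature_db(p, "db", "miRNA"), "6 columns")
  writeLines("chr1\t100\t130\tm1\tID1\tx", p)
  expect_error(load_feature_db(p, "db", "miRNA"), "strand")
  writeLines(rep("chr1\t100\t130\tm1\tID1\t+", 2), p)
  expect_message(f2 <- load_feature_db(p, "db", "miRNA"), "duplicate")
  expect_equal(nrow(f2), 1)
  expect_error(load_feature_db(p, "db", "nosuchtype"))
})

test_that("interval index queries equal an exhaustive linear scan", {
  set.seed(31)
  feats <- do.call(rbind, lapply(1:200, function(i) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    s <- sample.int(10000, 1)
    mk_feat(paste0("f", i), s, s + sample(20:150, 1), chrom = chrom,
            strand = sample(c("+", "-"), 1),
            rna_type = sample(c("miRNA", "piRNA", "tRNA"), 1))
  }))
  idx <- feature_index(feats)
  for (k in 1:300) {
    chrom <- sample(c("chr1", "chr2", "chr3", "chr4"), 1)
    s <- sample.int(10200, 1)
    e <- s + sample(1:80, 1)
    expect_identical(query_features(idx, chrom, s, e),
                     oracle_feature_scan(feats, chrom, s, e))
    expect_identical(query_features(idx, chrom, s, e, strand = "-"),
                     oracle_feature_scan(feats, chrom, s, e, strand = "-"))
  }
})

test_that("a multi-mapped read is counted once per molecule", {
  feats <- rbind(mk_feat("mA", 100, 130), mk_feat("mA", 500, 530),
                 mk_feat("mA", 900, 930))
  idx <- feature_index(feats)
  group <- rbind(mk_aln("r1", "chr1", 104, 126),
                 mk_aln("r1", "chr1", 504, 526),
                 mk_aln("r1", "chr1", 904, 926))
  ann <- annotate_read(group, idx)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$name, "mA")
  q <- quantify(group, idx)
  expect_equal(q$counts$miRNA$Count, 1)
})

test_that("overlapping molecules of different types each get one count", {
  feats <- rbind(
    mk_feat("let-7a-5p", 100, 122, rna_type = "miRNA", db = "mirdb"),
    mk_feat("piR_008113", 100, 130, rna_type = "piRNA", db = "pirdb_a"),
    mk_feat("piR_008113", 100, 130, rna_type = "piRNA", db = "pirdb_b"))
  idx <- feature_index(feats)
  group <- mk_aln("r1", "chr1", 100, 122)
  ann <- annotate_read(group, idx)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$name, c("let-7a-5p", "piR_008113"))
  # supporting databases are joined at the molecule level
  expect_equal(ann$db[ann$name == "piR_008113"], "pirdb_a,pirdb_b")

  q <- quantify(group, idx)
  expect_equal(q$counts$miRNA$Count, 1)
  expect_equal(q$counts$piRNA$Count, 1)
  # empty annotation away from features
  expect_equal(nrow(annotate_read(mk_aln("r2", "chr1", 5000, 5022), idx)), 0)
})

test_that("ratio 1 requires full containment; one base outside rejects", {
  feats <- mk_feat("m1", 100, 130)
  idx <- feature_index(feats)
  inside <- mk_aln("r1", "chr1", 105, 127)
  expect_equal(compute_overlap_ratio(inside, feats)$r_olp, 1)
  expect_equal(nrow(annotate_read(inside, idx, min_ratio = 1)), 1)

  over <- mk_aln("r2", "chr1", 99, 121)   # one base before the feature
  expect_lt(compute_overlap_ratio(over, feats)$r_olp, 1)
  expect_equal(nrow(annotate_read(over, idx, min_ratio = 1)), 0)
  over2 <- mk_aln("r3", "chr1", 109, 131) # one base past the feature
  expect_equal(nrow(annotate_read(over2, idx, min_ratio = 1)), 0)

  # containment <=> ratio 1 on random intervals
  set.seed(41)
  for (k in 1:50) {
    s <- sample.int(1000, 1); e <- s + sample(15:40, 1)
    fs <- sample.int(1000, 1); fe <- fs + sample(15:60, 1)
    a <- mk_aln("rx", "chr1", s, e)
    f <- mk_feat("fx", fs, fe)
    contained <- fs <= s && e <= fe
    expect_equal(compute_overlap_ratio(a, f)$r_olp == 1, contained)
    expect_equal(nrow(annotate_read(a, feature_index(f), min_ratio = 1)) == 1,
                 contained)
  }
})

test_that("strand handling: same-strand default, ignore-strand option", {
  f_minus <- mk_feat("m1", 100, 130, strand = "-")
  idx <- feature_index(f_minus)
  a_plus <- mk_aln("r1", "chr1", 105, 127, strand = "+")
  expect_equal(nrow(annotate_read(a_plus, idx)), 0)
  expect_equal(nrow(annotate_read(a_plus, idx, strand_mode = "ignore")), 1)
  a_minus <- mk_aln("r1", "chr1", 105, 127, strand = "-")
  expect_equal(nrow(annotate_read(a_minus, idx)), 1)
})

test_that("lowering the overlap threshold never decreases any count", {
  gf <- make_genome(seed = 8, genome_len = 8000)
  rd <- make_reads(seed = 8, gf, n_intergenic = 8, n_bad = 0, n_microbial = 0)
  qc <- run_qc(rd$reads)
  al <- micro_align(qc$reads, gf$genome, 1)
  idx <- feature_index(gf$features)
  counts_at <- function(ratio) {
    q <- quantify(al$alignments, idx, min_ratio = ratio)
    out <- unlist(lapply(q$counts, function(d)
      stats::setNames(d$Count, d$Name)))
    out
  }
  ratios <- c(1, 0.8, 0.5, 0.2)
  tabs <- lapply(ratios, counts_at)
  for (i in seq_len(length(ratios) - 1)) {
    shared <- names(tabs[[i]])
    expect_true(all(tabs[[i + 1]][shared] >= tabs[[i]][shared]))
  }
})

test_that("quantify equals the per-read annotate_read tally", {
  gf <- make_genome(seed = 9, genome_len = 8000)
  rd <- make_reads(seed = 9, gf, n_intergenic = 6, n_bad = 0, n_microbial = 0)
  qc <- run_qc(rd$reads)
  al <- micro_align(qc$reads, gf$genome, 1)
  idx <- feature_index(gf$features)
  q <- quantify(al$alignments, idx)

  # oracle: per-read molecule sets, then tally
  tally <- list()
  for (rid in unique(al$alignments$read_id)) {
    grp <- al$alignments[al$alignments$read_id == rid, , drop = FALSE]
    ann <- annotate_read(grp, idx)
    for (j in seq_len(nrow(ann))) {
      key <- paste(ann$rna_type[j], ann$name[j], sep = ":")
      tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
    }
  }
  for (tp in names(q$counts)) {
    d <- q$counts[[tp]]
    for (j in seq_len(nrow(d))) {
      expect_equal(d$Count[j], tally[[paste(tp, d$Name[j], sep = ":")]],
                   info = paste(tp, d$Name[j]))
    }
  }
  expect_equal(sum(unlist(tally)), sum(unlist(lapply(q$counts, function(d)
    sum(d$Count)))))

  # per-read, per-molecule contribution is at most one
  ann <- q$read_annotations
  expect_false(any(duplicated(ann[, c("read_id", "rna_type", "name")])))
})

test_that("per-type export honors the no-priority rule and rejects bad types", {
  feats <- rbind(
    mk_feat("mi1", 100, 122, rna_type = "miRNA"),
    mk_feat("pi1", 100, 130, rna_type = "piRNA"),
    mk_feat("mi2", 500, 530, rna_type = "miRNA"))
  idx <- feature_index(feats)
  aln <- rbind(mk_aln("both", "chr1", 100, 122),
               mk_aln("mionly", "chr1", 505, 527),
               mk_aln("neither", "chr1", 2000, 2022))
  genome <- c(chr1 = strrep("A", 3000))
  q <- quantify(aln, idx)

  expect_error(export_reads_by_type(aln, q$read_annotations, "junkRNA",
                                    genome, tempfile()), "valid types")

  p_mi <- tempfile(fileext = ".sam"); p_pi <- tempfile(fileext = ".sam")
  p_tr <- tempfile(fileext = ".sam")
  export_reads_by_type(aln, q$read_annotations, "miRNA", genome, p_mi)
  export_reads_by_type(aln, q$read_annotations, "piRNA", genome, p_pi)
  export_reads_by_type(aln, q$read_annotations, "tRNA", genome, p_tr)
  ids_in <- function(p) unique(ingest_sam(p)$alignments$read_id)
  expect_setequal(ids_in(p_mi), c("both", "mionly"))
  expect_setequal(ids_in(p_pi), "both")   # dual-typed read in both exports
  expect_length(ids_in(p_tr), 0)
})

test_that("count files carry exactly the four annotation columns", {
  feats <- mk_feat("m1", 100, 130)
  q <- quantify(mk_aln("r1", "chr1", 104, 126), feature_index(feats))
  d <- tempfile()
  paths <- write_count_files(q$counts, d, prefix = "s1")
  tab <- read.delim(file.path(d, "s1_miRNA.txt"))
  expect_identical(names(tab), c("DB", "Name", "ID", "Count"))
  expect_equal(tab$Count, 1)
})
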