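toy_tree <- function() {
  load_taxonomy(data.frame(
    taxid = c(1, 2, 10, 11, 12, 20, 21),
    parent = c(1, 1, 2, 10, 10, 2, 20),
    rank = c("root", "superkingdom", "genus", "species", "species",
             "genus", "species"),
    name = c("root", "Bacteria", "genusA", "spA1", "spA2", "genusB", "spB1"),
    group = c("other", rep("bacteria", 6)),
    stringsAsFactors = FALSE))
}

hit_row <- function(query, subject, identity = 99, evalue = 1e-8,
                    bits = 44, taxid = NA) {
  data.frame(query_id = query, subject_id = subject, pct_identity = identity,
             align_len = 22L, mismatches = 0L, gap_opens = 0L, q_start = 1L,
             q_end = 22L, s_start = 10L, s_end = 31L, evalue = evalue,
             bitscore = bits, taxid = taxid, stringsAsFactors = FALSE)
}

test_that("BLAST tabular parsing validates shape and maps accessions to taxa", {
  p <- tempfile()
  writeLines(character(0), p)
  a2t <- data.frame(accession = c("accA", "accB"), taxid = c(11L, 12L))
  h <- parse_blast_tabular(p, a2t)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "dropped"), 0)

  writeLines(c("q1\taccA\t100.0\t22\t0\t0\t1\t22\t10\t31\t1e-9\t44",
               "q1\taccB\t95.45\t22\t1\t0\t1\t22\t40\t61\t1e-7\t40",
               "q2\taccA\t100.0\t20\t0\t0\t1\t20\t5\t24\t1e-8\t40"), p)
  h <- parse_blast_tabular(p, a2t)
  expect_equal(nrow(h), 3)
  expect_equal(h$taxid, c(11L, 12L, 11L))
  expect_equal(h$pct_identity[2], 95.45)
  expect_equal(h$s_start[3], 5L)

  writeLines(c("q1\taccA\t100.0\t22\t0\t0\t1\t22\t10\t31\t1e-9\t44",
               "q1\taccX\t100.0\t22\t0\t0\t1\t22\t10\t31\t1e-9\t44",
               "q2\taccB\t100.0\t22\t0\t0\t1\t22\t10\t31\t1e-9\t44"), p)
  expect_message(h2 <- parse_blast_tabular(p, a2t), "dropped")
  expect_equal(nrow(h2), 2)
  expect_equal(attr(h2, "dropped"), 1)

  writeLines("q1\taccA\t100.0\t22", p)
  expect_error(parse_blast_tabular(p, a2t), "12 columns")
})

test_that("hit writing and parsing round-trip", {
  h <- rbind(hit_row("q1", "accA"), hit_row("q2", "accB", identity = 95.45))
  p <- tempfile()
  write_blast_tabular(h, p)
  a2t <- data.frame(accession = c("accA", "accB"), taxid = c(11L, 12L))
  back <- parse_blast_tabular(p, a2t)
  expect_equal(back$query_id, h$query_id)
  expect_equal(back$pct_identity, h$pct_identity)
  expect_equal(back$evalue, h$evalue)
})

test_that("taxonomy loading enforces tree structure", {
  expect_error(load_taxonomy(data.frame(
    taxid = c(1, 2), parent = c(1, 2), rank = "x", name = c("a", "b"),
    group = "other")), "exactly one root")
  expect_error(load_taxonomy(data.frame(
    taxid = c(1, 2), parent = c(1, 99), rank = "x", name = c("a", "b"),
    group = "other")), "not present")
  expect_error(load_taxonomy(data.frame(
    taxid = c(1, 2), parent = c(1, 1), rank = "x", name = c("a", "b"),
    group = c("other", "weird"))), "unknown taxonomy group")
  tr <- toy_tree()
  expect_equal(taxonomy_ancestors(tr, 11), c(11, 10, 2, 1))
})

test_that("nodes/names dump parsing derives groups from top-level taxa", {
  nodes <- tempfile(); nms <- tempfile()
  writeLines(c("1\t|\t1\t|\troot\t|",
               "2\t|\t1\t|\tsuperkingdom\t|",
               "7\t|\t2\t|\tspecies\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
               "7\t|\tCoolibacter demo\t|\t\t|\tscientific name\t|"), nms)
  tr <- load_taxonomy_dump(nodes, nms)
  expect_equal(tr$group[tr$taxid == 7], "bacteria")
  expect_equal(tr$group[tr$taxid == 1], "other")
  expect_equal(tr$name[tr$taxid == 7], "Coolibacter demo")
})

test_that("per-read taxon assignment keeps all passing taxa without bias", {
  tr <- toy_tree()
  hits <- rbind(hit_row("q1", "a", taxid = 11),
                hit_row("q1", "b", taxid = 12, bits = 40))
  expect_equal(assign_read_taxa(hits), c(11, 12))
  expect_equal(assign_read_taxa(hits, best_hit_only = TRUE), 11)

  # filters: failing hits contribute nothing
  weak <- rbind(hit_row("q1", "a", taxid = 11, evalue = 1),
                hit_row("q1", "b", taxid = 12, identity = 80))
  expect_length(assign_read_taxa(weak), 0)

  # duplicates collapse within a read
  dup <- do.call(rbind, replicate(5, hit_row("q1", "a", taxid = 11),
                                  simplify = FALSE))
  expect_equal(assign_read_taxa(dup), 11)

  expect_error(assign_read_taxa(rbind(hit_row("q1", "a", taxid = 11),
                                      hit_row("q2", "a", taxid = 11))),
               "single read")
})

test_that("taxon counting rolls up the tree with per-read deduplication", {
  tr <- toy_tree()
  # one read hitting two species of one genus: genus rollup is 1, not 2
  tc <- count_taxa(list(r1 = c(11L, 12L)), tr)
  expect_equal(tc$count[tc$taxid == 10], 1)
  expect_equal(tc$count[tc$taxid == 11], 1)
  expect_equal(tc$count_direct[tc$taxid == 10], 0)

  expect_equal(nrow(count_taxa(list(), tr)), 0)

  # chain propagation: two reads to one species count 2 at every ancestor
  tc2 <- count_taxa(list(r1 = 11L, r2 = 11L), tr)
  for (t in c(11, 10, 2, 1)) expect_equal(tc2$count[tc2$taxid == t], 2)

  expect_error(count_taxa(list(r1 = 999L), tr), "999")
})

test_that("rollup counts equal the brute-force ancestor-union tally", {
  mb <- make_microbe_fixture(seed = 5)
  tr <- mb$taxonomy
  set.seed(55)
  species <- tr$taxid[tr$rank == "species"]
  read_taxa <- lapply(1:60, function(i) {
    sort(sample(species, sample(0:3, 1)))
  })
  names(read_taxa) <- paste0("r", 1:60)
  got <- count_taxa(read_taxa, tr)
  exp <- oracle_taxa_rollup(read_taxa, tr)
  for (i in seq_len(nrow(got))) {
    expect_equal(got$count[i], unname(exp[as.character(got$taxid[i])]))
  }
  expect_setequal(as.character(got$taxid), names(exp[exp > 0]))

  # rollup bounds: child max <= parent rollup <= sum of children (+direct)
  for (t in tr$taxid) {
    kids <- tr$taxid[tr$parent == t & tr$taxid != t]
    if (length(kids) == 0) next
    kid_counts <- exp[as.character(kids)]
    expect_gte(exp[as.character(t)], max(kid_counts))
    expect_lte(exp[as.character(t)],
               sum(kid_counts) + sum(vapply(read_taxa, function(x)
                 t %in% x, logical(1))))
  }

  # disjoint group subtrees partition the root rollup
  nonempty <- read_taxa[lengths(read_taxa) > 0]
  groups <- c("Archaea", "Bacteria", "Fungi", "Viruses")
  tops <- tr$taxid[tr$name %in% groups]
  expect_equal(sum(exp[as.character(tops)]),
               unname(exp["1"]) +
                 sum(vapply(nonempty, function(x) {
                   length(unique(tr$group[match(x, tr$taxid)])) - 1L
                 }, integer(1))))
})

test_that("micro-matcher reports all plantings in BLAST shape", {
  mb <- make_microbe_fixture(seed = 1)
  h <- micro_match(mb$reads, mb$refs, max_mismatch = 1)
  # read planted in two references -> two subjects
  h1 <- h[h$query_id == "mb_read_1", ]
  expect_setequal(h1$subject_id, c("ACC_Bacsp1", "ACC_Bacsp2"))
  expect_true(all(h1$pct_identity == 100))
  # read planted in one reference -> one hit at 100% identity
  expect_equal(sum(h$query_id == "mb_read_2"), 1)
  # read planted nowhere -> no hits
  expect_equal(sum(h$query_id == "mb_read_4"), 0)

  # full chain reproduces the fixture truth
  h$taxid <- mb$acc2taxid$taxid[match(h$subject_id, mb$acc2taxid$accession)]
  rt <- assign_all_read_taxa(h)
  for (id in names(mb$truth)) {
    got <- if (id %in% names(rt)) rt[[id]] else integer(0)
    expect_equal(got, mb$truth[[id]], info = id)
  }
})
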