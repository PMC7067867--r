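#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads 12-column tab-delimited BLAST hits and attaches a taxon id to each
#' hit through an accession-to-taxid map. Hits whose subject accession has
#' no taxid mapping are dropped; the number dropped is recorded in the
#' `"dropped"` attribute of the result.
#'
#' @param path path to the tabular hit file.
#' @param acc2taxid a data frame with columns `accession` and `taxid`, or a
#'   2-column tab-delimited file path.
#' @return a data frame of hits (`query_id`, `subject_id`, `pct_identity`,
#'   `align_len`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bitscore`, `taxid`) with attribute `dropped`.
#' @export
parse_blast_tabular <- function(path, acc2taxid) {
  if (is.character(acc2taxid)) {
    acc2taxid <- utils::read.table(acc2taxid, sep = "\t", header = FALSE,
                                   col.names = c("accession", "taxid"),
                                   stringsAsFactors = FALSE)
  }
  cols <- c("query_id", "subject_id", "pct_identity", "align_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 13))
    names(out) <- c(cols, "taxid")
    attr(out, "dropped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    stop("line ", which(nf != 12)[1], " of '", path, "': expected 12 columns, got ",
         nf[nf != 12][1])
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), align_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (any(out$align_len <= 0)) stop("non-positive alignment length in '", path, "'")
  out$taxid <- acc2taxid$taxid[match(out$subject_id, acc2taxid$accession)]
  dropped <- sum(is.na(out$taxid))
  if (dropped) {
    message(dropped, " hit(s) dropped: no taxid mapping for their accession")
  }
  out <- out[!is.na(out$taxid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Load a taxonomy tree
#'
#' Accepts either a 5-column tab-delimited file (`taxid`, `parent`, `rank`,
#' `name`, `group`, with a header line) or a data frame in the same shape.
#' The tree must be acyclic with a single root (a node whose parent is
#' itself, as in the NCBI dumps); every other node's parent must exist.
#' `group` places each node in one of the four reported microbial groups
#' (`archaea`, `bacteria`, `fungi`, `viruses`) or `other`.
#'
#' @param x path or data frame.
#' @return a validated taxonomy data frame of class `taxonomy`.
#' @export
load_taxonomy <- function(x) {
  if (is.character(x)) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("taxid", "parent", "rank", "name", "group") %in% names(x)))
  x$taxid <- as.integer(x$taxid); x$parent <- as.integer(x$parent)
  if (anyDuplicated(x$taxid)) stop("duplicate taxid in taxonomy")
  roots <- x$taxid[x$taxid == x$parent]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one root (taxid == parent); found ",
         length(roots))
  }
  if (!all(x$parent %in% x$taxid)) {
    stop("taxonomy parent(s) not present: ",
         paste(setdiff(x$parent, x$taxid), collapse = ", "))
  }
  bad <- setdiff(unique(x$group),
                 c("archaea", "bacteria", "fungi", "viruses", "other"))
  if (length(bad)) stop("unknown taxonomy group(s): ", paste(bad, collapse = ", "))
  # cycle check: every node must reach the root
  for (t in x$taxid) taxonomy_ancestors(x, t)
  class(x) <- c("taxonomy", "data.frame")
  x
}

#' Load a taxonomy from NCBI-style nodes/names dump files
#'
#' Parses the `\\t|\\t`-delimited `nodes.dmp` / `names.dmp` dialect
#' (scientific names only). Group membership is derived from the named
#' top-level taxa: nodes under `Archaea`, `Bacteria`, `Fungi` or `Viruses`
#' inherit that group; everything else is `other`.
#'
#' @param nodes_path path to a nodes.dmp-style file.
#' @param names_path path to a names.dmp-style file.
#' @return a taxonomy data frame (see [load_taxonomy()]).
#' @export
load_taxonomy_dump <- function(nodes_path, names_path) {
  split_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lapply(strsplit(sub("\t\\|$", "", lines), "\t\\|\t"), trimws)
  }
  nodes <- split_dmp(nodes_path)
  nm <- split_dmp(names_path)
  nm <- nm[vapply(nm, function(p) length(p) >= 4 &&
                    p[4] == "scientific name", logical(1))]
  name_map <- stats::setNames(vapply(nm, `[`, character(1), 2),
                              vapply(nm, `[`, character(1), 1))
  tx <- data.frame(
    taxid = as.integer(vapply(nodes, `[`, character(1), 1)),
    parent = as.integer(vapply(nodes, `[`, character(1), 2)),
    rank = vapply(nodes, `[`, character(1), 3),
    stringsAsFactors = FALSE)
  tx$name <- unname(name_map[as.character(tx$taxid)])
  tx$name[is.na(tx$name)] <- paste0("taxid_", tx$taxid[is.na(tx$name)])
  tx$group <- "other"
  for (g in c("archaea", "bacteria", "fungi", "viruses")) {
    top <- tx$taxid[tolower(tx$name) == g]
    if (length(top) == 1) {
      under <- vapply(tx$taxid, function(t)
        top %in% ancestors_raw(tx, t), logical(1))
      tx$group[under] <- g
    }
  }
  load_taxonomy(tx)
}

# Ancestors (self included) walking parent pointers; errors on cycles.
ancestors_raw <- function(tree, taxid) {
  out <- integer(0)
  t <- taxid
  repeat {
    if (t %in% out) stop("cycle detected in taxonomy at taxid ", t)
    out <- c(out, t)
    i <- match(t, tree$taxid)
    if (is.na(i)) stop("unknown taxid ", t)
    p <- tree$parent[i]
    if (p == t) break
    t <- p
  }
  out
}

#' Ancestors of a taxon (self included)
#'
#' @param tree a taxonomy data frame.
#' @param taxid taxon id present in the tree.
#' @return integer vector of taxids from `taxid` up to the root.
#' @export
taxonomy_ancestors <- function(tree, taxid) ancestors_raw(tree, taxid)

#' Taxa supported by one read's BLAST hits
#'
#' Because of sequence homology a read often hits many species; all
#' distinct taxa passing the screening filters are retained — no best-hit
#' selection and no lowest-common-ancestor collapse — so every potential
#' source taxon is reported without bias. Set `best_hit_only = TRUE` to
#' keep only the top-bitscore hit's taxon.
#'
#' @param hits BLAST hit data frame for a single read (shared `query_id`).
#' @param max_evalue,min_identity screening filters (conventional BLAST
#'   screening defaults; the taxon listing itself applies no reduction).
#' @param best_hit_only keep only the highest-bitscore hit.
#' @return integer vector of distinct taxids (possibly empty).
#' @export
assign_read_taxa <- function(hits, max_evalue = 1e-3, min_identity = 90,
                             best_hit_only = FALSE) {
  if (nrow(hits) == 0) return(integer(0))
  if (length(unique(hits$query_id)) != 1) {
    stop("assign_read_taxa expects hits for a single read")
  }
  pass <- hits$evalue <= max_evalue & hits$pct_identity >= min_identity
  hits <- hits[pass, , drop = FALSE]
  if (nrow(hits) == 0) return(integer(0))
  if (best_hit_only) hits <- hits[which.max(hits$bitscore), , drop = FALSE]
  sort(unique(as.integer(hits$taxid)))
}

#' Per-read taxon sets for a whole hit table
#'
#' @param hits BLAST hit data frame (any number of reads).
#' @inheritParams assign_read_taxa
#' @return named list of taxid vectors, one element per read.
#' @export
assign_all_read_taxa <- function(hits, max_evalue = 1e-3, min_identity = 90,
                                 best_hit_only = FALSE) {
  if (nrow(hits) == 0) return(stats::setNames(list(), character(0)))
  sp <- split(hits, hits$query_id)
  lapply(sp, assign_read_taxa, max_evalue = max_evalue,
         min_identity = min_identity, best_hit_only = best_hit_only)
}

#' Count reads per taxon with phylogenetic rollup
#'
#' The direct count of a taxon is the number of reads whose taxon set
#' contains it. The rollup count at any node is the number of reads whose
#' set contains *any* descendant-or-self of that node — a read counts at
#' most once per ancestor even when it supports several descendants (e.g. a
#' read assigned to two species of one genus adds 1, not 2, to the genus).
#'
#' @param read_taxa named list of per-read taxid vectors, as returned by
#'   [assign_all_read_taxa()].
#' @param tree a taxonomy data frame.
#' @return a data frame `taxid`, `name`, `rank`, `group`, `count`
#'   (rollup), `count_direct`, ordered by group then decreasing count;
#'   taxa with zero rollup count are omitted.
#' @export
count_taxa <- function(read_taxa, tree) {
  rollup <- integer(nrow(tree)); names(rollup) <- tree$taxid
  direct <- rollup
  for (taxa in read_taxa) {
    if (length(taxa) == 0) next
    anc <- unique(unlist(lapply(taxa, function(t) {
      if (!t %in% tree$taxid) stop("unknown taxid ", t)
      ancestors_raw(tree, t)
    })))
    rollup[as.character(anc)] <- rollup[as.character(anc)] + 1L
    dt <- unique(taxa)
    direct[as.character(dt)] <- direct[as.character(dt)] + 1L
  }
  out <- data.frame(taxid = tree$taxid, name = tree$name, rank = tree$rank,
                    group = tree$group, count = unname(rollup),
                    count_direct = unname(direct), stringsAsFactors = FALSE)
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$group, -out$count, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-group taxon counts
#'
#' @param taxon_counts result of [count_taxa()].
#' @param path output TSV path.
#' @param groups groups to include, in order.
#' @return `path`, invisibly.
#' @export
write_taxa_counts <- function(taxon_counts, path,
                              groups = c("archaea", "bacteria", "fungi",
                                         "viruses")) {
  out <- taxon_counts[taxon_counts$group %in% groups, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exhaustive micro-matcher emitting BLAST-shaped hits
#'
#' A deterministic stand-in for an external sequence-similarity search at
#' fixture scale: every end-to-end placement of each read inside each
#' reference sequence (both strands, at most `max_mismatch` substitutions)
#' is emitted as a 12-column tabular hit. Identity and score fields are
#' synthesized deterministically from the match (`pident` from the
#' mismatch fraction, bitscore `2 * matched bases`, e-value
#' `10^-(10 - 3*mismatches)`).
#'
#' @param reads an `srna_reads` object (genome-unmapped reads).
#' @param refs reference sequences: a `DNAStringSet`, named character
#'   vector or FASTA path (names are the subject accessions).
#' @param max_mismatch maximum substitutions per placement.
#' @return a BLAST-hit data frame as from [parse_blast_tabular()] but
#'   without the `taxid` column.
#' @export
micro_match <- function(reads, refs, max_mismatch = 1L) {
  refs <- load_genome(refs)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if (!nzchar(s)) next
    pat <- Biostrings::DNAString(s)
    rcp <- Biostrings::reverseComplement(pat)
    L <- nchar(s)
    for (acc in names(refs)) {
      subj <- refs[[acc]]
      if (L > length(subj)) next
      for (str in c("+", "-")) {
        p <- if (str == "+") pat else rcp
        m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        for (k in seq_along(m)) {
          mm <- str_mismatches(as.character(m[[k]]), as.character(p))
          st <- BiocGenerics::start(m)[k]; en <- BiocGenerics::end(m)[k]
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = reads$id[i], subject_id = acc,
            pct_identity = round(100 * (L - mm) / L, 2),
            align_len = L, mismatches = mm, gap_opens = 0L,
            q_start = 1L, q_end = L,
            s_start = if (str == "+") st else en,
            s_end = if (str == "+") en else st,
            evalue = 10^-(10 - 3 * mm), bitscore = 2 * (L - mm),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- parse_blast_empty()
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

parse_blast_empty <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), align_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write hits in BLAST tabular (outfmt 6) form
#'
#' @param hits a hit data frame (taxid column, if present, is not written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "align_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
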