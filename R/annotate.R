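#' Load a small-RNA feature database
#'
#' Feature databases are BED6-like tab-delimited text: `chrom`, `start`,
#' `end` (0-based half-open, as in BED), `name`, `id`, `strand`. `track`
#' and `#` comment lines are skipped. Each record is tagged with the
#' database of origin and the RNA type it annotates. A molecule is
#' identified by its `(rna_type, name)` pair and may own several intervals
#' (multi-locus genes); exact duplicate records are dropped on load.
#'
#' @param path path to the database file.
#' @param db_name database-of-origin label (e.g. the source catalogue).
#' @param rna_type one of [rna_types()].
#' @return a feature data frame: `db`, `rna_type`, `name`, `id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
load_feature_db <- function(path, db_name, rna_type) {
  rna_type <- match.arg(rna_type, rna_types())
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(raw)
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0) return(empty_features())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  feats <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 6) {
      stop("line ", lineno[i], " of '", path, "': expected 6 columns, got ",
           length(p))
    }
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", lineno[i], " of '", path, "': non-numeric coordinates")
    }
    if (start >= end) {
      stop("line ", lineno[i], " of '", path, "': start >= end (", start,
           " >= ", end, ")")
    }
    if (!p[6] %in% c("+", "-")) {
      stop("line ", lineno[i], " of '", path, "': bad strand '", p[6], "'")
    }
    feats[[i]] <- data.frame(db = db_name, rna_type = rna_type,
                             name = p[4], id = p[5], chrom = p[1],
                             start = start, end = end, strand = p[6],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, feats)
  dup <- duplicated(out)
  if (any(dup)) {
    message(sum(dup), " duplicate feature line(s) dropped from '", path, "'")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Valid RNA type labels
#' @return character vector of recognized small-RNA classes.
#' @export
rna_types <- function() {
  c("miRNA", "piRNA", "snRNA", "snoRNA", "tRNA", "circRNA", "other")
}

empty_features <- function() {
  data.frame(db = character(0), rna_type = character(0), name = character(0),
             id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), stringsAsFactors = FALSE)
}

#' Build an interval index over feature records
#'
#' Wraps the feature table in a per-chromosome interval index
#' (a [GenomicRanges::GRanges] under the hood) so overlap queries do not
#' scan the whole database.
#'
#' @param features a feature data frame, e.g. from [load_feature_db()]
#'   (several databases may be `rbind`-ed first).
#' @return an object of class `feature_index`.
#' @export
feature_index <- function(features) {
  stopifnot(all(c("db", "rna_type", "name", "id", "chrom", "start", "end",
                  "strand") %in% names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  structure(list(features = features, gr = gr), class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat("feature_index:", nrow(x$features), "records,",
      length(unique(paste(x$features$rna_type, x$features$name))),
      "molecules\n")
  invisible(x)
}

#' Query a feature index
#'
#' Returns the rows of the feature table whose interval intersects the
#' query interval (0-based half-open) on the given chromosome.
#'
#' @param index a [feature_index()].
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @param strand optional strand; when given, only same-strand features are
#'   returned.
#' @return integer vector of row indices into `index$features`.
#' @export
query_features <- function(index, chrom, start, end, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start = start + 1L, end = end),
                              strand = if (is.null(strand)) "*" else strand)
  # a chromosome absent from the index is a legal no-hit query
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$gr, ignore.strand = is.null(strand)))
  sort(S4Vectors::subjectHits(hits))
}

#' Overlap ratio between an aligned read and a feature interval
#'
#' The degree of read support for an annotation is the ratio of overlapped
#' bases to read bases, `r_olp = l_olp / l_read`. `l_olp` is the size of
#' the intersection of the alignment's genomic interval with the feature
#' interval (both 0-based half-open); `l_read` is by default the aligned
#' span on the read (soft clips excluded), so an isomiR with clipped
#' non-templated bases can still reach a ratio of 1; set
#' `use_full_read_length = TRUE` to divide by the full read length instead.
#' A ratio of exactly 1 means the read lies completely within the
#' annotation.
#'
#' @param aln one alignment (a 1-row data frame or list with `chrom`,
#'   `start`, `end`, and `read_start`/`read_end`/`read_len`).
#' @param feat one feature (a 1-row data frame or list with `chrom`,
#'   `start`, `end`).
#' @param use_full_read_length divide by total read length rather than the
#'   aligned span.
#' @return a list with `r_olp`, `l_olp`, `l_read`.
#' @export
compute_overlap_ratio <- function(aln, feat, use_full_read_length = FALSE) {
  l_read <- if (use_full_read_length) {
    as.integer(aln$read_len)
  } else {
    as.integer(aln$read_end) - as.integer(aln$read_start)
  }
  if (is.na(l_read) || l_read <= 0) stop("zero-length read span")
  l_olp <- 0L
  if (identical(as.character(aln$chrom), as.character(feat$chrom))) {
    l_olp <- max(0L, min(aln$end, feat$end) - max(aln$start, feat$start))
  }
  list(r_olp = l_olp / l_read, l_olp = as.integer(l_olp), l_read = l_read)
}

# Vectorized molecule assignment over an alignment table. Returns a data
# frame of (read_id, rna_type, name, id, db) pairs: one row per alignment x
# overlapping-feature combination passing the ratio and strand rules,
# BEFORE per-molecule deduplication.
overlap_pairs <- function(alignments, index, min_ratio = 1,
                          strand_mode = c("same", "ignore"),
                          use_full_read_length = FALSE) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(alignments) == 0) {
    return(data.frame(read_id = character(0), rna_type = character(0),
                      name = character(0), id = character(0),
                      db = character(0), stringsAsFactors = FALSE))
  }
  agr <- GenomicRanges::GRanges(
    seqnames = alignments$chrom,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(agr, index$gr,
                                ignore.strand = strand_mode == "ignore"))
  if (strand_mode == "same") {
    same <- as.character(BiocGenerics::strand(agr))[S4Vectors::queryHits(hits)] ==
      as.character(BiocGenerics::strand(index$gr))[S4Vectors::subjectHits(hits)]
    hits <- hits[same]
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  a <- alignments[qi, , drop = FALSE]
  f <- index$features[si, , drop = FALSE]
  l_olp <- pmin(a$end, f$end) - pmax(a$start, f$start)
  l_read <- if (use_full_read_length) a$read_len else a$read_end - a$read_start
  if (any(l_read <= 0)) stop("zero-length read span in alignment table")
  pass <- l_olp >= min_ratio * l_read - 1e-9
  data.frame(read_id = a$read_id[pass], rna_type = f$rna_type[pass],
             name = f$name[pass], id = f$id[pass], db = f$db[pass],
             stringsAsFactors = FALSE)
}

#' Annotate one read's multi-map group
#'
#' Collects every feature whose overlap ratio with any alignment in the
#' group reaches `min_ratio`, then deduplicates at the molecule level
#' (`rna_type`, `name`): a molecule appears at most once no matter how many
#' loci or alignments supported it (the count-once rule for multi-mapped
#' reads), and molecules of *different* types supported by the same
#' alignment are all retained — there is no priority order between RNA
#' types, so a read inside both a miRNA and a piRNA annotation contributes
#' one count to each.
#'
#' @param group alignment data frame for a single read (its multi-map
#'   group).
#' @param index a [feature_index()].
#' @param min_ratio minimum overlap ratio in (0, 1]; the default 1 requires
#'   the read to lie completely within the annotation.
#' @param strand_mode `"same"` (default) requires alignment and feature on
#'   the same strand; `"ignore"` disables the check.
#' @param use_full_read_length see [compute_overlap_ratio()].
#' @return a data frame of assigned molecules: `rna_type`, `name`, `id`
#'   (comma-joined distinct ids), `db` (comma-joined distinct supporting
#'   databases). Zero rows when nothing is assigned.
#' @export
annotate_read <- function(group, index, min_ratio = 1,
                          strand_mode = c("same", "ignore"),
                          use_full_read_length = FALSE) {
  stopifnot(min_ratio > 0, min_ratio <= 1)
  if (nrow(group) && length(unique(group$read_id)) != 1) {
    stop("annotate_read expects the alignments of a single read")
  }
  pairs <- overlap_pairs(group, index, min_ratio = min_ratio,
                         strand_mode = strand_mode,
                         use_full_read_length = use_full_read_length)
  collapse_molecules(pairs)[, c("rna_type", "name", "id", "db")]
}

# Deduplicate (read_id, molecule) pairs and join supporting db/id labels.
collapse_molecules <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(read_id = character(0), rna_type = character(0),
                      name = character(0), id = character(0),
                      db = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(pairs$read_id, pairs$rna_type, pairs$name, sep = "\r")
  sp <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(sp, function(ix) {
    p <- pairs[ix, , drop = FALSE]
    data.frame(read_id = p$read_id[1], rna_type = p$rna_type[1],
               name = p$name[1],
               id = paste(sort(unique(p$id)), collapse = ","),
               db = paste(sort(unique(p$db)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify annotated molecules for one sample
#'
#' Runs the molecule-assignment rules over a whole sample's alignment table
#' and tallies, per RNA type, the number of distinct reads assigned to each
#' molecule. Because a read may legitimately support several molecules
#' (no-priority rule), column sums across molecules can exceed the number
#' of annotated reads; a single read, however, never contributes more than
#' 1 to any one molecule.
#'
#' @inheritParams annotate_read
#' @param alignments alignment data frame for one sample (all reads).
#' @return a list with `counts`: a named list of per-type data frames with
#'   columns `DB`, `Name`, `ID`, `Count` (sorted by decreasing count, then
#'   name); and `read_annotations`: the per-read molecule assignments
#'   (`read_id`, `rna_type`, `name`, `id`, `db`).
#' @export
quantify <- function(alignments, index, min_ratio = 1,
                     strand_mode = c("same", "ignore"),
                     use_full_read_length = FALSE) {
  stopifnot(min_ratio > 0, min_ratio <= 1)
  pairs <- overlap_pairs(alignments, index, min_ratio = min_ratio,
                         strand_mode = strand_mode,
                         use_full_read_length = use_full_read_length)
  ann <- collapse_molecules(pairs)
  types <- intersect(rna_types(), unique(index$features$rna_type))
  counts <- lapply(types, function(tp) {
    a <- ann[ann$rna_type == tp, , drop = FALSE]
    if (nrow(a) == 0) {
      return(data.frame(DB = character(0), Name = character(0),
                        ID = character(0), Count = integer(0),
                        stringsAsFactors = FALSE))
    }
    sp <- split(seq_len(nrow(a)), a$name)
    rows <- lapply(sp, function(ix) {
      dbs <- sort(unique(unlist(strsplit(a$db[ix], ",", fixed = TRUE))))
      ids <- sort(unique(unlist(strsplit(a$id[ix], ",", fixed = TRUE))))
      data.frame(DB = paste(dbs, collapse = ","),
                 Name = a$name[ix][1],
                 ID = paste(ids, collapse = ","),
                 Count = length(unique(a$read_id[ix])),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$Count, out$Name), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(counts) <- types
  list(counts = counts, read_annotations = ann)
}

#' Write per-type count tables
#'
#' One tab-delimited file per RNA type with the four columns `DB`, `Name`,
#' `ID`, `Count`.
#'
#' @param counts the `counts` element of a [quantify()] result.
#' @param dir output directory.
#' @param prefix filename prefix (typically the sample name).
#' @return named character vector of written paths, invisibly.
#' @export
write_count_files <- function(counts, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(counts), function(tp) {
    p <- file.path(dir, paste0(prefix, "_", tp, ".txt"))
    utils::write.table(counts[[tp]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Export the alignments of reads annotated to one RNA type
#'
#' Writes, in SAM format, every alignment record whose read was assigned to
#' at least one molecule of the requested type. Under the no-priority rule
#' a read annotated to both a miRNA and a piRNA appears in both type
#' exports.
#'
#' @param alignments a sample's alignment data frame.
#' @param read_annotations the `read_annotations` element of a
#'   [quantify()] result.
#' @param rna_type the type to export.
#' @param genome genome for the SAM header (see [write_sam()]).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
export_reads_by_type <- function(alignments, read_annotations, rna_type,
                                 genome, path) {
  if (!rna_type %in% rna_types()) {
    stop("unknown RNA type '", rna_type, "'; valid types: ",
         paste(rna_types(), collapse = ", "))
  }
  ids <- unique(read_annotations$read_id[read_annotations$rna_type == rna_type])
  write_sam(alignments[alignments$read_id %in% ids, , drop = FALSE],
            genome, path)
}
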