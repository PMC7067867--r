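#' Load a reference genome
#'
#' Accepts a FASTA path, a named character vector or a
#' [Biostrings::DNAStringSet]; returns a `DNAStringSet` with unique names.
#'
#' @param genome genome in any of the accepted forms.
#' @return a `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome vector must be named by chromosome")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) stop("unsupported genome input")
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names in genome")
  genome
}

empty_alignments <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_mismatch = integer(0), read_start = integer(0),
             read_end = integer(0), read_len = integer(0),
             seq = character(0), stringsAsFactors = FALSE)
}

#' Exhaustively align short reads against a small genome
#'
#' A self-contained micro-aligner for test-scale genomes: every end-to-end
#' placement of each read, on both strands, with at most `max_mismatch`
#' substitutions (Hamming distance; no indels, no soft clips) is reported.
#' All placements of a read form its multi-map group. Reads with no
#' placement are returned as the unmapped set. This is not a replacement
#' for a production aligner (use [ingest_sam()] for real alignments); it
#' exists so the annotation counting rules can be exercised end-to-end
#' without external tools.
#'
#' @param reads an `srna_reads` object of qualified reads.
#' @param genome anything accepted by [load_genome()].
#' @param max_mismatch maximum substitutions per placement (0 or 1 typical).
#' @return a list with `alignments` (data frame: `read_id`, `chrom`,
#'   `start`, `end` 0-based half-open, `strand`, `n_mismatch`,
#'   `read_start`, `read_end` aligned span on the read, `read_len`, `seq`)
#'   and `unmapped` (an `srna_reads` object).
#' @export
micro_align <- function(reads, genome, max_mismatch = 1L) {
  genome <- load_genome(genome)
  stopifnot(max_mismatch >= 0)
  uniq <- unique(reads$seq)
  uniq <- uniq[nzchar(uniq)]
  hit_list <- lapply(uniq, function(s) {
    pat <- Biostrings::DNAString(s)
    rcp <- Biostrings::reverseComplement(pat)
    out <- list()
    for (chrom in names(genome)) {
      subj <- genome[[chrom]]
      if (length(pat) > length(subj)) next
      for (str in c("+", "-")) {
        p <- if (str == "+") pat else rcp
        m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        mm <- vapply(seq_along(m), function(i) {
          str_mismatches(as.character(m[[i]]), as.character(p))
        }, integer(1))
        out[[length(out) + 1L]] <- data.frame(
          seq = s, chrom = chrom,
          start = BiocGenerics::start(m) - 1L, end = BiocGenerics::end(m),
          strand = str, n_mismatch = mm, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  names(hit_list) <- uniq

  aln <- list()
  for (i in seq_len(nrow(reads))) {
    h <- hit_list[[reads$seq[i]]]
    if (is.null(h)) next
    L <- nchar(reads$seq[i])
    aln[[length(aln) + 1L]] <- data.frame(
      read_id = reads$id[i], chrom = h$chrom, start = h$start, end = h$end,
      strand = h$strand, n_mismatch = h$n_mismatch,
      read_start = 0L, read_end = L, read_len = L,
      seq = reads$seq[i], stringsAsFactors = FALSE)
  }
  alignments <- if (length(aln)) do.call(rbind, aln) else empty_alignments()
  rownames(alignments) <- NULL
  mapped_ids <- unique(alignments$read_id)
  unmapped <- reads[!(reads$id %in% mapped_ids), , drop = FALSE]
  list(alignments = alignments, unmapped = unmapped)
}

#' Ingest alignments from a SAM or BAM file
#'
#' Converts records to the internal alignment table: SAM 1-based positions
#' become 0-based half-open coordinates; the aligned span on the read is
#' derived from the CIGAR (soft clips excluded); all records sharing a read
#' id (including secondary alignments) form one multi-map group. Records
#' flagged unmapped are collected separately.
#'
#' @param path path to a SAM (`.sam`) or BAM (`.bam`) file with a header.
#' @return a list with `alignments` (see [micro_align()]) and `unmapped`
#'   (an `srna_reads` object built from the unmapped records).
#' @export
ingest_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM '", path, "': ",
                               conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)

  if (length(ga)) {
    cig <- GenomicAlignments::cigar(ga)
    qranges <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cig, ops = c("M", "I", "=", "X"))
    qspan <- unlist(range(qranges))
    nm <- S4Vectors::mcols(ga)$NM
    nm[is.na(nm)] <- 0L
    alignments <- data.frame(
      read_id = S4Vectors::mcols(ga)$qname,
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      start = BiocGenerics::start(ga) - 1L,
      end = BiocGenerics::end(ga),
      strand = as.character(BiocGenerics::strand(ga)),
      n_mismatch = as.integer(nm),
      read_start = BiocGenerics::start(qspan) - 1L,
      read_end = BiocGenerics::end(qspan),
      read_len = GenomicAlignments::qwidth(ga),
      seq = as.character(S4Vectors::mcols(ga)$seq),
      stringsAsFactors = FALSE)
  } else {
    alignments <- empty_alignments()
  }

  uparam <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  u <- Rsamtools::scanBam(bam, param = uparam)[[1]]
  unmapped <- if (length(u$qname)) {
    q <- as.character(u$qual)
    seqs <- as.character(u$seq)
    q[is.na(q) | nchar(q) != nchar(seqs)] <-
      vapply(nchar(seqs)[is.na(q) | nchar(q) != nchar(seqs)],
             function(n) strrep("I", n), character(1))
    srna_reads(id = u$qname, seq = seqs, qual = q)
  } else {
    srna_reads(character(0), character(0), character(0))
  }
  list(alignments = alignments, unmapped = unmapped)
}

#' Write an alignment table as a SAM file
#'
#' Minimal single-end SAM emitter used for fixtures, round-trips and
#' per-type read export. End-to-end alignments are written with a full-match
#' CIGAR; reverse-strand records carry the reverse-complemented sequence, as
#' SAM requires. The first record of each multi-map group is primary; the
#' rest are flagged secondary.
#'
#' @param alignments an alignment data frame (see [micro_align()]).
#' @param genome anything accepted by [load_genome()]; provides the `@SQ`
#'   header lines.
#' @param path output path ending in `.sam`.
#' @param unmapped optional `srna_reads` of unmapped reads to append as
#'   flag-4 records.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path, unmapped = NULL) {
  genome <- load_genome(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)))
  lines <- hdr
  if (nrow(alignments)) {
    first <- !duplicated(alignments$read_id)
    for (i in seq_len(nrow(alignments))) {
      a <- alignments[i, ]
      flag <- 0L
      if (a$strand == "-") flag <- flag + 16L
      if (!first[i]) flag <- flag + 256L
      seq_out <- a$seq
      if (a$strand == "-") {
        seq_out <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq_out)))
      }
      span <- a$read_end - a$read_start
      cig <- paste0(
        if (a$read_start > 0) paste0(a$read_start, "S") else "",
        span, "M",
        if (a$read_len - a$read_end > 0) paste0(a$read_len - a$read_end, "S")
        else "")
      lines <- c(lines, paste(
        a$read_id, flag, a$chrom, a$start + 1L, 255L, cig, "*", 0L, 0L,
        seq_out, "*", paste0("NM:i:", a$n_mismatch), sep = "\t"))
    }
  }
  if (!is.null(unmapped) && nrow(unmapped)) {
    lines <- c(lines, paste(unmapped$id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                            unmapped$seq, unmapped$qual, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
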