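#' Quality-control configuration
#'
#' Bundles the parameters of the read quality-control stage. Defaults mirror
#' the common small-RNA library layout from randomized-ligation kits (e.g.
#' NEXTflex): a 3' sequencing adapter, 4 randomized bases at each ligation
#' junction, removal of reads whose mean PHRED is at or below 20 (`-rr 20`),
#' stripping of terminal bases at or below PHRED 20 (`-rh 20 -rt 20`), and a
#' qualified length window of 15-45 nt.
#'
#' @param adapter 3' adapter sequence to trim.
#' @param n_random_5p,n_random_3p number of randomized ligation bases to
#'   remove from the 5' and 3' ends after adapter trimming.
#' @param min_mean_phred reads with mean PHRED at or *below* this value are
#'   discarded (inclusive boundary).
#' @param head_phred,tail_phred leading/trailing bases with PHRED at or
#'   below these values are stripped.
#' @param min_len,max_len closed length interval a qualified read must fall
#'   in.
#' @param min_overlap minimum adapter prefix length considered a match.
#' @param max_mismatch_rate maximum fraction of mismatched bases tolerated
#'   in an adapter match.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                      n_random_5p = 4L, n_random_3p = 4L,
                      min_mean_phred = 20, head_phred = 20, tail_phred = 20,
                      min_len = 15L, max_len = 45L,
                      min_overlap = 3L, max_mismatch_rate = 0.1) {
  stopifnot(n_random_5p >= 0, n_random_3p >= 0,
            min_mean_phred >= 0, head_phred >= 0, tail_phred >= 0,
            min_len >= 0, max_len >= 0, min_len <= max_len,
            min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 1)
  structure(list(
    adapter = toupper(adapter),
    n_random_5p = as.integer(n_random_5p), n_random_3p = as.integer(n_random_3p),
    min_mean_phred = min_mean_phred, head_phred = head_phred,
    tail_phred = tail_phred,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_overlap = as.integer(min_overlap), max_mismatch_rate = max_mismatch_rate
  ), class = "qc_config")
}

# Hamming distance of two equal-length strings.
str_mismatches <- function(a, b) {
  if (!nzchar(a)) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# Leftmost read position (1-based) at which a prefix of the adapter matches
# through to the read end within the mismatch tolerance, or NA. The adapter
# prefix is anchored at the 3' side: at each candidate start the compared
# window runs to the read end (or to the full adapter, whichever is shorter),
# so an internal full-adapter hit also trims away any downstream filler.
adapter_hit_at <- function(seq, adapter, min_overlap, max_mismatch_rate) {
  L <- nchar(seq); alen <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  for (i in seq_len(L - min_overlap + 1L)) {
    ov <- min(alen, L - i + 1L)
    allowed <- floor(ov * max_mismatch_rate)
    mm <- str_mismatches(substr(seq, i, i + ov - 1L), substr(adapter, 1L, ov))
    if (mm <= allowed) return(i)
  }
  NA_integer_
}

#' Trim 3' sequencing adapters from reads
#'
#' At each read position the adapter's prefix (of length at least
#' `min_overlap`) is compared against the read suffix; the read is truncated
#' at the leftmost position where the mismatch fraction does not exceed
#' `max_mismatch_rate` (cutadapt-like semantics). Qualities are truncated in
#' lockstep. Reads without a match are returned unchanged.
#'
#' @param reads an `srna_reads` object.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum match length.
#' @param max_mismatch_rate tolerated mismatch fraction.
#' @return trimmed `srna_reads`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L,
                         max_mismatch_rate = 0.1) {
  adapter <- toupper(adapter)
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  hit <- vapply(reads$seq, adapter_hit_at, integer(1),
                adapter = adapter, min_overlap = min_overlap,
                max_mismatch_rate = max_mismatch_rate, USE.NAMES = FALSE)
  keep_to <- ifelse(is.na(hit), nchar(reads$seq), hit - 1L)
  reads$seq <- substr(reads$seq, 1L, keep_to)
  reads$qual <- substr(reads$qual, 1L, keep_to)
  reads
}

#' Remove randomized ligation bases from read ends
#'
#' Removes exactly `n5` leading and `n3` trailing bases (library kits such as
#' NEXTflex add 4 degenerate nucleotides at each ligation junction). A read
#' shorter than `n5 + n3` becomes a legal zero-length read.
#'
#' @param reads an `srna_reads` object (adapter-trimmed).
#' @param n5,n3 non-negative counts of randomized bases at the 5'/3' ends.
#' @return trimmed `srna_reads`.
#' @export
trim_random_bases <- function(reads, n5 = 4L, n3 = 4L) {
  stopifnot(n5 >= 0, n3 >= 0)
  L <- nchar(reads$seq)
  from <- pmin(n5 + 1L, L + 1L)
  to <- pmax(L - n3, from - 1L)
  reads$seq <- substr(reads$seq, from, to)
  reads$qual <- substr(reads$qual, from, to)
  reads
}

#' Mean PHRED score per read
#'
#' @param reads an `srna_reads` object; every read must be non-empty.
#' @return numeric vector of per-read arithmetic mean qualities.
#' @export
mean_phred <- function(reads) {
  if (any(!nzchar(reads$seq))) {
    stop("mean_phred undefined for zero-length read '",
         reads$id[which(!nzchar(reads$seq))[1]], "'")
  }
  vapply(phred_decode(reads$qual), function(q) mean(q), numeric(1))
}

#' Flag reads passing the mean-quality filter
#'
#' A read is discarded when its average PHRED is at or below the threshold
#' (the boundary is inclusive: mean exactly 20 is removed at threshold 20).
#'
#' @param reads an `srna_reads` object of non-empty reads.
#' @param threshold mean-PHRED cutoff.
#' @return logical vector, `TRUE` where the read is kept.
#' @export
filter_by_mean_quality <- function(reads, threshold = 20) {
  mean_phred(reads) > threshold
}

#' Strip low-quality runs from read ends
#'
#' Removes the maximal run of leading bases with PHRED at or below
#' `head_threshold` and the maximal run of trailing bases at or below
#' `tail_threshold`; interior bases are untouched. A read that is
#' low-quality throughout becomes zero-length.
#'
#' @param reads an `srna_reads` object.
#' @param head_threshold,tail_threshold inclusive PHRED cutoffs for the
#'   5' and 3' ends.
#' @return trimmed `srna_reads`.
#' @export
trim_low_quality_ends <- function(reads, head_threshold = 20,
                                  tail_threshold = 20) {
  stopifnot(head_threshold >= 0, tail_threshold >= 0)
  quals <- phred_decode(reads$qual)
  bounds <- vapply(quals, function(q) {
    n <- length(q)
    if (n == 0L) return(c(1L, 0L))
    good_head <- which(q > head_threshold)
    good_tail <- which(q > tail_threshold)
    if (length(good_head) == 0L || length(good_tail) == 0L) return(c(1L, 0L))
    from <- good_head[1]
    to <- good_tail[length(good_tail)]
    if (to < from) return(c(1L, 0L))
    c(from, to)
  }, integer(2))
  reads$seq <- substr(reads$seq, bounds[1, ], bounds[2, ])
  reads$qual <- substr(reads$qual, bounds[1, ], bounds[2, ])
  reads
}

#' Flag reads inside the qualified length interval
#'
#' @param reads an `srna_reads` object.
#' @param min_len,max_len closed interval bounds.
#' @return logical vector, `TRUE` where `min_len <= length <= max_len`.
#' @export
select_length <- function(reads, min_len = 15L, max_len = 45L) {
  stopifnot(min_len <= max_len)
  L <- nchar(reads$seq)
  L >= min_len & L <= max_len
}

#' Run the full quality-control stage
#'
#' Applies, in this fixed order: adapter trimming, removal of randomized
#' ligation bases, stripping of low-quality read ends, removal of reads with
#' low mean quality (evaluated on the end-trimmed sequence), and length
#' selection. The order matters: adapters must come off before the
#' randomized junction bases, which sit immediately inside them.
#'
#' @param input an `srna_reads` object or a FASTQ path.
#' @param config a [qc_config()] object.
#' @param out_fastq optional path; qualified reads are written there.
#' @return a list with `reads` (qualified `srna_reads`), and `report`, a
#'   list holding per-filter in/out counts and the qualified read-length
#'   histogram (`length_hist`, a named integer vector).
#' @export
run_qc <- function(input, config = qc_config(), out_fastq = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  n_in <- nrow(reads)

  reads <- trim_adapter(reads, config$adapter,
                        min_overlap = config$min_overlap,
                        max_mismatch_rate = config$max_mismatch_rate)
  reads <- trim_random_bases(reads, config$n_random_5p, config$n_random_3p)
  reads <- trim_low_quality_ends(reads, config$head_phred, config$tail_phred)

  nonempty <- nzchar(reads$seq)
  n_empty <- sum(!nonempty)
  reads <- reads[nonempty, , drop = FALSE]

  keep_q <- if (nrow(reads)) {
    filter_by_mean_quality(reads, config$min_mean_phred)
  } else logical(0)
  n_lowq <- sum(!keep_q)
  reads <- reads[keep_q, , drop = FALSE]

  keep_len <- select_length(reads, config$min_len, config$max_len)
  n_len <- sum(!keep_len)
  reads <- reads[keep_len, , drop = FALSE]

  hist <- table(factor(nchar(reads$seq),
                       levels = seq(0L, max(config$max_len, 0L))))
  report <- list(
    n_input = n_in,
    n_empty_after_trim = n_empty,
    n_removed_low_mean_quality = n_lowq,
    n_removed_length = n_len,
    n_qualified = nrow(reads),
    length_hist = stats::setNames(as.integer(hist), names(hist))
  )
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  list(reads = reads, report = report)
}

#' Write a QC report as tab-delimited text
#'
#' @param report the `report` element returned by [run_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  counts <- report[setdiff(names(report), "length_hist")]
  lines <- c(
    paste0("#srnakit QC report"),
    paste(names(counts), unlist(counts), sep = "\t"),
    "#length\tcount",
    paste(names(report$length_hist), report$length_hist, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
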