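#' Construct a set of sequencing reads
#'
#' The basic read container used throughout the toolkit: a data frame with
#' one row per read and columns `id` (non-empty identifier), `seq`
#' (nucleotide string over A/C/G/T/N; `U` is normalized to `T` on input)
#' and `qual` (PHRED qualities encoded as an ASCII string, offset 33, same
#' length as `seq`).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param qual either a character vector of PHRED+33 encoded quality
#'   strings, or a list of integer PHRED score vectors (one per read).
#' @return an object of class `srna_reads` (a data frame).
#' @export
srna_reads <- function(id, seq, qual) {
  if (is.list(qual) && !is.character(qual)) qual <- phred_encode(qual)
  id <- as.character(id); seq <- as.character(seq); qual <- as.character(qual)
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(!nzchar(id))) stop("read ids must be non-empty")
  seq <- toupper(chartr("Uu", "Tt", seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid characters in sequence of read '", id[which(bad)[1]], "'")
  }
  if (any(nchar(seq) != nchar(qual))) {
    i <- which(nchar(seq) != nchar(qual))[1]
    stop("sequence/quality length mismatch for read '", id[i], "'")
  }
  structure(
    data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE),
    class = c("srna_reads", "data.frame")
  )
}

#' Decode PHRED+33 quality strings to integer scores
#'
#' @param qual character vector of ASCII-encoded quality strings.
#' @param offset integer ASCII offset (33 for modern Illumina).
#' @return a list of integer vectors, one per input string.
#' @export
phred_decode <- function(qual, offset = 33L) {
  lapply(qual, function(q) {
    if (!nzchar(q)) return(integer(0))
    as.integer(charToRaw(q)) - as.integer(offset)
  })
}

#' Encode integer PHRED scores as ASCII strings
#'
#' @param scores a list of integer vectors (or a single integer vector).
#' @param offset integer ASCII offset.
#' @return character vector of encoded quality strings.
#' @export
phred_encode <- function(scores, offset = 33L) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) {
    if (length(s) == 0) return("")
    if (any(s < 0)) stop("PHRED scores must be >= 0")
    rawToChar(as.raw(as.integer(s) + as.integer(offset)))
  }, character(1))
}

#' Read a FASTQ file into an `srna_reads` object
#'
#' Sequences are uppercased and `U` residues normalized to `T` so that reads
#' from RNA-alphabet sources align against DNA genomes. Qualities are
#' interpreted with a configurable ASCII offset (PHRED+33 by default).
#'
#' @param path path to a FASTQ file (4-line records, uncompressed or gzip).
#' @param offset quality ASCII offset; 33 assumed (modern Illumina).
#' @return an `srna_reads` object.
#' @export
read_fastq <- function(path, offset = 33L) {
  fq <- tryCatch(ShortRead::readFastq(path), error = function(e) e)
  if (inherits(fq, "error")) {
    # readFastq cannot represent RNA-alphabet (U) records; after validating
    # the 4-line structure, parse those directly (U is normalized to T by
    # the srna_reads constructor)
    diagnose_fastq(path)
    lines <- readLines(path, warn = FALSE)
    i <- seq(1L, length(lines), by = 4L)
    if (length(lines) == 0) {
      return(srna_reads(character(0), character(0), character(0)))
    }
    ids <- sub("\\s.*$", "", sub("^@", "", lines[i]))
    seqs <- lines[i + 1L]
    qual <- lines[i + 3L]
  } else {
    qual <- as.character(Biostrings::quality(Biostrings::quality(fq)))
    ids <- sub("\\s.*$", "", as.character(ShortRead::id(fq)))
    seqs <- as.character(ShortRead::sread(fq))
  }
  if (length(ids) && offset != 33L) {
    qual <- phred_encode(phred_decode(qual, offset = offset))
  }
  srna_reads(id = ids, seq = seqs, qual = qual)
}

# Scan the raw lines of a FASTQ file and raise an error naming the first
# malformed record, so parse failures are actionable.
diagnose_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  nrec <- ceiling(n / 4)
  for (k in seq_len(nrec)) {
    i <- (k - 1L) * 4L
    if (i + 4L > n) stop("malformed FASTQ record ", k, ": truncated record")
    if (!startsWith(lines[i + 1L], "@"))
      stop("malformed FASTQ record ", k, ": header does not start with '@'")
    if (!startsWith(lines[i + 3L], "+"))
      stop("malformed FASTQ record ", k, ": separator line missing '+'")
    if (nchar(lines[i + 2L]) != nchar(lines[i + 4L]))
      stop("malformed FASTQ record ", k, ": sequence/quality length mismatch")
  }
  invisible(TRUE)
}

#' Write an `srna_reads` object to a FASTQ file
#'
#' @param reads an `srna_reads` object.
#' @param path output path (written uncompressed).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(reads$seq),
    quality = Biostrings::BStringSet(reads$qual),
    id = Biostrings::BStringSet(reads$id)
  )
  if (file.exists(path)) unlink(path)
  ShortRead::writeFastq(fq, path, compress = FALSE)
  invisible(path)
}

#' Write reads to a FASTA file
#'
#' Used for handing genome-unmapped reads to the microbe module; one record
#' per read, identifiers preserved, input order kept.
#'
#' @param reads an `srna_reads` object (qualities ignored).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unmapped_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as an `srna_reads` object (qualities absent)
#'
#' @param path path to a FASTA file.
#' @return an `srna_reads` object with maximal (40) placeholder qualities.
#' @export
read_fasta_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  srna_reads(
    id = sub("\\s.*$", "", names(x)),
    seq = seqs,
    qual = phred_encode(lapply(nchar(seqs), function(n) rep(40L, n)))
  )
}
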