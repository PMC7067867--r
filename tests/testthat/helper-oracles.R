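# Independent brute-force oracles used to check the package's fast paths.
# These deliberately avoid the package internals (and Biostrings) so each
# comparison is a genuine dual-route check.

# reverse complement via plain string ops
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# every end-to-end placement of `seq` in a named character genome with at
# most max_mm substitutions, scanning every offset on both strands
oracle_align_scan <- function(seq, genome_chars, max_mm) {
  out <- list()
  L <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  rv <- strsplit(oracle_revcomp(seq), "")[[1]]
  for (chrom in names(genome_chars)) {
    gc <- genome_chars[[chrom]]
    n <- length(gc)
    if (L > n) next
    for (off in 0:(n - L)) {
      win <- gc[(off + 1):(off + L)]
      mm_f <- sum(win != sv)
      if (mm_f <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = off, end = off + L, strand = "+",
          n_mismatch = mm_f, stringsAsFactors = FALSE)
      }
      mm_r <- sum(win != rv)
      if (mm_r <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = off, end = off + L, strand = "-",
          n_mismatch = mm_r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

genome_as_chars <- function(genome) {
  genome <- srnakit::load_genome(genome)
  out <- lapply(seq_along(genome), function(i)
    strsplit(as.character(genome[[i]]), "")[[1]])
  names(out) <- names(genome)
  out
}

# leftmost adapter-prefix trim position by naive exhaustive scan
oracle_adapter_pos <- function(seq, adapter, min_overlap, rate) {
  L <- nchar(seq); alen <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  for (i in 1:(L - min_overlap + 1)) {
    ov <- min(alen, L - i + 1)
    mm <- oracle_hamming(substr(seq, i, i + ov - 1), substr(adapter, 1, ov))
    if (mm <= floor(ov * rate)) return(i)
  }
  NA_integer_
}

# features overlapping a query interval by linear scan
oracle_feature_scan <- function(features, chrom, start, end, strand = NULL) {
  hit <- features$chrom == chrom & features$start < end & features$end > start
  if (!is.null(strand)) hit <- hit & features$strand == strand
  sort(which(hit))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xs, ys) {
    sum(vapply(xs, function(a) sum(a > ys) + 0.5 * sum(a == ys), numeric(1)))
  }
  u0 <- u_of(x, y)
  idx <- utils::combn(length(pooled), n)
  us <- apply(idx, 2, function(ci) u_of(pooled[ci], pooled[-ci]))
  p <- 2 * min(mean(us <= u0 + 1e-9), mean(us >= u0 - 1e-9))
  min(1, p)
}

# per-taxon rollup counts by per-read ancestor-union tally with an
# independent parent walk
oracle_taxa_rollup <- function(read_taxa, tree) {
  anc <- function(t) {
    out <- integer(0)
    while (TRUE) {
      out <- c(out, t)
      p <- tree$parent[match(t, tree$taxid)]
      if (p == t) break
      t <- p
    }
    out
  }
  counts <- setNames(integer(nrow(tree)), tree$taxid)
  for (taxa in read_taxa) {
    if (length(taxa) == 0) next
    a <- unique(unlist(lapply(taxa, anc)))
    counts[as.character(a)] <- counts[as.character(a)] + 1L
  }
  counts
}

# random reads helper: n reads of given length with constant quality
rand_reads <- function(n, len = 22, q = 35, prefix = "r") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  srnakit::srna_reads(paste0(prefix, seq_len(n)), seqs,
                      srnakit::phred_encode(lapply(seq_len(n),
                                                   function(i) rep(q, len))))
}

one_read <- function(seq, qual_scores, id = "r1") {
  srnakit::srna_reads(id, seq, srnakit::phred_encode(list(qual_scores)))
}
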