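#' Merge per-sample count files into a molecule-by-sample matrix
#'
#' Takes any number of four-column (`DB`, `Name`, `ID`, `Count`) per-sample
#' count tables — file paths or data frames — and aggregates them into a
#' data matrix with RNA molecules as rows and samples as columns. The row
#' set is the union of molecules across samples; a molecule absent from a
#' sample gets count 0 there. Sample (column) order follows input order.
#'
#' @param samples a named list of data frames, or a named character vector
#'   of file paths; names are the sample names.
#' @return a data frame with columns `DB`, `Name`, `ID` followed by one
#'   numeric column per sample.
#' @export
merge_samples <- function(samples) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be named")
  }
  if (anyDuplicated(names(samples))) {
    stop("duplicate sample name: ",
         names(samples)[duplicated(names(samples))][1])
  }
  tabs <- lapply(seq_along(samples), function(i) {
    x <- samples[[i]]
    if (is.character(x)) {
      x <- utils::read.table(x, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    }
    if (!all(c("DB", "Name", "ID", "Count") %in% names(x))) {
      stop("sample '", names(samples)[i],
           "': expected columns DB, Name, ID, Count")
    }
    if (any(x$Count < 0)) stop("negative count in sample '", names(samples)[i], "'")
    x
  })
  keys <- unique(do.call(rbind, lapply(tabs, function(x)
    x[, c("Name", "ID"), drop = FALSE])))
  rownames(keys) <- NULL
  key_str <- paste(keys$Name, keys$ID, sep = "\r")
  db <- character(nrow(keys))
  mat <- matrix(0, nrow = nrow(keys), ncol = length(samples),
                dimnames = list(NULL, names(samples)))
  for (i in seq_along(tabs)) {
    x <- tabs[[i]]
    j <- match(paste(x$Name, x$ID, sep = "\r"), key_str)
    mat[j, i] <- x$Count
    db[j] <- ifelse(nzchar(db[j]),
                    mapply(function(a, b) paste(
                      sort(unique(c(strsplit(a, ",")[[1]],
                                    strsplit(b, ",")[[1]]))), collapse = ","),
                      db[j], x$DB),
                    x$DB)
  }
  cbind(data.frame(DB = db, Name = keys$Name, ID = keys$ID,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

# Numeric sample columns of a merged table.
sample_columns <- function(table) {
  setdiff(names(table), c("DB", "Name", "ID"))
}

#' Counts-per-million normalization
#'
#' Rescales each sample column so its library sums to one million reads:
#' `value' = value / column_sum * 1e6`. Library size defaults to the column
#' sum of the matrix being normalized; pass `lib_sizes` to normalize
#' against externally determined library sizes (e.g. total qualified
#' reads).
#'
#' @param table a merged count table from [merge_samples()] (or any data
#'   frame whose non-`DB`/`Name`/`ID` columns are numeric).
#' @param lib_sizes optional named numeric vector of library sizes.
#' @return the table with sample columns CpM-normalized.
#' @export
cpm_normalize <- function(table, lib_sizes = NULL) {
  sc <- sample_columns(table)
  for (s in sc) {
    total <- if (is.null(lib_sizes)) sum(table[[s]]) else lib_sizes[[s]]
    if (is.null(total) || is.na(total) || total <= 0) {
      stop("sample '", s, "' has zero (or missing) library size")
    }
    table[[s]] <- table[[s]] / total * 1e6
  }
  table
}

#' Detection calls at a read-count threshold
#'
#' A molecule is called detected in a sample when its raw read count is at
#' or above the threshold (default 5: detected means count >= 5).
#'
#' @param table a merged raw count table.
#' @param threshold integer detection cutoff.
#' @return a logical matrix (molecules x samples); row names are
#'   `Name|ID` keys.
#' @export
detection_filter <- function(table, threshold = 5L) {
  sc <- sample_columns(table)
  m <- as.matrix(table[, sc, drop = FALSE]) >= threshold
  rownames(m) <- paste(table$Name, table$ID, sep = "|")
  m
}

#' Mann-Whitney case/control differential expression
#'
#' For each molecule row, compares case against control samples with the
#' two-sided Mann-Whitney U test (Wilcoxon rank-sum). The exact null
#' distribution is used when the smaller group has at most 8 samples and
#' the row has no ties; otherwise the normal approximation with tie and
#' continuity corrections. By default the matrix is CpM-normalized before
#' testing (the pipeline default); set `normalize = "none"` to test raw
#' counts. Rows that are constant across all samples carry no rank
#' information: they get `p_value = 1` and are flagged.
#'
#' @param table a merged count table.
#' @param case,control character vectors of sample (column) names.
#' @param normalize `"cpm"` (default) or `"none"`.
#' @return a data frame per molecule: `DB`, `Name`, `ID`, `u` (U statistic
#'   of the case group), `p_value`, `median_case`, `median_control`,
#'   `direction` (sign of `median_case - median_control`), `constant`.
#' @export
mann_whitney_de <- function(table, case, control,
                            normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  sc <- sample_columns(table)
  if (length(case) < 1 || length(control) < 1) {
    stop("need at least one case and one control sample")
  }
  missing <- setdiff(c(case, control), sc)
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  if (length(intersect(case, control))) {
    stop("samples cannot be both case and control")
  }
  if (normalize == "cpm") table <- cpm_normalize(table)
  exact <- min(length(case), length(control)) <= 8
  res <- lapply(seq_len(nrow(table)), function(i) {
    x <- as.numeric(table[i, case])
    y <- as.numeric(table[i, control])
    const <- length(unique(c(x, y))) == 1
    if (const) {
      u <- length(x) * length(y) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE))
      u <- unname(wt$statistic)
      p <- min(1, wt$p.value)
      if (is.na(p)) p <- 1
    }
    data.frame(DB = table$DB[i], Name = table$Name[i], ID = table$ID[i],
               u = u, p_value = p,
               median_case = stats::median(x), median_control = stats::median(y),
               direction = sign(stats::median(x) - stats::median(y)),
               constant = const, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment of DE p-values
#'
#' Optional multiple-testing correction (off by default in the pipeline,
#' which reports raw Mann-Whitney p-values).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method passed to [stats::p.adjust()].
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = method)
}

#' Write a merged matrix or DE table as tab-delimited text
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
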