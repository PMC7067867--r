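#' Pipeline configuration
#'
#' Collects every stage toggle, parameter and input path for
#' [run_pipeline()]. Stages run in the fixed order
#' qc -> align -> annotate -> microbe -> stats; any subset may be
#' requested, provided the inputs each requested stage needs are available
#' (either produced by an earlier requested stage or supplied directly,
#' e.g. pre-aligned SAM files for an annotate-only run).
#'
#' @param fastq named vector of FASTQ paths (or named list of `srna_reads`),
#'   one element per sample.
#' @param sam named vector of SAM/BAM paths per sample, bypassing qc/align.
#' @param genome genome accepted by [load_genome()] (required for align and
#'   for SAM export).
#' @param feature_dbs either a feature data frame, or a data frame with
#'   columns `path`, `db`, `rna_type` naming BED-like database files.
#' @param stages subset of `c("qc","align","annotate","microbe","stats")`.
#' @param out_dir output directory.
#' @param qc a [qc_config()].
#' @param max_mismatch micro-aligner mismatch allowance.
#' @param min_ratio,strand_mode,use_full_read_length annotation parameters
#'   (see [annotate_read()]).
#' @param abam_types RNA types whose annotated reads are exported as SAM.
#' @param microbe_refs,taxonomy,acc2taxid microbe-stage inputs: reference
#'   sequences for [micro_match()] (or a precomputed hit file via
#'   `blast_hits`), a taxonomy, and an accession-to-taxid map.
#' @param blast_hits optional path to a precomputed 12-column hit file.
#' @param unmapped_fasta optional named vector of FASTA paths of unmapped
#'   reads per sample (when align is not run).
#' @param max_evalue,min_identity microbe screening filters.
#' @param count_files optional named vector of per-sample four-column count
#'   files (when annotate is not run).
#' @param case,control sample names for differential expression.
#' @param de_normalize `"cpm"` or `"none"`.
#' @param detection_threshold read-count threshold for detection calls.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq = NULL, sam = NULL, genome = NULL,
                            feature_dbs = NULL,
                            stages = c("qc", "align", "annotate"),
                            out_dir = tempfile("srnakit_run_"),
                            qc = qc_config(), max_mismatch = 1L,
                            min_ratio = 1, strand_mode = "same",
                            use_full_read_length = FALSE,
                            abam_types = character(0),
                            microbe_refs = NULL, taxonomy = NULL,
                            acc2taxid = NULL, blast_hits = NULL,
                            unmapped_fasta = NULL,
                            max_evalue = 1e-3, min_identity = 90,
                            count_files = NULL,
                            case = NULL, control = NULL,
                            de_normalize = "cpm",
                            detection_threshold = 5L) {
  stages <- match.arg(stages, c("qc", "align", "annotate", "microbe",
                                "stats"), several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

load_features_config <- function(feature_dbs) {
  if (all(c("db", "rna_type", "chrom", "start", "end", "name", "id",
            "strand") %in% names(feature_dbs))) {
    return(feature_dbs)
  }
  if (all(c("path", "db", "rna_type") %in% names(feature_dbs))) {
    return(do.call(rbind, lapply(seq_len(nrow(feature_dbs)), function(i) {
      load_feature_db(feature_dbs$path[i], feature_dbs$db[i],
                      feature_dbs$rna_type[i])
    })))
  }
  stop("feature_dbs must be a feature table or a path/db/rna_type manifest")
}

#' Run the small-RNA quantification pipeline
#'
#' Executes the requested stages in order for every sample, writes all
#' stage outputs under `config$out_dir`, and records a machine-readable
#' run manifest (parameters, input checksums, per-stage read counts and
#' output files). The manifest carries no timestamps, so re-running an
#' identical configuration on identical inputs reproduces every output
#' file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with per-sample results (`qc_report`,
#'   `alignments`, `counts`), merged matrices and DE results when
#'   computed, taxon counts when computed, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- input availability checks up front
  if ("qc" %in% st && is.null(config$fastq)) {
    stop("stage 'qc' requested but no FASTQ inputs provided")
  }
  if ("align" %in% st) {
    if (!"qc" %in% st && is.null(config$fastq)) {
      stop("stage 'align' requested but no reads available (run qc or provide fastq)")
    }
    if (is.null(config$genome)) stop("stage 'align' requested but no genome provided")
  }
  if ("annotate" %in% st) {
    if (!"align" %in% st && is.null(config$sam)) {
      stop("stage 'annotate' requested but no alignments available ",
           "(run align or provide sam)")
    }
    if (is.null(config$feature_dbs)) {
      stop("stage 'annotate' requested but no feature databases provided")
    }
  }
  if ("microbe" %in% st) {
    if (!"align" %in% st && is.null(config$unmapped_fasta) &&
        is.null(config$blast_hits)) {
      stop("stage 'microbe' requested but no unmapped reads available ",
           "(run align or provide unmapped_fasta/blast_hits)")
    }
    if (is.null(config$taxonomy) || is.null(config$acc2taxid)) {
      stop("stage 'microbe' requested but taxonomy/acc2taxid missing")
    }
    if (is.null(config$blast_hits) && is.null(config$microbe_refs)) {
      stop("stage 'microbe' requested but no reference sequences or hit file")
    }
  }
  if ("stats" %in% st && !"annotate" %in% st && is.null(config$count_files)) {
    stop("stage 'stats' requested but no count tables available ",
         "(run annotate or provide count_files)")
  }

  samples <- names(config$fastq)
  if (is.null(samples)) samples <- names(config$sam)
  if (is.null(samples) && !is.null(config$count_files)) {
    samples <- names(config$count_files)
  }

  genome <- if (!is.null(config$genome)) load_genome(config$genome)
  index <- if (!is.null(config$feature_dbs)) {
    feature_index(load_features_config(config$feature_dbs))
  }

  per_sample <- list()
  stage_counts <- list()
  unmapped_by_sample <- list()

  for (s in samples) {
    sdir <- file.path(config$out_dir, s)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    res <- list()
    reads <- NULL
    if (!is.null(config$fastq)) {
      x <- config$fastq[[s]]
      reads <- if (is.character(x)) read_fastq(x) else x
    }

    if ("qc" %in% st) {
      qc <- run_qc(reads, config$qc,
                   out_fastq = file.path(sdir, "qualified.fastq"))
      write_qc_report(qc$report, file.path(sdir, "qc_report.txt"))
      reads <- qc$reads
      res$qc_report <- qc$report
      stage_counts[[s]]$qc_in <- qc$report$n_input
      stage_counts[[s]]$qc_qualified <- qc$report$n_qualified
    }

    alignments <- NULL
    if ("align" %in% st) {
      al <- micro_align(reads, genome, max_mismatch = config$max_mismatch)
      alignments <- al$alignments
      write_sam(alignments, genome, file.path(sdir, "aligned.sam"),
                unmapped = al$unmapped)
      write_unmapped_fasta(al$unmapped, file.path(sdir, "unmapped.fasta"))
      unmapped_by_sample[[s]] <- al$unmapped
      res$alignments <- alignments
      stage_counts[[s]]$aligned_reads <- length(unique(alignments$read_id))
      stage_counts[[s]]$unmapped_reads <- nrow(al$unmapped)
    } else if (!is.null(config$sam)) {
      al <- ingest_sam(config$sam[[s]])
      alignments <- al$alignments
      unmapped_by_sample[[s]] <- al$unmapped
      res$alignments <- alignments
      stage_counts[[s]]$aligned_reads <- length(unique(alignments$read_id))
      stage_counts[[s]]$unmapped_reads <- nrow(al$unmapped)
    }

    if ("annotate" %in% st) {
      q <- quantify(alignments, index, min_ratio = config$min_ratio,
                    strand_mode = config$strand_mode,
                    use_full_read_length = config$use_full_read_length)
      write_count_files(q$counts, sdir, prefix = s)
      res$counts <- q$counts
      res$read_annotations <- q$read_annotations
      stage_counts[[s]]$annotated_reads <-
        length(unique(q$read_annotations$read_id))
      for (tp in config$abam_types) {
        export_reads_by_type(alignments, q$read_annotations, tp, genome,
                             file.path(sdir, paste0(s, "_", tp, ".sam")))
      }
    }
    per_sample[[s]] <- res
  }

  out <- list(per_sample = per_sample)

  if ("microbe" %in% st) {
    tree <- if (is.character(config$taxonomy)) load_taxonomy(config$taxonomy)
            else config$taxonomy
    hits <- if (!is.null(config$blast_hits)) {
      parse_blast_tabular(config$blast_hits, config$acc2taxid)
    } else {
      ur <- if (length(unmapped_by_sample)) {
        do.call(rbind, unname(unmapped_by_sample))
      } else {
        do.call(rbind, lapply(config$unmapped_fasta, read_fasta_reads))
      }
      h <- micro_match(ur, config$microbe_refs,
                       max_mismatch = config$max_mismatch)
      a2t <- config$acc2taxid
      if (is.character(a2t)) {
        a2t <- utils::read.table(a2t, sep = "\t", header = FALSE,
                                 col.names = c("accession", "taxid"),
                                 stringsAsFactors = FALSE)
      }
      h$taxid <- a2t$taxid[match(h$subject_id, a2t$accession)]
      h <- h[!is.na(h$taxid), , drop = FALSE]
      h
    }
    read_taxa <- assign_all_read_taxa(hits, max_evalue = config$max_evalue,
                                      min_identity = config$min_identity)
    taxa <- count_taxa(read_taxa, tree)
    write_taxa_counts(taxa, file.path(config$out_dir, "microbe_counts.txt"))
    out$taxa <- taxa
  }

  if ("stats" %in% st) {
    merged <- list()
    if ("annotate" %in% st) {
      types <- names(per_sample[[samples[1]]]$counts)
      for (tp in types) {
        tabs <- lapply(samples, function(s) per_sample[[s]]$counts[[tp]])
        names(tabs) <- samples
        nonempty <- vapply(tabs, nrow, integer(1)) > 0
        if (!any(nonempty)) next
        m <- merge_samples(tabs)
        write_table_tsv(m, file.path(config$out_dir,
                                     paste0("merged_", tp, ".txt")))
        merged[[tp]] <- m
      }
    } else {
      merged$all <- merge_samples(as.list(config$count_files))
      write_table_tsv(merged$all, file.path(config$out_dir, "merged_all.txt"))
    }
    out$merged <- merged
    out$detected <- lapply(merged, detection_filter,
                           threshold = config$detection_threshold)
    if (!is.null(config$case) && !is.null(config$control)) {
      out$de <- lapply(names(merged), function(tp) {
        de <- mann_whitney_de(merged[[tp]], config$case, config$control,
                              normalize = config$de_normalize)
        write_table_tsv(de, file.path(config$out_dir, paste0("de_", tp, ".txt")))
        de
      })
      names(out$de) <- names(merged)
    }
  }

  manifest <- list(
    tool = "srnakit",
    version = as.character(utils::packageVersion("srnakit")),
    stages = st,
    samples = samples,
    parameters = list(
      max_mismatch = config$max_mismatch, min_ratio = config$min_ratio,
      strand_mode = config$strand_mode,
      use_full_read_length = config$use_full_read_length,
      qc = unclass(config$qc), max_evalue = config$max_evalue,
      min_identity = config$min_identity,
      detection_threshold = config$detection_threshold,
      de_normalize = config$de_normalize),
    input_hashes = manifest_hashes(config),
    stage_read_counts = stage_counts,
    outputs = sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                           "manifest.json")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

manifest_hashes <- function(config) {
  paths <- character(0)
  for (field in c("fastq", "sam", "unmapped_fasta", "count_files",
                  "blast_hits")) {
    x <- config[[field]]
    if (is.character(x)) paths <- c(paths, x)
  }
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}
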