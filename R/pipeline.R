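#' Pipeline run configuration
#'
#' @param input Input reads: a character vector of FASTA/FASTQ paths (sample
#'   id = file basename), a data frame with columns `sample_id` and `path`,
#'   or the path of a two-column TSV manifest with those columns.
#' @param trim_length Constant read length to trim to (nt).
#' @param format `"fasta"` or `"fastq"`.
#' @param primer Optional 5' IUPAC primer to strip (reads without it are
#'   discarded).
#' @param min_parent_abundance Cluster parent-depth filter; default 1,000
#'   reads (consider 10,000 for very deeply sequenced data sets).
#' @param fdr FDR threshold for calling children; default 0.05.
#' @param loess_span Span of the background LOESS fits; default 0.75.
#' @param sd_floor Floor for background SD on the log10 scale.
#' @param error_handling `"collapse"` (error-child counts folded into their
#'   parent) or `"drop"`.
#' @param output_dir Optional directory for written outputs; `NULL` skips
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(input, trim_length, format = c("fasta", "fastq"),
                       primer = NULL, min_parent_abundance = 1000,
                       fdr = 0.05, loess_span = 0.75, sd_floor = 1e-3,
                       error_handling = c("collapse", "drop"),
                       output_dir = NULL) {
  format <- match.arg(format)
  error_handling <- match.arg(error_handling)
  stopifnot(trim_length >= 1, min_parent_abundance >= 0,
            fdr >= 0, fdr < 1, loess_span > 0, loess_span <= 1)
  structure(list(input = input, trim_length = as.integer(trim_length),
                 format = format, primer = primer,
                 min_parent_abundance = min_parent_abundance, fdr = fdr,
                 loess_span = loess_span, sd_floor = sd_floor,
                 error_handling = error_handling, output_dir = output_dir),
            class = "run_config")
}

# resolve the input argument into a list of sample_reads
load_samples <- function(input, format) {
  if (is.data.frame(input)) {
    stopifnot(all(c("sample_id", "path") %in% names(input)))
    return(lapply(seq_len(nrow(input)), function(i) {
      read_sample(input$path[i], format, input$sample_id[i])
    }))
  }
  stopifnot(is.character(input), length(input) >= 1L)
  if (length(input) == 1L && grepl("\\.tsv$", input, ignore.case = TRUE)) {
    manifest <- read.delim(input, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "path") %in% names(manifest))) {
      stop("manifest must have columns 'sample_id' and 'path': ", input)
    }
    return(load_samples(manifest, format))
  }
  lapply(input, read_sample, format = format)
}

#' Run the full variant-calling pipeline
#'
#' Chains all stages: read and trim each sample, dereplicate with
#' per-sample singleton removal, cluster parents with their one-mismatch
#' children, fit the Poisson per-base error rate (diagnostic only),
#' calibrate the normal error background by LOESS (falling back to a pooled
#' constant background, with a warning, when fewer than 10 clusters have
#' defined statistics), test and call variants, and assemble the final
#' count table. Identical inputs and configuration give byte-identical
#' outputs.
#'
#' If `output_dir` is set, writes: `variants.fasta` (called true variants),
#' `counts.tsv` (final per-sample counts), `stats.tsv` (per-sequence call
#' details), `clusters.tsv`, `poisson_diagnostics.tsv` (observed vs expected
#' child fractions under the fitted rate) and `run_log.txt` (per-stage
#' counts).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `table` (dereplicated
#'   `variant_table`), `clusters`, `poisson_fit` (or `NULL` if the fit
#'   failed), `stats`, `curves`, `calls` (`variant_calls`) and `counts`
#'   (final `variant_table`); `NULL` if no variants survive preprocessing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  samples <- load_samples(config$input, config$format)
  note("loaded %d sample(s), %d reads total", length(samples),
       sum(vapply(samples, function(s) length(s$reads), integer(1))))
  samples <- lapply(samples, trim_and_filter,
                    trim_length = config$trim_length, primer = config$primer)
  n_trimmed <- sum(vapply(samples, function(s) length(s$reads), integer(1)))
  note("%d reads after trimming/filtering", n_trimmed)

  table <- dereplicate(samples, config$trim_length)
  note("%d variants after dereplication and singleton removal (%d reads)",
       nrow(table$counts), sum(table$counts))
  if (nrow(table$counts) == 0L) {
    message("no variants survive preprocessing; nothing to call")
    return(invisible(NULL))
  }

  clusters <- build_clusters(table)
  note("%d clusters", length(clusters))

  pois <- tryCatch(
    suppressWarnings(fit_error_rate(clusters, config$trim_length)),
    error = function(e) {
      note("Poisson error-rate fit unavailable: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(pois)) {
    note("fitted per-base error rate %.4g", pois$error_rate)
  }

  stats <- compute_cluster_stats(clusters)
  curves <- tryCatch(
    fit_loess(stats, span = config$loess_span, sd_floor = config$sd_floor),
    error = function(e) {
      warning("falling back to pooled constant background: ",
              conditionMessage(e), call. = FALSE)
      note("background: pooled constant (too few clusters for LOESS)")
      pooled_background(clusters, sd_floor = config$sd_floor)
    })

  calls <- call_variants(clusters, stats, curves,
                         min_parent_abundance = config$min_parent_abundance,
                         fdr = config$fdr)
  note("%d true variants, %d error children, %d filtered sequences",
       sum(calls$call == "true_variant"), sum(calls$call == "error"),
       sum(calls$call == "filtered"))
  counts <- collapse_counts(table, calls, config$error_handling)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_variant_fasta(counts, out("variants.fasta"))
    write_variant_table(counts, out("counts.tsv"))
    write.table(as.data.frame(calls), out("stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_clusters(clusters, out("clusters.tsv"))
    if (!is.null(pois)) {
      diag <- data.frame(
        cluster_index = vapply(clusters, `[[`, integer(1), "index"),
        parent_abundance = vapply(clusters, `[[`, integer(1), "parent_abundance"),
        observed_fraction = vapply(clusters, children_fraction, numeric(1),
                                   L = config$trim_length),
        expected_fraction = expected_children_fraction(
          vapply(clusters, `[[`, integer(1), "parent_abundance"),
          pois$error_rate))
      write.table(diag, out("poisson_diagnostics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    writeLines(log_lines, out("run_log.txt"))
  }

  invisible(list(table = table, clusters = clusters, poisson_fit = pois,
                 stats = stats, curves = curves, calls = calls,
                 counts = counts))
}

#' Percent identity from tabular alignment statistics
#'
#' Alignment similarity that penalizes mismatches, gaps and unaligned query
#' sequence:
#' `100 * (alignment_length - (mismatches + gaps)) /
#'   max(alignment_length, sequence_length)`.
#' The inputs are the standard fields of tabular alignment output (e.g.
#' BLAST outfmt 6) plus the known query length, so database hits can be
#' post-processed without re-running the alignment.
#'
#' @param alignment_length Length of the reported alignment.
#' @param mismatches Number of mismatched positions in the alignment.
#' @param gaps Number of gap positions in the alignment.
#' @param sequence_length Full length of the query sequence.
#' @return Percentage(s) in `[0, 100]`; vectorized.
#' @export
percent_identity <- function(alignment_length, mismatches, gaps,
                             sequence_length) {
  if (any(alignment_length < 0) || any(mismatches < 0) || any(gaps < 0) ||
      any(sequence_length < 0)) {
    stop("all inputs must be non-negative")
  }
  if (any(alignment_length < mismatches + gaps)) {
    stop("alignment_length must be at least mismatches + gaps")
  }
  100 * (alignment_length - (mismatches + gaps)) /
    pmax(alignment_length, sequence_length)
}
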