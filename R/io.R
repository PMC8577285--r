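#' Reads belonging to one sample
#'
#' A light container pairing a sample identifier with its nucleotide reads.
#' Reads are plain uppercase character strings over `{A,C,G,T,N}`; quality
#' information is never stored because the caller does not use it.
#'
#' @param sample_id Single string, unique within a run.
#' @param reads Character vector of reads (possibly heterogeneous lengths
#'   before trimming).
#' @return An object of class `sample_reads`.
#' @export
sample_reads <- function(sample_id, reads = character()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  structure(list(sample_id = sample_id, reads = as.character(reads)),
            class = "sample_reads")
}

#' @export
print.sample_reads <- function(x, ...) {
  cat("<sample_reads> ", x$sample_id, ": ", length(x$reads), " reads\n", sep = "")
  invisible(x)
}

#' Read one sample's FASTA or FASTQ file
#'
#' Parses all records of a (optionally gzipped) FASTA or FASTQ file into a
#' [sample_reads] object. Sequences are uppercased; FASTQ quality strings are
#' discarded. Reads containing characters outside `{A,C,G,T,N}` are dropped
#' with a warning.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param sample_id Sample identifier; defaults to the file basename with the
#'   extension stripped.
#' @return A [sample_reads] object.
#' @export
read_sample <- function(path, format = c("fasta", "fastq"), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  reads <- toupper(as.character(set))
  names(reads) <- NULL
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning("discarded ", sum(bad), " read(s) with characters outside ",
            "{A,C,G,T,N} in ", basename(path))
    reads <- reads[!bad]
  }
  if (length(reads) == 0L) {
    warning("no usable reads in ", basename(path))
  }
  sample_reads(sample_id, reads)
}

# anchored regular expression matching an IUPAC primer at the 5' end
iupac_prefix_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1L]]
  map <- Biostrings::IUPAC_CODE_MAP
  if (!all(chars %in% names(map))) {
    stop("primer contains non-IUPAC characters: ",
         paste(unique(chars[!chars %in% names(map)]), collapse = ", "))
  }
  paste0("^", paste0("[", map[chars], "]", collapse = ""))
}

#' Trim reads to a constant length and apply read-level filters
#'
#' Applies, in order: optional primer stripping (IUPAC-aware exact anchored
#' prefix match; reads without the primer are discarded), removal of reads
#' shorter than `trim_length`, 3'-end truncation to exactly `trim_length`,
#' and removal of reads still containing `N`. Counts removed at each step are
#' reported via [message()].
#'
#' @param reads A [sample_reads] object.
#' @param trim_length Positive integer; the constant read length kept.
#' @param primer Optional IUPAC nucleotide string expected at the 5' end.
#' @return A [sample_reads] object whose reads all have length `trim_length`
#'   and contain no `N`.
#' @export
trim_and_filter <- function(reads, trim_length, primer = NULL) {
  stopifnot(inherits(reads, "sample_reads"))
  trim_length <- as.integer(trim_length)
  stopifnot(length(trim_length) == 1L, !is.na(trim_length), trim_length >= 1L)
  x <- reads$reads
  n_in <- length(x)
  n_primer <- 0L
  if (!is.null(primer)) {
    hit <- grepl(iupac_prefix_regex(primer), x)
    n_primer <- sum(!hit)
    x <- substring(x[hit], nchar(primer) + 1L)
  }
  short <- nchar(x) < trim_length
  n_short <- sum(short)
  x <- substr(x[!short], 1L, trim_length)
  has_n <- grepl("N", x, fixed = TRUE)
  n_n <- sum(has_n)
  x <- x[!has_n]
  message(sprintf(
    "%s: %d reads in; removed %d without primer, %d short, %d with N; %d kept",
    reads$sample_id, n_in, n_primer, n_short, n_n, length(x)))
  sample_reads(reads$sample_id, x)
}

#' Dereplicate reads into a variant count table
#'
#' Counts every unique sequence per sample by hash lookup (linear in the
#' total number of reads), then removes per-sample singletons: within each
#' sample, a sequence observed exactly once has that sample's count set to
#' zero. Variants whose total across samples is then zero are dropped, so
#' every retained variant has total count >= 2.
#'
#' @param samples A list of [sample_reads], all trimmed to `trim_length`.
#' @param trim_length The common read length; reads of any other length are
#'   an error.
#' @return A `variant_table`: list with `counts` (integer matrix, rows =
#'   variant sequences, columns = samples), `length` (read length) and
#'   `sample_ids`.
#' @export
dereplicate <- function(samples, trim_length) {
  if (inherits(samples, "sample_reads")) samples <- list(samples)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "sample_reads")))
  trim_length <- as.integer(trim_length)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicated sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  per <- lapply(samples, function(s) {
    if (length(s$reads) && any(nchar(s$reads) != trim_length)) {
      stop("sample '", s$sample_id, "' has reads not of length ", trim_length)
    }
    tab <- table(s$reads)
    tab[tab >= 2L]                       # per-sample singleton removal
  })
  seqs <- sort(unique(unlist(lapply(per, names), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(ids),
                   dimnames = list(seqs, ids))
  for (j in seq_along(per)) {
    if (length(per[[j]])) counts[names(per[[j]]), j] <- as.integer(per[[j]])
  }
  structure(list(counts = counts, length = trim_length, sample_ids = ids),
            class = "variant_table")
}

#' Total abundance of each variant across samples
#'
#' @param table A `variant_table`.
#' @return Named integer vector of row sums (names are variant sequences).
#' @export
variant_totals <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  rowSums(table$counts)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$counts), " variants x ", ncol(x$counts),
      " samples (read length ", x$length, ")\n", sep = "")
  invisible(x)
}

#' Write a variant count table as TSV
#'
#' Rows are variant sequences, columns the per-sample counts plus a `total`
#' column.
#'
#' @param table A `variant_table`.
#' @param path Output file path.
#' @export
write_variant_table <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  tot <- variant_totals(table)
  ord <- order(-tot, names(tot))
  df <- data.frame(sequence = rownames(table$counts)[ord],
                   table$counts[ord, , drop = FALSE],
                   total = as.integer(tot[ord]),
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant sequences as FASTA
#'
#' Variants are ordered by decreasing total abundance (ties broken by
#' sequence) and named `SV<index>;size=<total>`, the usual dereplication
#' header convention.
#'
#' @param table A `variant_table`.
#' @param path Output FASTA path.
#' @export
write_variant_fasta <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  tot <- variant_totals(table)
  ord <- order(-tot, names(tot))
  seqs <- Biostrings::DNAStringSet(names(tot)[ord])
  names(seqs) <- sprintf("SV%d;size=%d", seq_along(ord), as.integer(tot[ord]))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
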