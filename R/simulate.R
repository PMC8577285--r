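#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Sequence length in nt.
#' @return Character vector of uniform-random sequences over `{A,C,G,T}`.
#' @export
random_sequences <- function(n, length) {
  stopifnot(n >= 1, length >= 1)
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
           collapse = "")
  }, character(1))
}

#' Simulate error-prone reads of one template
#'
#' Emulates a polymerase/sequencer that copies `sequence` `depth` times,
#' substituting each base independently with probability `error_rate` and
#' choosing uniformly among the three alternative bases. Internally the
#' number of substituted positions per read is drawn from
#' Binomial(L, error_rate) and positions are then sampled without
#' replacement — identical in distribution to per-base Bernoulli draws but
#' much faster at realistic (small) error rates.
#'
#' Uses the current RNG state; seed via [set.seed()] or use
#' [simulate_reads()] for a fully seeded run.
#'
#' @param sequence Template string over `{A,C,G,T}`.
#' @param depth Number of reads to emit.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @return Character vector of `depth` reads.
#' @export
mutate_reads <- function(sequence, depth, error_rate) {
  stopifnot(grepl("^[ACGT]+$", sequence), depth >= 1,
            error_rate >= 0, error_rate <= 1)
  L <- nchar(sequence)
  reads <- rep.int(sequence, depth)
  k <- rbinom(depth, L, error_rate)
  idx <- which(k > 0L)
  if (length(idx)) {
    template <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    for (i in idx) {
      pos <- sample.int(L, k[i])
      ch <- template
      for (p in pos) ch[p] <- alt[[ch[p]]][sample.int(3L, 1L)]
      reads[i] <- paste0(ch, collapse = "")
    }
  }
  reads
}

# Hamming distance of each read to a same-length reference
hamming_to_ref <- function(reads, ref) {
  d <- integer(length(reads))
  diff <- which(reads != ref)
  if (length(diff)) {
    ref_int <- utf8ToInt(ref)
    d[diff] <- vapply(diff, function(i) {
      sum(utf8ToInt(reads[i]) != ref_int)
    }, integer(1))
  }
  d
}

#' Configuration for a synthetic amplicon run
#'
#' @param parents Character vector of true template sequences, or `NULL` to
#'   draw `n_parents` random sequences of length `length` at simulation time.
#' @param n_parents,length Used only when `parents` is `NULL`.
#' @param parent_depths Integer vector of read depths, one per parent.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param planted_children Optional data frame of true biological variants
#'   one substitution away from a parent, with columns `parent_index`,
#'   `position`, `base`, `depth`. `base = NA` picks the cyclic successor
#'   (A->C->G->T->A) of the parent's base at `position`, convenient when the
#'   parents themselves are drawn at random.
#' @param n_samples Number of samples reads are distributed over
#'   (round-robin).
#' @param seed Integer RNG seed; the simulation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(parents = NULL, n_parents = NULL, length = 250L,
                       parent_depths, error_rate, planted_children = NULL,
                       n_samples = 1L, seed = 1L) {
  if (is.null(parents)) {
    stopifnot(!is.null(n_parents), n_parents >= 1)
  } else {
    stopifnot(all(grepl("^[ACGT]+$", parents)),
              length(unique(nchar(parents))) == 1L)
    n_parents <- base::length(parents)
    length <- nchar(parents[1L])
  }
  stopifnot(base::length(parent_depths) == n_parents, all(parent_depths >= 1),
            error_rate >= 0, error_rate < 1, n_samples >= 1)
  if (!is.null(planted_children)) {
    stopifnot(is.data.frame(planted_children),
              all(c("parent_index", "position", "base", "depth") %in%
                    names(planted_children)),
              all(planted_children$parent_index %in% seq_len(n_parents)),
              all(planted_children$position >= 1),
              all(planted_children$position <= length),
              all(is.na(planted_children$base) |
                    planted_children$base %in% c("A", "C", "G", "T")),
              all(planted_children$depth >= 1))
  }
  structure(list(parents = parents, n_parents = n_parents,
                 length = as.integer(length),
                 parent_depths = as.integer(parent_depths),
                 error_rate = error_rate,
                 planted_children = planted_children,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic amplicon data set with known truth
#'
#' Draws parent templates (if not given), derives any planted true child
#' sequences, emits each source's depth in reads through the polymerase
#' error process of [mutate_reads()], and deals the reads round-robin across
#' `n_samples` samples. The returned truth table records every biologically
#' true sequence, so downstream calls can be scored against ground truth.
#'
#' @param config A [sim_config()].
#' @return List with `samples` (list of [sample_reads], ids `S1..Sn`),
#'   `truth` (data frame: `sequence`, `origin` in parent/planted_child,
#'   `depth`) and `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  parents <- config$parents
  if (is.null(parents)) {
    parents <- random_sequences(config$n_parents, config$length)
  }
  sources <- parents
  depths <- config$parent_depths
  origin <- rep("parent", length(parents))
  pc <- config$planted_children
  if (!is.null(pc) && nrow(pc)) {
    planted <- vapply(seq_len(nrow(pc)), function(i) {
      s <- parents[pc$parent_index[i]]
      b <- pc$base[i]
      if (is.na(b)) {
        cyc <- c(A = "C", C = "G", G = "T", T = "A")
        b <- cyc[[substr(s, pc$position[i], pc$position[i])]]
      } else if (substr(s, pc$position[i], pc$position[i]) == b) {
        stop("planted child ", i, " is identical to its parent at position ",
             pc$position[i])
      }
      substr(s, pc$position[i], pc$position[i]) <- b
      s
    }, character(1))
    sources <- c(sources, planted)
    depths <- c(depths, as.integer(pc$depth))
    origin <- c(origin, rep("planted_child", length(planted)))
  }
  reads <- unlist(lapply(seq_along(sources), function(i) {
    mutate_reads(sources[i], depths[i], config$error_rate)
  }), use.names = FALSE)
  assign_to <- rep_len(seq_len(config$n_samples), length(reads))
  samples <- lapply(seq_len(config$n_samples), function(j) {
    sample_reads(paste0("S", j), reads[assign_to == j])
  })
  list(samples = samples,
       truth = data.frame(sequence = sources, origin = origin,
                          depth = depths, stringsAsFactors = FALSE),
       config = config)
}

#' Accumulation of unique one-mismatch children with sequencing depth
#'
#' For each depth, simulates that many reads of a single template at the
#' given error rate and reports the number of distinct single-substitution
#' variants observed among the reads, divided by the 3L possible ones. In
#' expectation this follows the zero-truncated Poisson curve of
#' [expected_children_fraction()]; pairing the two is the standard check
#' that the one-parameter error model matches an explicit polymerase
#' simulation.
#'
#' @param parent_depths Integer vector of depths to simulate.
#' @param L Read length (used to draw the template when `parent` is `NULL`).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param parent Optional explicit template sequence.
#' @return Data frame with columns `depth` and `observed_fraction`.
#' @export
children_accumulation <- function(parent_depths, L, error_rate, seed = 1L,
                                  parent = NULL) {
  stopifnot(all(parent_depths >= 1), L >= 1)
  set.seed(seed)
  if (is.null(parent)) parent <- random_sequences(1L, L)
  frac <- vapply(parent_depths, function(d) {
    reads <- mutate_reads(parent, d, error_rate)
    dist <- hamming_to_ref(reads, parent)
    length(unique(reads[dist == 1L])) / (3 * L)
  }, numeric(1))
  data.frame(depth = as.integer(parent_depths), observed_fraction = frac)
}

#' Substitution-count spectrum of simulated reads
#'
#' Simulates `depth` reads of a single template in chunks and tabulates how
#' many carry 0, 1, 2, ... substitutions. Used to quantify how rare
#' multi-mismatch reads are at realistic per-base error rates — the
#' justification for modeling only one-mismatch children.
#'
#' @param depth Total number of reads to simulate.
#' @param L Read length.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param chunk_size Reads simulated per chunk (memory control).
#' @return Named integer vector: counts of reads by substitution number
#'   (names "0", "1", ...).
#' @export
error_spectrum <- function(depth, L, error_rate, seed = 1L,
                           chunk_size = 100000L) {
  stopifnot(depth >= 1, L >= 1)
  set.seed(seed)
  parent <- random_sequences(1L, L)
  counts <- integer(0)
  remaining <- depth
  while (remaining > 0L) {
    n <- min(chunk_size, remaining)
    reads <- mutate_reads(parent, n, error_rate)
    d <- hamming_to_ref(reads, parent)
    tab <- table(d)
    for (nm in names(tab)) {
      counts[nm] <- (if (nm %in% names(counts)) counts[nm] else 0L) +
        as.integer(tab[nm])
    }
    remaining <- remaining - n
  }
  counts[order(as.integer(names(counts)))]
}

#' Write simulated samples as per-sample FASTA files
#'
#' @param sim Output of [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths; a `truth.tsv` with
#'   the true sequences is written alongside.
#' @export
write_simulated_fasta <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sim$samples, function(s) {
    p <- file.path(dir, paste0(s$sample_id, ".fasta"))
    seqs <- Biostrings::DNAStringSet(s$reads)
    names(seqs) <- sprintf("%s_read%d", s$sample_id, seq_along(s$reads))
    Biostrings::writeXStringSet(seqs, p)
    p
  }, character(1))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  names(paths) <- vapply(sim$samples, `[[`, character(1), "sample_id")
  paths
}
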