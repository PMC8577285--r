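#' All single-substitution neighbors of a sequence
#'
#' Enumerates every sequence at Hamming distance exactly 1 from `seq`:
#' 3L distinct neighbors for a sequence of length L (three alternative bases
#' at each position).
#'
#' @param seq A single string over `{A,C,G,T}`.
#' @return Character vector of length `3 * nchar(seq)`.
#' @export
one_mismatch_neighbors <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !grepl("^[ACGT]+$", seq)) {
    stop("'seq' must be a single non-empty string over {A,C,G,T}")
  }
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(3L * L)
  k <- 0L
  for (p in seq_len(L)) {
    for (b in bases[bases != chars[p]]) {
      s <- seq
      substr(s, p, p) <- b
      k <- k + 1L
      out[k] <- s
    }
  }
  out
}

new_cluster <- function(index, parent, parent_abundance, children, child_abundance) {
  structure(list(index = index,
                 parent = parent,
                 parent_abundance = as.integer(parent_abundance),
                 children = children,
                 child_abundance = as.integer(child_abundance)),
            class = "sv_cluster")
}

#' @export
print.sv_cluster <- function(x, ...) {
  cat("<sv_cluster ", x$index, "> parent ", substr(x$parent, 1, 12),
      "... (", x$parent_abundance, " reads), ", length(x$children),
      " one-mismatch children\n", sep = "")
  invisible(x)
}

#' Greedy one-mismatch clustering of a variant table
#'
#' Repeatedly takes the most abundant unassigned variant as a cluster
#' parent (ties broken lexicographically by sequence), probes the hash of
#' unassigned variants with each of the parent's `3L` single-substitution
#' neighbors, assigns hits as the cluster's children, and removes parent and
#' children from the pool. Each variant ends up in exactly one cluster, as
#' parent or child; clusters are returned in creation order, i.e. by
#' non-increasing parent abundance.
#'
#' Each parent costs O(3L) hash probes, so the whole partition is built in
#' expected O(n * L) time for n variants — no pairwise distance matrix is
#' ever formed.
#'
#' @param table A `variant_table` from [dereplicate()].
#' @return A list of `sv_cluster` objects, class `sv_clusters`.
#' @export
build_clusters <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  totals <- variant_totals(table)
  if (length(totals) == 0L) stop("empty variant table: nothing to cluster")
  ord <- order(-totals, names(totals))
  seqs <- names(totals)[ord]
  tot <- unname(totals[ord])
  pool <- new.env(hash = TRUE, parent = emptyenv(),
                  size = max(29L, length(seqs)))
  for (i in seq_along(seqs)) assign(seqs[i], tot[i], envir = pool)
  clusters <- vector("list", length(seqs))
  nc <- 0L
  for (i in seq_along(seqs)) {
    p <- seqs[i]
    if (!exists(p, envir = pool, inherits = FALSE)) next   # already a child
    nb <- one_mismatch_neighbors(p)
    hit <- nb[vapply(nb, exists, logical(1), envir = pool, inherits = FALSE)]
    ab <- if (length(hit)) {
      vapply(hit, get, numeric(1), envir = pool)
    } else numeric(0)
    o <- order(-ab, hit)
    rm(list = c(p, hit), envir = pool)
    nc <- nc + 1L
    clusters[[nc]] <- new_cluster(nc, p, tot[i], unname(hit[o]), ab[o])
  }
  structure(clusters[seq_len(nc)], class = "sv_clusters")
}

#' @export
print.sv_clusters <- function(x, ...) {
  nch <- vapply(x, function(cl) length(cl$children), integer(1))
  cat("<sv_clusters> ", length(x), " clusters, ", sum(nch),
      " one-mismatch children\n", sep = "")
  invisible(x)
}

#' Fraction of possible one-mismatch children observed in a cluster
#'
#' @param cluster An `sv_cluster`.
#' @param L Sequence length.
#' @return `length(children) / (3 * L)`, in `[0, 1]`.
#' @export
children_fraction <- function(cluster, L) {
  stopifnot(inherits(cluster, "sv_cluster"), L >= 1)
  length(cluster$children) / (3 * L)
}

#' Flatten a clustering to a data frame
#'
#' One row per sequence with columns `cluster_index`, `role`
#' (`"parent"`/`"child"`), `sequence` and `total_abundance`.
#'
#' @param clusters An `sv_clusters` list.
#' @return A data frame.
#' @export
clusters_to_data_frame <- function(clusters) {
  stopifnot(inherits(clusters, "sv_clusters"))
  parts <- lapply(clusters, function(cl) {
    data.frame(cluster_index = cl$index,
               role = c("parent", rep("child", length(cl$children))),
               sequence = c(cl$parent, cl$children),
               total_abundance = c(cl$parent_abundance, cl$child_abundance),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Write a clustering as TSV
#'
#' @param clusters An `sv_clusters` list.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters_to_data_frame(clusters), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
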