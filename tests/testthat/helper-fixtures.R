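# shared fixtures and independent oracles

# variant_table straight from named totals, one sample
table_from_totals <- function(totals, sample_id = "A", L = NULL) {
  if (is.null(L)) L <- nchar(names(totals)[1])
  counts <- matrix(as.integer(totals), ncol = 1,
                   dimnames = list(names(totals), sample_id))
  structure(list(counts = counts, length = as.integer(L),
                 sample_ids = sample_id),
            class = "variant_table")
}

# character-level Hamming distance (oracle; independent of package internals)
hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# O(n^2) brute-force greedy one-mismatch clustering: sort by (-abundance,
# sequence); repeatedly take the first unassigned as parent and scan all
# remaining unassigned sequences for Hamming distance exactly 1
brute_force_clusters <- function(totals) {
  ord <- order(-totals, names(totals))
  seqs <- names(totals)[ord]
  assigned <- logical(length(seqs))
  out <- list()
  for (i in seq_along(seqs)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    kids <- character(0)
    for (j in seq_along(seqs)) {
      if (assigned[j]) next
      if (hamming_oracle(seqs[i], seqs[j]) == 1L) {
        assigned[j] <- TRUE
        kids <- c(kids, seqs[j])
      }
    }
    out[[length(out) + 1L]] <- list(parent = seqs[i], children = sort(kids))
  }
  out
}

# random instance for clustering tests: short alphabet so distance-1 pairs
# are common; abundances with ties
random_variant_totals <- function(n, L) {
  seqs <- unique(vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  stats::setNames(sample(2:500, length(seqs), replace = TRUE), seqs)
}

# simulate an error-only data set and run clustering + background calibration
# (depths chosen so >= 10 clusters carry defined child SDs after per-sample
# singleton removal)
simulate_error_only_run <- function(seed, n_parents = 25,
                                    depth_range = c(3.48, 4.78),
                                    error_rate = 0.00015) {
  cfg <- sim_config(n_parents = n_parents, length = 250,
                    parent_depths = round(10^seq(depth_range[1], depth_range[2],
                                                 length.out = n_parents)),
                    error_rate = error_rate, n_samples = 1, seed = seed)
  sim <- simulate_reads(cfg)
  tab <- dereplicate(sim$samples, 250)
  clusters <- build_clusters(tab)
  stats <- compute_cluster_stats(clusters)
  curves <- fit_loess(stats)
  list(sim = sim, table = tab, clusters = clusters, stats = stats,
       curves = curves)
}
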