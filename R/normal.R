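#' Per-cluster summary statistics of log10 child abundance
#'
#' For each cluster, log10-transforms the child total abundances and records
#' their mean (defined for >= 1 child) and sample standard deviation
#' (n - 1 denominator, defined for >= 2 children). Undefined statistics are
#' `NA`, never imputed.
#'
#' @param clusters An `sv_clusters` list.
#' @return Data frame with columns `cluster_index`, `parent`,
#'   `parent_abundance`, `log10_parent`, `n_children`, `mean_log10_child`,
#'   `sd_log10_child`.
#' @export
compute_cluster_stats <- function(clusters) {
  stopifnot(inherits(clusters, "sv_clusters"))
  do.call(rbind, lapply(clusters, function(cl) {
    lg <- log10(cl$child_abundance)
    n <- length(lg)
    data.frame(cluster_index = cl$index,
               parent = cl$parent,
               parent_abundance = cl$parent_abundance,
               log10_parent = log10(cl$parent_abundance),
               n_children = n,
               mean_log10_child = if (n >= 1L) mean(lg) else NA_real_,
               sd_log10_child = if (n >= 2L) sd(lg) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Calibrate the error background by local regression
#'
#' Fits two LOESS curves (locally weighted polynomial regression, tricube
#' weights, degree 2) describing the sequencing-error background as a
#' function of parent depth: the mean of log10 child abundance against log10
#' parent abundance (clusters with >= 1 child) and its standard deviation
#' (clusters with >= 2 children). Predictions outside the fitted abundance
#' range are clamped to the nearest fitted edge, and predicted SDs are
#' floored at `sd_floor` so the normal tail stays defined.
#'
#' @param stats Data frame from [compute_cluster_stats()].
#' @param span LOESS span in `(0, 1]`; default 0.75.
#' @param sd_floor Lower bound for predicted SD on the log10 scale.
#' @return A `loess_curves` object.
#' @export
fit_loess <- function(stats, span = 0.75, sd_floor = 1e-3) {
  stopifnot(is.data.frame(stats), span > 0, span <= 1, sd_floor > 0)
  mdat <- stats[!is.na(stats$mean_log10_child), , drop = FALSE]
  sdat <- stats[!is.na(stats$sd_log10_child), , drop = FALSE]
  if (nrow(mdat) < 10L || nrow(sdat) < 10L) {
    stop("too few clusters with defined child statistics to fit background ",
         "curves (need >= 10 for both mean and SD); supply more data or use ",
         "pooled_background()")
  }
  mean_fit <- loess(mean_log10_child ~ log10_parent, data = mdat,
                    span = span, degree = 2, family = "gaussian",
                    control = loess.control(surface = "direct"))
  sd_fit <- loess(sd_log10_child ~ log10_parent, data = sdat,
                  span = span, degree = 2, family = "gaussian",
                  control = loess.control(surface = "direct"))
  structure(list(mean_fit = mean_fit, sd_fit = sd_fit,
                 span = span, sd_floor = sd_floor,
                 domain_mean = range(mdat$log10_parent),
                 domain_sd = range(sdat$log10_parent)),
            class = "loess_curves")
}

#' @export
print.loess_curves <- function(x, ...) {
  cat(sprintf(
    "<loess_curves> span %.2f, fitted on log10 depth [%.2f, %.2f]\n",
    x$span, x$domain_mean[1], x$domain_mean[2]))
  invisible(x)
}

#' Constant background from pooled child abundances
#'
#' Fallback background for data sets too small to support a local
#' regression (fewer than 10 clusters with defined statistics, e.g. a
#' desk-scale mock community): the mean and SD of all log10 child abundances
#' pooled across clusters, used as depth-independent background curves.
#'
#' @param clusters An `sv_clusters` list with at least 2 children overall.
#' @param sd_floor Lower bound for the pooled SD.
#' @return A `constant_curves` object usable wherever `loess_curves` is.
#' @export
pooled_background <- function(clusters, sd_floor = 1e-3) {
  stopifnot(inherits(clusters, "sv_clusters"))
  lg <- log10(unlist(lapply(clusters, `[[`, "child_abundance"),
                     use.names = FALSE))
  if (length(lg) < 2L) {
    stop("cannot pool background: fewer than 2 children in total")
  }
  structure(list(mean = mean(lg), sd = max(sd(lg), sd_floor),
                 sd_floor = sd_floor, n_children = length(lg)),
            class = "constant_curves")
}

#' Predicted background mean at a given log10 parent depth
#'
#' @param curves A `loess_curves` or `constant_curves` object.
#' @param log10_parent Numeric vector of log10 parent abundances.
#' @return Predicted mean log10 child abundance(s).
#' @export
curve_mean <- function(curves, log10_parent) UseMethod("curve_mean")

#' Predicted background SD at a given log10 parent depth
#'
#' @inheritParams curve_mean
#' @return Predicted SD(s), floored at the curve's `sd_floor`.
#' @export
curve_sd <- function(curves, log10_parent) UseMethod("curve_sd")

#' @export
curve_mean.loess_curves <- function(curves, log10_parent) {
  x <- pmin(pmax(log10_parent, curves$domain_mean[1]), curves$domain_mean[2])
  unname(predict(curves$mean_fit, data.frame(log10_parent = x)))
}

#' @export
curve_sd.loess_curves <- function(curves, log10_parent) {
  x <- pmin(pmax(log10_parent, curves$domain_sd[1]), curves$domain_sd[2])
  pmax(unname(predict(curves$sd_fit, data.frame(log10_parent = x))),
       curves$sd_floor)
}

#' @export
curve_mean.constant_curves <- function(curves, log10_parent) {
  rep(curves$mean, length(log10_parent))
}

#' @export
curve_sd.constant_curves <- function(curves, log10_parent) {
  rep(max(curves$sd, curves$sd_floor), length(log10_parent))
}

# background parameters for one cluster under the max rule
background_params <- function(cluster_stats, curves) {
  m_fit <- curve_mean(curves, cluster_stats$log10_parent)
  s_fit <- curve_sd(curves, cluster_stats$log10_parent)
  m <- max(c(cluster_stats$mean_log10_child, m_fit), na.rm = TRUE)
  s <- max(c(cluster_stats$sd_log10_child, s_fit, curves$sd_floor),
           na.rm = TRUE)
  c(mean = m, sd = s)
}

#' One-sided normal test of a child variant against the error background
#'
#' The null hypothesis is that the child is a sequencing error of its
#' parent, with log10 abundance distributed Normal(M_i, S_i). To be
#' conservative, M_i is the larger of the cluster's own mean of log10 child
#' abundance and the LOESS background mean at the parent's depth, and S_i
#' the larger of the cluster SD and the LOESS background SD (an undefined
#' cluster statistic simply defers to the fitted curve). The p-value is the
#' upper-tail probability of `log10(child_abundance)` under that normal.
#'
#' @param child_abundance Positive integer count(s) of the child variant.
#' @param cluster_stats A single row of [compute_cluster_stats()] output (or
#'   an equivalent list with `log10_parent`, `mean_log10_child`,
#'   `sd_log10_child`).
#' @param curves Fitted background curves ([fit_loess()] or
#'   [pooled_background()]).
#' @return p-value(s) in `(0, 1)`; vectorized over `child_abundance`.
#' @export
child_p_value <- function(child_abundance, cluster_stats, curves) {
  stopifnot(all(child_abundance >= 1))
  bp <- background_params(cluster_stats, curves)
  if (!is.finite(bp["sd"]) || bp["sd"] <= 0) {
    stop("background SD is not positive; this should be prevented by the SD floor")
  }
  pnorm(log10(child_abundance), mean = bp["mean"], sd = bp["sd"],
        lower.tail = FALSE)
}

#' Call true sequence variants against the calibrated error background
#'
#' Clusters whose parent total abundance is below `min_parent_abundance`
#' (default 1,000 reads across all samples, the depth below which the
#' mean-depth relationship becomes too noisy to calibrate; deeper data sets
#' may warrant 10,000) are marked `filtered` and not tested. In retained
#' clusters the parent is called `true_variant`; each child is tested with
#' [child_p_value()], p-values are Benjamini-Hochberg adjusted jointly over
#' all tested children in the run, and a child is called `true_variant` iff
#' its q-value is below `fdr`, otherwise `error`.
#'
#' @param clusters An `sv_clusters` list.
#' @param stats Output of [compute_cluster_stats()] for the same clusters.
#' @param curves Fitted background curves.
#' @param min_parent_abundance Parent-depth filter threshold (reads).
#' @param fdr False-discovery-rate threshold in `(0, 1)`.
#' @return A `variant_calls` data frame with one row per sequence: columns
#'   `sequence`, `role`, `cluster_index`, `parent`, `total_abundance`,
#'   `log10_abundance`, `bg_mean`, `bg_sd`, `p_value`, `q_value`, `call`.
#' @export
call_variants <- function(clusters, stats, curves,
                          min_parent_abundance = 1000, fdr = 0.05) {
  stopifnot(inherits(clusters, "sv_clusters"), is.data.frame(stats),
            min_parent_abundance >= 0, fdr >= 0, fdr < 1)
  rows <- lapply(clusters, function(cl) {
    st <- stats[stats$cluster_index == cl$index, , drop = FALSE]
    retained <- cl$parent_abundance >= min_parent_abundance
    n <- length(cl$children)
    bg <- if (retained && n > 0L) background_params(st, curves) else c(mean = NA_real_, sd = NA_real_)
    p <- if (retained && n > 0L) {
      unname(child_p_value(cl$child_abundance, st, curves))
    } else rep(NA_real_, n)
    data.frame(
      sequence = c(cl$parent, cl$children),
      role = c("parent", rep("child", n)),
      cluster_index = cl$index,
      parent = cl$parent,
      total_abundance = c(cl$parent_abundance, cl$child_abundance),
      log10_abundance = log10(c(cl$parent_abundance, cl$child_abundance)),
      bg_mean = c(NA_real_, rep(unname(bg["mean"]), n)),
      bg_sd = c(NA_real_, rep(unname(bg["sd"]), n)),
      p_value = c(NA_real_, p),
      call = if (retained) c("true_variant", rep(NA_character_, n))
             else rep("filtered", n + 1L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  if (any(tested)) {
    out$q_value[tested] <- bh_adjust(out$p_value[tested])
    out$call[tested] <- ifelse(out$q_value[tested] < fdr,
                               "true_variant", "error")
  }
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Final per-sample count table for called variants
#'
#' Builds the output abundance table from a call set. Variants called
#' `true_variant` keep their own counts. Children called `error` either have
#' their per-sample counts added to their parent's row
#' (`error_handling = "collapse"`, the default, which preserves read depth
#' within retained clusters) or are discarded (`"drop"`). Clusters marked
#' `filtered` are excluded entirely.
#'
#' @param table The dereplicated `variant_table` the calls came from.
#' @param calls A `variant_calls` data frame.
#' @param error_handling `"collapse"` or `"drop"`.
#' @return A `variant_table` restricted to called variants.
#' @export
collapse_counts <- function(table, calls,
                            error_handling = c("collapse", "drop")) {
  stopifnot(inherits(table, "variant_table"), inherits(calls, "variant_calls"))
  error_handling <- match.arg(error_handling)
  keep <- calls$sequence[calls$call == "true_variant"]
  counts <- table$counts[keep, , drop = FALSE]
  if (error_handling == "collapse") {
    err <- calls[calls$call == "error", , drop = FALSE]
    for (i in seq_len(nrow(err))) {
      counts[err$parent[i], ] <- counts[err$parent[i], ] +
        table$counts[err$sequence[i], ]
    }
  }
  structure(list(counts = counts, length = table$length,
                 sample_ids = table$sample_ids),
            class = "variant_table")
}
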