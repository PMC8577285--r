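#' Expected fraction of observed one-mismatch children under the Poisson
#' error model
#'
#' With a per-base substitution rate `error_rate`, a specific one of the 3L
#' possible single-substitution variants of a parent sequenced to depth
#' `parent_abundance` is generated per read with rate `error_rate / 3`
#' (three alternative bases per position). The probability that it is seen
#' at least once is the zero-truncation of a Poisson count:
#' `1 - exp(-parent_abundance * error_rate / 3)`.
#'
#' @param parent_abundance Parent read depth(s), >= 1.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @return Expected observed fraction(s) in `[0, 1]`; vectorized over
#'   `parent_abundance`.
#' @export
expected_children_fraction <- function(parent_abundance, error_rate) {
  stopifnot(all(parent_abundance >= 1), length(error_rate) == 1L,
            error_rate >= 0, error_rate <= 1)
  1 - exp(-parent_abundance * error_rate / 3)
}

new_poisson_fit <- function(error_rate, residual_sse, n_clusters_used) {
  structure(list(error_rate = error_rate,
                 residual_sse = residual_sse,
                 n_clusters_used = n_clusters_used),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("<poisson_fit> per-base error rate %.4g (SSE %.4g, %d clusters)\n",
              x$error_rate, x$residual_sse, x$n_clusters_used))
  invisible(x)
}

#' Fit the per-base error rate to observed child fractions
#'
#' Low-level fitting routine: finds the single rate `P` minimizing the sum of
#' squared differences between the observed fraction of possible one-mismatch
#' children and [expected_children_fraction()] across parents. The search is
#' a bounded scalar minimization of the least-squares objective over
#' `P` in `[1e-7, 1e-1]` (carried out on the log10 scale for uniform relative
#' precision).
#'
#' @param parent_abundance Vector of parent depths.
#' @param observed_fraction Vector of observed fractions in `[0, 1]`, same
#'   length.
#' @return A `poisson_fit` with fields `error_rate`, `residual_sse`,
#'   `n_clusters_used`.
#' @export
fit_error_rate_points <- function(parent_abundance, observed_fraction) {
  stopifnot(length(parent_abundance) == length(observed_fraction),
            length(parent_abundance) >= 2L,
            all(parent_abundance >= 1),
            all(observed_fraction >= 0), all(observed_fraction <= 1))
  if (length(parent_abundance) < 10L ||
      diff(range(log10(parent_abundance))) < 2) {
    warning("error-rate fit may be unreliable: fewer than 10 clusters or ",
            "parent depths spanning less than two decades")
  }
  if (all(observed_fraction == 0)) {
    stop("cannot fit error rate: no one-mismatch children observed")
  }
  sse <- function(l) {
    sum((observed_fraction -
           expected_children_fraction(parent_abundance, 10^l))^2)
  }
  opt <- optimize(sse, interval = c(-7, -1), tol = 1e-10)
  new_poisson_fit(10^opt$minimum, opt$objective, length(parent_abundance))
}

#' Fit the per-base error rate from a one-mismatch clustering
#'
#' Computes each cluster's observed fraction of the 3L possible one-mismatch
#' children ([children_fraction()]) and fits the one-parameter Poisson
#' presence/absence model by least squares (see [fit_error_rate_points()]).
#'
#' @param clusters An `sv_clusters` list from [build_clusters()].
#' @param L Sequence length.
#' @return A `poisson_fit`.
#' @export
fit_error_rate <- function(clusters, L) {
  stopifnot(inherits(clusters, "sv_clusters"), L >= 1)
  fit_error_rate_points(
    vapply(clusters, `[[`, numeric(1), "parent_abundance"),
    vapply(clusters, children_fraction, numeric(1), L = L))
}

#' One-sided Poisson abundance test for a child variant
#'
#' Exact upper-tail Poisson probability `Pr(X >= C)` for a child observed
#' `C` times when its parent has depth `parent_abundance` and reads mutate at
#' `error_rate` per base (`lambda = parent_abundance * error_rate / 3`). This
#' is the p-value of R's one-sided rate test
#' `poisson.test(C, parent_abundance, error_rate/3, alternative = "greater")`.
#' On real amplicon data child abundances are overdispersed relative to the
#' Poisson, so this test is anticonservative; it is provided for diagnostics
#' and comparison, and is not used by [call_variants()].
#'
#' @param child_abundance Non-negative integer count(s).
#' @param parent_abundance Parent depth(s), >= 1.
#' @param error_rate Per-base substitution probability in `(0, 1)`.
#' @return p-value(s) in `(0, 1]`; vectorized.
#' @export
poisson_test <- function(child_abundance, parent_abundance, error_rate) {
  stopifnot(all(child_abundance >= 0), all(parent_abundance >= 1),
            length(error_rate) == 1L, error_rate > 0, error_rate < 1)
  ppois(child_abundance - 1, parent_abundance * error_rate / 3,
        lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up adjustment, preserving input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an
#'   error.
#' @return Vector of q-values in `[0, 1]`, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values)) stop("p-values contain NA/NaN")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-cluster dispersion of child abundance
#'
#' Mean and variance of raw child counts per cluster, the diagnostic used to
#' check the Poisson assumption (variance = mean). Real data typically show
#' variance well above the mean (overdispersion), which is why the final
#' caller uses a normal background instead.
#'
#' @param clusters An `sv_clusters` list.
#' @return Data frame with columns `cluster_index`, `parent_abundance`,
#'   `n_children`, `mean_child`, `var_child` (`NA` where undefined).
#' @export
cluster_dispersion <- function(clusters) {
  stopifnot(inherits(clusters, "sv_clusters"))
  do.call(rbind, lapply(clusters, function(cl) {
    n <- length(cl$child_abundance)
    data.frame(cluster_index = cl$index,
               parent_abundance = cl$parent_abundance,
               n_children = n,
               mean_child = if (n >= 1L) mean(cl$child_abundance) else NA_real_,
               var_child = if (n >= 2L) stats::var(cl$child_abundance) else NA_real_)
  }))
}
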