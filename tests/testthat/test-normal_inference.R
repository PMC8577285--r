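make_clusters <- function(parent_abundance, child_abundances) {
  # synthetic sv_clusters with given abundances; sequences are placeholders
  structure(lapply(seq_along(parent_abundance), function(i) {
    kids <- child_abundances[[i]]
    structure(list(index = i,
                   parent = sprintf("P%03d", i),
                   parent_abundance = as.integer(parent_abundance[i]),
                   children = if (length(kids)) sprintf("P%03d_c%d", i, seq_along(kids)) else character(0),
                   child_abundance = as.integer(kids)),
              class = "sv_cluster")
  }), class = "sv_clusters")
}

test_that("cluster statistics are log10 mean/SD with NA where undefined", {
  cl <- make_clusters(c(5000, 400, 300),
                      list(c(10, 100, 1000), c(100), integer(0)))
  st <- compute_cluster_stats(cl)
  expect_equal(st$mean_log10_child, c(2, 2, NA))
  expect_equal(st$sd_log10_child, c(1, NA, NA))
  expect_equal(st$n_children, c(3L, 1L, 0L))
  expect_equal(st$log10_parent, log10(c(5000, 400, 300)))
})

test_that("LOESS curves reproduce polynomials and constants exactly", {
  x <- seq(2, 5, length.out = 40)
  stats <- data.frame(cluster_index = seq_along(x), log10_parent = x,
                      mean_log10_child = x,          # the line y = x
                      sd_log10_child = 0.3,          # constant SD
                      n_children = 5L)
  curves <- fit_loess(stats)
  xs <- seq(2.5, 4.5, length.out = 7)
  expect_equal(curve_mean(curves, xs), xs, tolerance = 1e-6)
  expect_equal(curve_sd(curves, xs), rep(0.3, 7), tolerance = 1e-6)
})

test_that("LOESS recovers a noisy smooth trend and clamps extrapolation", {
  set.seed(23)
  x <- runif(200, 2, 5)
  stats <- data.frame(cluster_index = seq_along(x), log10_parent = x,
                      mean_log10_child = 0.5 * x - 1 + rnorm(200, 0, 0.05),
                      sd_log10_child = 0.2 + 0.02 * x + rnorm(200, 0, 0.02),
                      n_children = 5L)
  curves <- fit_loess(stats)
  xs <- seq(2.5, 4.5, length.out = 9)
  expect_true(all(abs(curve_mean(curves, xs) - (0.5 * xs - 1)) < 0.05))

  # predictions outside the fitted depth range stick to the edge values
  expect_equal(curve_mean(curves, 10), curve_mean(curves, max(x)))
  expect_equal(curve_mean(curves, 0), curve_mean(curves, min(x)))
  # SD predictions are floored strictly above zero
  expect_true(all(curve_sd(curves, seq(0, 10, by = 0.5)) >= curves$sd_floor))
})

test_that("LOESS fitting refuses too-few clusters, pooled background steps in", {
  stats <- data.frame(cluster_index = 1:5, log10_parent = 1:5,
                      mean_log10_child = 1:5, sd_log10_child = 0.1,
                      n_children = 3L)
  expect_error(fit_loess(stats), "too few clusters")

  cl <- make_clusters(c(1000, 2000), list(c(10, 100), c(10, 1000)))
  bg <- pooled_background(cl)
  lg <- log10(c(10, 100, 10, 1000))
  expect_equal(curve_mean(bg, 3.5), mean(lg))
  expect_equal(curve_sd(bg, 3.5), sd(lg))
})

test_that("the child test is a one-sided normal tail under the max rule", {
  x <- seq(2, 5, length.out = 40)
  curves <- fit_loess(data.frame(cluster_index = seq_along(x),
                                 log10_parent = x,
                                 mean_log10_child = 1.0,
                                 sd_log10_child = 0.5,
                                 n_children = 5L))
  st <- list(log10_parent = 3.5, mean_log10_child = NA_real_,
             sd_log10_child = NA_real_)
  # child exactly at the background mean: p = 1/2 by symmetry
  expect_equal(child_p_value(10, st, curves), 0.5, tolerance = 1e-6)
  # log10(1000) = 3 is 4 SDs above M = 1: standard normal upper tail at z = 4
  expect_equal(child_p_value(1000, st, curves), pnorm(4, lower.tail = FALSE),
               tolerance = 1e-6)

  # max rule: the larger of sample SD and curve SD wins (more conservative)
  st_wide <- list(log10_parent = 3.5, mean_log10_child = 1.0,
                  sd_log10_child = 0.2)
  expect_equal(child_p_value(1000, st_wide, curves),
               pnorm(3, 1, 0.5, lower.tail = FALSE), tolerance = 1e-6)
  st_wider <- list(log10_parent = 3.5, mean_log10_child = 1.0,
                   sd_log10_child = 0.8)
  expect_equal(child_p_value(1000, st_wider, curves),
               pnorm(3, 1, 0.8, lower.tail = FALSE), tolerance = 1e-6)
  # and a larger SD never lowers the p-value of an above-mean child
  expect_gt(child_p_value(1000, st_wider, curves),
            child_p_value(1000, st_wide, curves))
})

test_that("call_variants filters shallow clusters, tests children, controls by BH", {
  set.seed(31)
  x <- 10^seq(3, 5, length.out = 30)
  cl <- make_clusters(
    c(x, 999),
    c(lapply(x, function(p) pmax(2, round(10^rnorm(8, 0.6 + 0.4 * log10(p) - 1.2, 0.15)))),
      list(c(5, 7))))
  st <- compute_cluster_stats(cl)
  curves <- fit_loess(st)
  calls <- call_variants(cl, st, curves, min_parent_abundance = 1000,
                         fdr = 0.05)

  # the sub-threshold cluster is entirely filtered, untested
  f <- calls[calls$cluster_index == 31L, ]
  expect_true(all(f$call == "filtered"))
  expect_true(all(is.na(f$p_value)))

  # retained parents are all called true exactly once
  parents <- calls[calls$role == "parent" & calls$call != "filtered", ]
  expect_identical(nrow(parents), 30L)
  expect_true(all(parents$call == "true_variant"))
  expect_identical(anyDuplicated(parents$sequence), 0L)

  # tested children carry BH-consistent q-values
  ch <- calls[!is.na(calls$p_value), ]
  expect_equal(ch$q_value, bh_adjust(ch$p_value))
  expect_true(all(ch$call[ch$q_value < 0.05] == "true_variant"))
  expect_true(all(ch$call[ch$q_value >= 0.05] == "error"))

  # raising the threshold never increases the number of calls
  calls_hi <- call_variants(cl, st, curves, min_parent_abundance = 10000,
                            fdr = 0.05)
  expect_lte(sum(calls_hi$call == "true_variant"),
             sum(calls$call == "true_variant"))
})

test_that("an extreme child is called true against 100-test BH correction", {
  x <- 10^seq(3, 5, length.out = 25)
  kid_sets <- lapply(x, function(p) rep(4L, 4))      # flat background, sd 0
  cl <- make_clusters(c(50000, x), c(list(c(rep(4L, 30), 40000L)), kid_sets))
  st <- compute_cluster_stats(cl)
  curves <- fit_loess(st)
  calls <- call_variants(cl, st, curves)
  big <- calls[calls$total_abundance == 40000L & calls$role == "child", ]
  expect_identical(big$call, "true_variant")
  expect_lt(big$q_value, 0.05)
})

test_that("error collapse returns child reads to the parent, drop discards them", {
  tab <- table_from_totals(c(AAAA = 5000L, AAAT = 10L, TTTT = 2000L))
  cl <- build_clusters(tab)
  st <- compute_cluster_stats(cl)
  calls <- call_variants(cl, st, pooled_background(make_clusters(1000, list(c(5, 20, 10, 7)))),
                         min_parent_abundance = 1000, fdr = 0.05)
  expect_identical(calls$call[calls$sequence == "AAAT"], "error")

  kept <- collapse_counts(tab, calls, "collapse")
  expect_identical(sum(kept$counts), 5000L + 10L + 2000L)
  expect_identical(unname(kept$counts["AAAA", "A"]), 5010L)

  dropped <- collapse_counts(tab, calls, "drop")
  expect_identical(sum(dropped$counts), 5000L + 2000L)
})
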