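test_that("zero error rate copies templates verbatim; rate one spares no base", {
  cfg <- sim_config(parents = c("ACGTACGT", "TTTTCCCC"),
                    parent_depths = c(20, 10), error_rate = 0,
                    n_samples = 2, seed = 3)
  sim <- simulate_reads(cfg)
  reads <- unlist(lapply(sim$samples, `[[`, "reads"))
  expect_length(reads, 30L)
  expect_setequal(unique(reads), c("ACGTACGT", "TTTTCCCC"))

  set.seed(1)
  hot <- mutate_reads("ACGTACGT", 50, 1)
  ref <- strsplit("ACGTACGT", "")[[1]]
  for (r in hot) expect_true(all(strsplit(r, "")[[1]] != ref))
})

test_that("reads are dealt round-robin and the run is seed-reproducible", {
  cfg <- sim_config(parents = "ACGTACGTAC", parent_depths = 10,
                    error_rate = 0.01, n_samples = 3, seed = 11)
  sim1 <- simulate_reads(cfg)
  expect_identical(vapply(sim1$samples, function(s) length(s$reads), integer(1)),
                   c(4L, 3L, 3L))
  sim2 <- simulate_reads(cfg)
  expect_identical(lapply(sim1$samples, `[[`, "reads"),
                   lapply(sim2$samples, `[[`, "reads"))
})

test_that("planted children are recorded in the truth table one mismatch away", {
  cfg <- sim_config(n_parents = 3, length = 30,
                    parent_depths = c(100, 100, 100), error_rate = 0,
                    planted_children = data.frame(parent_index = 2L,
                                                  position = 7L,
                                                  base = NA_character_,
                                                  depth = 40L),
                    seed = 19)
  sim <- simulate_reads(cfg)
  expect_identical(sim$truth$origin, c(rep("parent", 3), "planted_child"))
  expect_identical(hamming_oracle(sim$truth$sequence[2],
                                  sim$truth$sequence[4]), 1L)
  expect_identical(sum(sim$truth$sequence[4] ==
                         unlist(lapply(sim$samples, `[[`, "reads"))), 40L)
})

test_that("substitution counts per read are Binomial(L, P) in aggregate", {
  set.seed(29)
  L <- 100
  p <- 0.002
  reads <- mutate_reads(paste(rep("A", L), collapse = ""), 20000, p)
  n_sub <- vapply(reads, function(r) {
    sum(strsplit(r, "")[[1]] != "A")
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(mean(n_sub), L * p, tolerance = 0.1)
  # fraction of untouched reads ~ (1 - p)^L
  expect_equal(mean(n_sub == 0), (1 - p)^L, tolerance = 0.02)
})

test_that("observed child fractions track the Poisson accumulation curve", {
  acc <- children_accumulation(c(1, 100, 31623, 100000), L = 250,
                               error_rate = 1.5e-4, seed = 37)
  # depth 1: at most one mutated read, fraction essentially 0
  expect_lte(acc$observed_fraction[1], 1 / 750)
  # depth 1e5: 1 - exp(-5) with binomial sampling slack (3 SE ~ 0.008)
  expect_equal(acc$observed_fraction[4], 1 - exp(-5), tolerance = 0.015)
  # fraction grows with depth
  expect_true(all(diff(acc$observed_fraction) > 0))

  # against the model curve across 3+ decades, 3 binomial SEs per point
  expected <- expected_children_fraction(acc$depth, 1.5e-4)
  se <- sqrt(expected * (1 - expected) / 750)
  expect_true(all(abs(acc$observed_fraction - expected) <= 3 * se + 1e-3))
})

test_that("mean accumulation over replicate simulations is non-decreasing in depth", {
  depths <- c(300, 3000, 30000)
  reps <- vapply(1:10, function(s) {
    children_accumulation(depths, L = 100, error_rate = 2e-4,
                          seed = 1000 + s)$observed_fraction
  }, numeric(3))
  expect_true(all(diff(rowMeans(reps)) > 0))
})

test_that("simulated samples round-trip through FASTA with a truth table", {
  cfg <- sim_config(n_parents = 2, length = 40, parent_depths = c(30, 20),
                    error_rate = 0.001, n_samples = 2, seed = 5)
  sim <- simulate_reads(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_fasta(sim, dir)
  expect_identical(names(paths), c("S1", "S2"))
  back <- read_sample(paths[["S1"]], "fasta")
  expect_identical(back$reads, sim$samples[[1]]$reads)
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  expect_identical(truth$sequence, sim$truth$sequence)
})
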