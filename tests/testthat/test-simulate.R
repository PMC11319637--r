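# Genome simulator: determinism, truth bookkeeping, mutation statistics,
# lineage logic and truth-file round trips.

test_that("zero mutation rates reproduce the master exactly", {
  cfg <- simulation_config(seed = 1, sub_rate = 0, indel_rate = 0,
                           n_copies_per_burst = 10, burst_times = 5)
  sim <- simulate_genomes(cfg)
  seqs <- sim_copy_sequences(sim)
  expect_length(seqs, 10)
  expect_true(all(seqs == sim$masters[[1]]))
  expect_true(all(startsWith(seqs, "TG")))
  expect_true(all(endsWith(seqs, "CA")))
})

test_that("a copy inserted after a split is lineage specific", {
  cfg <- simulation_config(seed = 2, sub_rate = 0, indel_rate = 0,
                           n_copies_per_burst = 1, burst_times = 3,
                           speciation_times = 5)
  sim <- simulate_genomes(cfg)
  expect_equal(sim$truth$species_presence, "focal")
  cfg2 <- simulation_config(seed = 2, sub_rate = 0, indel_rate = 0,
                            n_copies_per_burst = 1, burst_times = 7,
                            speciation_times = 5)
  sim2 <- simulate_genomes(cfg2)
  expect_equal(sim2$truth$species_presence, "focal,outgroup1")
})

test_that("mean mismatch fraction matches the binomial expectation", {
  cfg <- simulation_config(seed = 1, n_copies_per_burst = 100,
                           burst_times = 5, sub_rate = 0.01,
                           indel_rate = 0, master_length = 500)
  sim <- simulate_genomes(cfg)
  # substitutions always change the base, so the logged count is the
  # mismatch count to the master
  frac <- sim$truth$n_subst / 500
  p <- 0.05
  se <- sqrt(p * (1 - p) / (500 * 100))
  expect_lt(abs(mean(frac) - p), 3 * se)
})

test_that("identical configs give byte-identical output", {
  cfg <- simulation_config(seed = 33, n_copies_per_burst = 15,
                           burst_times = 6, speciation_times = c(3, 8))
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$intervals, s2$intervals)
})

test_that("truth covers every configured copy and lineage logic holds", {
  cfg <- simulation_config(seed = 4, n_copies_per_burst = 12,
                           burst_times = c(2, 6, 9),
                           speciation_times = c(4, 7),
                           subfamily_events = list(
                             list(time = 5, type = "deletion",
                                  position = 100, length = 20,
                                  n_copies = 7)),
                           hybrid_events = list(
                             list(time = 5, family_a = "famA",
                                  family_b = "famA", breakpoint_a = 150,
                                  breakpoint_b = 300, n_copies = 5)))
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(sim$truth), 3 * 12 + 7 + 5)
  # |presence| is determined solely by insertion time vs split ages
  for (i in seq_len(nrow(sim$truth))) {
    n_expected <- 1L + sum(c(4, 7) < sim$truth$insertion_time[i])
    n_actual <- length(strsplit(sim$truth$species_presence[i], ",")[[1]])
    expect_equal(n_actual, n_expected)
  }
})

test_that("hybrid founders are exact joins at the configured breakpoints", {
  cfg <- simulation_config(seed = 5, sub_rate = 0, indel_rate = 0,
                           family_lengths = c(fa = 400L, fb = 500L),
                           bursts = data.frame(time = 5,
                                               family = c("fa", "fb"),
                                               n_copies = 1),
                           hybrid_events = list(
                             list(time = 5, family_a = "fa",
                                  family_b = "fb", breakpoint_a = 150,
                                  breakpoint_b = 200, n_copies = 2),
                             list(time = 5, family_a = "fa",
                                  family_b = "fb", breakpoint_a = 150,
                                  breakpoint_b = 200, breakpoint_b2 = 400,
                                  breakpoint_a2 = 250, n_copies = 2,
                                  name = "h3")))
  sim <- simulate_genomes(cfg)
  fa <- sim$masters[["fa"]]; fb <- sim$masters[["fb"]]
  expect_equal(sim$founders[["hybrid1"]],
               paste0(substr(fa, 1, 150), substr(fb, 201, 500)))
  expect_equal(sim$founders[["h3"]],
               paste0(substr(fa, 1, 150), substr(fb, 201, 400),
                      substr(fa, 251, 400)))
  seqs <- sim_copy_sequences(sim)
  hyb <- seqs[sim$truth$copy_id[sim$truth$family == "hybrid1"]]
  expect_true(all(hyb == sim$founders[["hybrid1"]]))
})

test_that("configuration errors are caught", {
  expect_error(simulation_config(seed = 1, sub_rate = -1), "rates")
  expect_error(
    simulation_config(seed = 1, burst_times = 5,
                      subfamily_events = list(
                        list(time = 9, type = "deletion", position = 100,
                             length = 20, n_copies = 5))),
    "older than the oldest")
  expect_error(
    simulation_config(seed = 1,
                      subfamily_events = list(
                        list(time = 2, type = "deletion", position = 490,
                             length = 20, n_copies = 5))),
    "inside the consensus")
  expect_error(
    simulation_config(seed = 1, hybrid_events = list(
      list(time = 2, family_a = "famA", family_b = "nope",
           breakpoint_a = 10, breakpoint_b = 10, n_copies = 1))),
    "unknown hybrid family")
})

test_that("truth files round-trip losslessly", {
  cfg <- simulation_config(seed = 6, n_copies_per_burst = 4,
                           burst_times = 6, speciation_times = 4)
  sim <- simulate_genomes(cfg)
  d1 <- file.path(tempdir(), "truth1")
  d2 <- file.path(tempdir(), "truth2")
  write_truth(sim, d1)
  rt <- read_truth(d1)
  expect_equal(rt$truth, sim$truth)
  expect_equal(nrow(rt$intervals), nrow(sim$intervals))
  sim2 <- sim
  sim2$truth <- rt$truth
  sim2$intervals <- rt$intervals[order(match(rt$intervals$species,
                                             sim$species)), ]
  write_truth(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("truth file shapes: empty truth and one record, two species", {
  cfg <- simulation_config(seed = 7, bursts = data.frame(
    time = numeric(0), family = character(0), n_copies = integer(0)),
    speciation_times = 4)
  sim <- simulate_genomes(cfg)
  d <- file.path(tempdir(), "truth_empty")
  write_truth(sim, d)
  expect_equal(length(readLines(file.path(d, "truth.tsv"))), 1) # header only
  expect_equal(file.size(file.path(d, "focal.bed")), 0)
  cfg1 <- simulation_config(seed = 8, n_copies_per_burst = 1,
                            burst_times = 6, speciation_times = 4)
  sim1 <- simulate_genomes(cfg1)
  d <- file.path(tempdir(), "truth_one")
  write_truth(sim1, d)
  expect_equal(length(readLines(file.path(d, "focal.bed"))), 1)
  expect_equal(length(readLines(file.path(d, "outgroup1.bed"))), 1)
  expect_equal(length(readLines(file.path(d, "truth.tsv"))), 2) # header + 1
})
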