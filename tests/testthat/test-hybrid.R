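# Element assembly, hybrid flagging and breakpoint clustering.

make_segments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome_start = r[[1]], genome_end = r[[2]],
               consensus_name = r[[3]],
               consensus_start = r[[4]], consensus_end = r[[5]],
               strand = r[[6]], segment_score = 100, parent = NA,
               stringsAsFactors = FALSE)))
}

test_that("a single segment forms one simple element", {
  seg <- make_segments(list(100, 400, "A", 0, 300, "+"))
  els <- assemble_elements(seg)
  expect_length(els, 1)
  expect_false(els[[1]]$is_hybrid)
  expect_equal(nrow(els[[1]]$breakpoints), 0)
})

test_that("contiguous A/B/A segments form one hybrid with two breakpoints", {
  seg <- make_segments(list(0, 180, "MLT2A2", 0, 180, "+"),
                       list(181, 480, "MLT2B3", 120, 420, "+"),
                       list(482, 650, "MLT2A2", 280, 453, "+"))
  els <- assemble_elements(seg, max_gap = 100)
  expect_length(els, 1)
  el <- els[[1]]
  expect_true(el$is_hybrid)
  expect_equal(el$composition, c("MLT2A2", "MLT2B3", "MLT2A2"))
  expect_equal(nrow(el$breakpoints), 2)
  expect_equal(el$breakpoints$left_consensus_end, c(180, 420))
  expect_equal(el$breakpoints$right_consensus_start, c(120, 280))
})

test_that("segments far apart stay separate elements", {
  seg <- make_segments(list(0, 300, "A", 0, 300, "+"),
                       list(5300, 5600, "B", 0, 300, "+"))
  els <- assemble_elements(seg, max_gap = 200)
  expect_length(els, 2)
  expect_false(any(vapply(els, `[[`, TRUE, "is_hybrid")))
})

test_that("adjacent same-family segments collapse in the composition", {
  seg <- make_segments(list(0, 100, "A", 0, 100, "+"),
                       list(110, 200, "A", 110, 200, "+"),
                       list(210, 400, "B", 50, 240, "+"))
  el <- assemble_elements(seg)[[1]]
  expect_equal(el$composition, c("A", "B"))
  expect_equal(nrow(el$breakpoints), 1)
})

test_that("minus-strand elements report consensus-forward composition", {
  # plus-strand A[0:180) then B[120:500); its reverse-complement insertion
  # annotates as B on minus first, A on minus second
  seg <- make_segments(list(0, 380, "B", 120, 500, "-"),
                       list(381, 560, "A", 0, 180, "-"))
  el <- assemble_elements(seg)[[1]]
  expect_equal(el$composition, c("A", "B"))
  expect_equal(el$breakpoints$left_consensus_end, 180)
  expect_equal(el$breakpoints$right_consensus_start, 120)
})

test_that("unsorted or overlapping segments error", {
  seg <- make_segments(list(100, 200, "A", 0, 100, "+"),
                       list(0, 90, "B", 0, 90, "+"))
  expect_error(assemble_elements(seg), "sorted")
  seg2 <- make_segments(list(0, 200, "A", 0, 200, "+"),
                        list(150, 300, "B", 0, 150, "+"))
  expect_error(assemble_elements(seg2), "non-overlapping")
})

make_hybrid <- function(bp1_end, bp1_start, comp = c("A", "B")) {
  list(genome_start = 0, genome_end = 500,
       segments = data.frame(strand = "+"),
       composition = comp, is_hybrid = TRUE,
       breakpoints = data.frame(
         left_family = comp[-length(comp)],
         left_consensus_end = bp1_end,
         right_family = comp[-1],
         right_consensus_start = bp1_start,
         genome_position = 250, stringsAsFactors = FALSE))
}

test_that("identical breakpoints cluster into one class", {
  hyb <- replicate(50, make_hybrid(180, 120), simplify = FALSE)
  cls <- cluster_hybrids(hyb)
  expect_length(cls, 1)
  expect_equal(cls[[1]]$member_count, 50)
  expect_equal(cls[[1]]$dispersion, 0)
})

test_that("jitter within tolerance keeps one class; separated modes split", {
  set.seed(401)
  tol <- 15
  jit <- lapply(1:30, function(i)
    make_hybrid(180 + sample(-7:7, 1), 120 + sample(-7:7, 1)))
  expect_length(cluster_hybrids(jit, tol), 1)
  two <- c(lapply(1:20, function(i) make_hybrid(180, 120)),
           lapply(1:10, function(i) make_hybrid(180 + 3 * tol, 120)))
  cls <- cluster_hybrids(two, tol)
  expect_length(cls, 2)
  expect_equal(cls[[1]]$member_count, 20)
  # single-linkage oracle agrees on membership
  vecs <- do.call(rbind, lapply(two, ltrsubfam:::.bp_vector))
  lab <- oracle_single_linkage(vecs, tol)
  expect_equal(length(unique(lab)), 2)
})

test_that("cluster membership equals transitive-closure single linkage", {
  set.seed(402)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    hyb <- lapply(seq_len(n), function(i)
      make_hybrid(sample(c(100, 180, 300), 1) + sample(-10:10, 1),
                  sample(c(50, 220), 1) + sample(-10:10, 1)))
    cls <- cluster_hybrids(hyb, 15)
    vecs <- do.call(rbind, lapply(hyb, ltrsubfam:::.bp_vector))
    lab <- oracle_single_linkage(vecs, 15)
    expect_equal(length(cls), length(unique(lab)))
    # partition of members: each hybrid in exactly one class
    all_members <- sort(unlist(lapply(cls, `[[`, "members")))
    expect_equal(all_members, seq_len(n))
  }
})

test_that("ordered compositions (A,B) and (B,A) never merge", {
  hyb <- c(lapply(1:5, function(i) make_hybrid(180, 120, c("A", "B"))),
           lapply(1:5, function(i) make_hybrid(180, 120, c("B", "A"))))
  cls <- cluster_hybrids(hyb)
  expect_length(cls, 2)
})

test_that("promotion refuses classes below min_copies", {
  cls <- list(member_count = 3, composition = c("A", "B"),
              representative_breakpoints = data.frame())
  expect_error(promote_class_to_family(cls, c(a = "ACGT"), fixture_model(),
                                       min_copies = 20),
               "min_copies")
})

test_that("a recurrent hybrid class is recovered with accurate breakpoints", {
  cfg <- simulation_config(seed = 403,
    family_lengths = c(famA = 453L, famB = 550L),
    bursts = data.frame(time = 8, family = c("famA", "famB"),
                        n_copies = 10),
    hybrid_events = list(list(time = 8, family_a = "famA",
                              family_b = "famB", breakpoint_a = 180,
                              breakpoint_b = 120, breakpoint_b2 = 420,
                              breakpoint_a2 = 280, n_copies = 25,
                              name = "aba_like")),
    sub_rate = 0.01, background_length = 250)
  sim <- simulate_genomes(cfg)
  seqs <- sim_copy_sequences(sim)
  mod <- train_model(seqs, sim$masters, tol = 1e-3)
  ann <- annotate_genome(sim$genomes[["focal"]], sim$masters, mod)
  els <- assemble_elements(ann)
  hyb <- els[vapply(els, `[[`, TRUE, "is_hybrid")]
  cls <- cluster_hybrids(hyb)
  top <- cls[[1]]
  expect_equal(top$composition, c("famA", "famB", "famA"))
  bp <- top$representative_breakpoints
  expect_lt(abs(bp$left_consensus_end[1] - 180), 10)
  expect_lt(abs(bp$right_consensus_start[1] - 120), 10)
  expect_lt(abs(bp$left_consensus_end[2] - 420), 10)
  expect_lt(abs(bp$right_consensus_start[2] - 280), 10)
  # promoted consensus close to the true founder
  esq <- element_sequences(hyb[top$members], sim$genomes[["focal"]])
  pm <- promote_class_to_family(top, esq, mod, name = "rec",
                                min_copies = 10)
  ps <- pairwise_stats(pm$consensus$sequence, sim$founders[["aba_like"]],
                       mod, "semiglobal")
  expect_lt(ps$percent_divergence, 1)
})
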