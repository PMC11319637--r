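# Cohort detection, family splitting and the iterate-to-convergence loop.
# (the make_family fixture generator lives in helper-family.R)

test_that("a planted shared deletion is detected at the right interval", {
  set.seed(601)
  master <- random_test_dna(400)
  fam <- make_family(master, 60, list(list(del = c(200, 25), n = 40)))
  m <- fixture_model()
  prof <- consensus_column_profile(master, fam$seqs, m)
  cohort <- detect_cohort(prof$alignments, 400, min_support = 10)
  expect_false(is.null(cohort))
  expect_equal(cohort$feature_type, "shared_deletion")
  expect_equal(sort(cohort$members),
               sort(names(fam$labels)[fam$labels == "cohort1"]))
  expect_lt(abs(cohort$consensus_interval[1] - 199), 10)
  expect_lt(abs(cohort$consensus_interval[2] - 224), 10)
})

test_that("homogeneous instances yield no cohort", {
  set.seed(602)
  master <- random_test_dna(400)
  fam <- make_family(master, 50, list())
  m <- fixture_model()
  prof <- consensus_column_profile(master, fam$seqs, m)
  expect_null(detect_cohort(prof$alignments, 400, min_support = 10))
})

test_that("with two planted cohorts the larger one is returned first", {
  set.seed(603)
  master <- random_test_dna(400)
  fam <- make_family(master, 35,
                     list(list(del = c(150, 25), n = 40),
                          list(del = c(300, 30), n = 25)))
  m <- fixture_model()
  prof <- consensus_column_profile(master, fam$seqs, m)
  cohort <- detect_cohort(prof$alignments, 400, min_support = 10)
  expect_equal(cohort$support, 40)
  expect_lt(abs(cohort$consensus_interval[1] - 149), 10)
})

test_that("split removes the cohort, rebuilds both consensuses", {
  set.seed(604)
  master <- random_test_dna(400)
  fam <- make_family(master, 40, list(list(del = c(200, 25), n = 30)))
  m <- fixture_model()
  prof <- consensus_column_profile(master, fam$seqs, m)
  cohort <- detect_cohort(prof$alignments, 400, min_support = 10)
  sp <- split_family(fam$seqs, ltrsubfam:::new_consensus_record("fam", master),
                     cohort, m, name = "fam_sub1")
  expect_equal(sort(c(sp$new$members, sp$remaining)),
               sort(names(fam$seqs)))
  # the new consensus lacks exactly the deleted block: one gap at the
  # planted interval when aligned to the parent consensus
  ps <- pairwise_stats(sp$new$consensus$sequence, master, m, "semiglobal")
  expect_lt(ps$percent_divergence, 1)
  expect_equal(sp$new$consensus$length, 375, tolerance = 0.01)
})

test_that("split error cases", {
  set.seed(605)
  m <- fixture_model()
  master <- random_test_dna(200)
  inst <- setNames(rep(master, 4), paste0("i", 1:4))
  co_all <- structure(list(members = names(inst),
                           feature_type = "shared_deletion",
                           consensus_interval = c(10, 30), support = 4,
                           dispersion = 0), class = "split_cohort")
  expect_error(split_family(inst, master, co_all, m), "cohort equals family")
  co_bad <- co_all; co_bad$members <- c("i1", "nope")
  expect_error(split_family(inst, master, co_bad, m), "not in the family")
  co_one <- co_all; co_one$members <- "i1"; co_one$support <- 1L
  sp <- split_family(inst, master, co_one, m)
  expect_true(sp$new$low_support)
})

test_that("iterate_splitting recovers planted subfamilies with high fidelity", {
  set.seed(606)
  master <- random_test_dna(450)
  fam <- make_family(master, 40,
                     list(list(del = c(150, 25), n = 30),
                          list(ins = c(320, 22), n = 20)),
                     n_sub = 35)
  m <- fixture_model()
  res <- iterate_splitting(fam$seqs, m, family_name = "fam")
  expect_length(res, 3)
  expect_true(attr(res, "converged"))
  # assignment partition invariant
  mem <- unlist(lapply(res, `[[`, "members"))
  expect_equal(sort(mem), sort(names(fam$seqs)))
  # greedy best matching of predicted groups to truth labels
  truth <- fam$labels
  prec <- rec <- numeric(0)
  for (sm in res) {
    tt <- table(truth[sm$members])
    best_lab <- names(tt)[which.max(tt)]
    prec <- c(prec, max(tt) / length(sm$members))
    rec <- c(rec, max(tt) / sum(truth == best_lab))
  }
  expect_true(all(prec >= 0.9))
  expect_true(all(rec >= 0.9))
})

test_that("a homogeneous family stays a single subfamily", {
  set.seed(607)
  master <- random_test_dna(400)
  fam <- make_family(master, 40, list())
  m <- fixture_model()
  res <- iterate_splitting(fam$seqs, m)
  expect_length(res, 1)
  expect_true(attr(res, "converged"))
})

test_that("assignment F1 does not improve as planted support shrinks", {
  set.seed(608)
  master <- random_test_dna(400)
  m <- fixture_model()
  f1_at <- function(n_cohort) {
    fam <- make_family(master, 50, list(list(del = c(180, 25),
                                             n = n_cohort)))
    res <- iterate_splitting(fam$seqs, m, min_support = 10)
    truth_pos <- names(fam$labels)[fam$labels == "cohort1"]
    pred <- res[vapply(res, function(x) !is.null(x$feature), TRUE)]
    if (length(pred) == 0) return(0)
    pred_pos <- pred[[1]]$members
    tp <- length(intersect(pred_pos, truth_pos))
    if (tp == 0) return(0)
    p <- tp / length(pred_pos); r <- tp / length(truth_pos)
    2 * p * r / (p + r)
  }
  f1s <- vapply(c(50, 30, 10), f1_at, 0)
  expect_true(all(diff(f1s) <= 1e-9))
  expect_gte(f1s[1], 0.9)
})

test_that("a hybrid-derived family re-splits into two models differing by one indel", {
  cfg <- simulation_config(seed = 610,
    family_lengths = c(famA = 453L, famB = 550L),
    bursts = data.frame(time = 10, family = c("famA", "famB"),
                        n_copies = 5),
    hybrid_events = list(list(time = 8, family_a = "famA",
                              family_b = "famB", breakpoint_a = 180,
                              breakpoint_b = 120, breakpoint_b2 = 420,
                              breakpoint_a2 = 280, n_copies = 30,
                              name = "aba_like")),
    subfamily_events = list(list(time = 6, type = "deletion",
                                 position = 300, length = 20,
                                 n_copies = 25, family = "aba_like",
                                 name = "subaba_like")),
    sub_rate = 0.01, background_length = 200)
  sim <- simulate_genomes(cfg)
  seqs <- sim_copy_sequences(sim)
  m <- fixture_model()
  ids <- sim$truth$copy_id[sim$truth$family == "aba_like"]
  res <- iterate_splitting(seqs[ids], m, family_name = "aba_rec")
  expect_length(res, 2)
  # the two consensuses differ by one ~20 bp indel feature near position
  # 300 and little else
  ps <- pairwise_stats(res[[1]]$consensus$sequence,
                       res[[2]]$consensus$sequence, m, "semiglobal")
  expect_lt(ps$percent_divergence, 2)
  expect_gt(ps$percent_indel, 2)
  feat <- res[[2]]$feature
  expect_true(feat$type %in% c("shared_deletion", "shared_insertion"))
  expect_lt(abs(feat$consensus_interval[1] - 300), 25)
  truth <- setNames(sim$truth$subfamily, sim$truth$copy_id)
  tt <- table(truth[res[[2]]$members])
  expect_gte(max(tt) / sum(tt), 0.9)
})

test_that("distinctness report flags identical consensuses and passes planted ones", {
  set.seed(609)
  m <- fixture_model()
  s <- random_test_dna(400)
  rep_id <- verify_subfamily_distinctness(c(a = s, b = s), m,
                                          min_score = 1000)
  expect_false(rep_id$distinct[1])
  expect_equal(rep_id$percent_divergence[1], 0)
  s2 <- mutate_seq(s, 0, del = c(150, 30))
  rep2 <- verify_subfamily_distinctness(c(a = s, b = s2), m,
                                        min_score = 1000)
  expect_true(rep2$percent_divergence[1] + rep2$percent_indel[1] > 2)
})
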