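# Instance selection, reference-anchored MSA, column filtering, distances
# and neighbor joining.

test_that("full-length selection follows the TG...CA rule strictly", {
  set.seed(801)
  mk <- function(len, head = "TG", tail = "CA")
    paste0(head, random_test_dna(len - 4), tail)
  inst <- c(keep1 = mk(400), short = mk(250), badhead = mk(400, head = "TA"),
            badtail = mk(400, tail = "CC"), keep2 = mk(301),
            boundary = mk(300))
  kept <- select_full_length(inst, 300)
  expect_equal(names(kept), c("keep1", "keep2")) # 300 bp is not > 300
  # hand filter of a random mixed set agrees
  pool <- setNames(vapply(1:20, function(i) {
    mk(sample(c(250, 320, 400), 1),
       head = sample(c("TG", "AA"), 1), tail = sample(c("CA", "GG"), 1))
  }, ""), paste0("p", 1:20))
  hand <- names(pool)[nchar(pool) > 300 &
                        substr(pool, 1, 2) == "TG" &
                        substr(pool, nchar(pool) - 1, nchar(pool)) == "CA"]
  expect_equal(names(select_full_length(pool, 300)), hand)
})

test_that("identical instances give a gap-free reference matrix", {
  set.seed(802)
  ref <- random_test_dna(200)
  inst <- setNames(rep(ref, 4), paste0("i", 1:4))
  m <- fixture_model()
  msa <- build_reference_msa(inst, ref, m)
  expect_equal(dim(msa), c(4, 200))
  expect_false(any(msa == "-"))
  expect_equal(attr(msa, "provenance"), 0:199)
})

test_that("one instance's 5-bp insertion becomes 5 insertion columns", {
  set.seed(803)
  ref <- random_test_dna(200)
  inst <- setNames(c(ref, mutate_seq(ref, 0, ins = c(100, 5)), ref),
                   c("a", "b", "c"))
  m <- fixture_model()
  msa <- build_reference_msa(inst, ref, m)
  expect_equal(ncol(msa), 205)
  ins_cols <- which(is.na(attr(msa, "provenance")))
  expect_length(ins_cols, 5)
  expect_true(all(msa["a", ins_cols] == "-"))
  expect_true(all(msa["c", ins_cols] == "-"))
  expect_true(all(msa["b", ins_cols] != "-"))
})

test_that("a planted cohort deletion shows as a shared gap block", {
  set.seed(804)
  ref <- random_test_dna(300)
  founder <- mutate_seq(ref, 0, del = c(120, 30))
  inst <- c(setNames(vapply(1:5, function(i) mutate_seq(ref, 10), ""),
                     paste0("r", 1:5)),
            setNames(vapply(1:5, function(i) mutate_seq(founder, 10), ""),
                     paste0("d", 1:5)))
  m <- fixture_model()
  msa <- build_reference_msa(inst, ref, m)
  pr <- attr(msa, "provenance")
  block <- which(pr %in% 125:145)
  gap_frac_cohort <- mean(msa[paste0("d", 1:5), block] == "-")
  gap_frac_rest <- mean(msa[paste0("r", 1:5), block] == "-")
  expect_gt(gap_frac_cohort, 0.9)
  expect_lt(gap_frac_rest, 0.1)
})

test_that("column filtering follows the at-least-gt rule and is idempotent", {
  set.seed(805)
  mat <- matrix(sample(c("A", "C", "G", "T"), 100 * 50, replace = TRUE),
                100, 50)
  mat[, 10] <- "-"                # 0 non-gap: dropped at any gt > 0
  mat[, 20] <- c("A", rep("-", 99)) # exactly 1% non-gap: kept at gt = 0.01
  f <- filter_columns(mat, 0.01)
  expect_equal(ncol(f), 49)
  expect_true(any(apply(f, 2, function(cl) sum(cl != "-") == 1)))
  expect_equal(filter_columns(f, 0.01), f)
  # brute-force recount oracle
  keep_hand <- which(colSums(mat != "-") / nrow(mat) >= 0.01)
  expect_equal(ncol(f), length(keep_hand))
})

test_that("distances: p-distance definition and K2P closed form", {
  m <- matrix(c(strsplit("ACGTACGTAC", "")[[1]],
                strsplit("ACGTACGTAC", "")[[1]]), 2, 10, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(msa_distances(m, "p")$d["a", "b"], 0)
  # 2 differences in 100 comparable columns
  s <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  s2 <- s; s2[3] <- "A"; s2[7] <- "C"
  mm <- rbind(a = s, b = s2)
  expect_equal(msa_distances(mm, "p")$d["a", "b"], 0.02)
  # K2P: plant known transition (P) and transversion (Q) fractions
  s3 <- s
  s3[seq(1, 40, by = 4)] <- "G"   # A->G transitions: 10 of 100
  s3[seq(2, 20, by = 4)] <- "A"   # C->A transversions: 5 of 100
  mk <- rbind(a = s, b = s3)
  P <- 10 / 100; Q <- 5 / 100
  hand <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(msa_distances(mk, "kimura2p")$d["a", "b"], hand,
               tolerance = 1e-9)
})

test_that("pairs with no comparable columns are flagged undefined", {
  mm <- rbind(a = c("A", "C", "-", "-"), b = c("-", "-", "G", "T"),
              c = c("A", "C", "G", "T"))
  d <- msa_distances(mm, "p")
  expect_true(d$undefined["a", "b"])
  expect_false(d$undefined["a", "c"])
})

test_that("neighbor joining: 3-taxon closed form and additive recovery", {
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nt <- nj_tree(d3)
  pd <- ape::cophenetic.phylo(nt$tree)
  expect_equal(pd["a", "b"], 5)
  expect_equal(pd["a", "c"], 9)
  expect_equal(pd["b", "c"], 10)
  # additive 5-taxon matrix: NJ reproduces all path lengths exactly,
  # which pins the generating topology
  tr <- ape::read.tree(text = "((a:2,b:3):4,(c:1,d:2):3,e:6);")
  dm <- ape::cophenetic.phylo(tr)
  nt5 <- nj_tree(dm)
  pd5 <- ape::cophenetic.phylo(nt5$tree)[rownames(dm), colnames(dm)]
  expect_equal(pd5, dm, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr), nt5$tree),
               structure(0, names = NULL), ignore_attr = TRUE)
  # newick round-trips
  expect_s3_class(ape::read.tree(text = nt5$newick), "phylo")
})

test_that("negative NJ branch lengths are clamped, deficit to the sister", {
  set.seed(806)
  # a noisy matrix known to produce negative NJ edges
  d <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 0.5, 6, 6, 0.5, 0),
              4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 8 # force imbalance
  d["b", "a"] <- 8
  nt <- nj_tree(d)
  expect_true(all(nt$tree$edge.length >= 0))
})

test_that("subfamily cohesion is 1 for well-separated clades", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):5,(b1:1,b2:1):5);")
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(subfamily_cohesion(tr, lab)$cohesion, 1)
  lab2 <- c(a1 = "A", a2 = "B", b1 = "A", b2 = "B")
  expect_equal(subfamily_cohesion(tr, lab2)$cohesion, 0)
})
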