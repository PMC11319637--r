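# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately avoid the package's own code paths: Biostrings
# supplies reference alignment scores, and partition instances are checked
# by exhaustive enumeration over assignment vectors.

# hand-score an alignment path from its gapped strings under a model
# (first gap char of a run costs gap_open, later ones gap_extend)
hand_score_path <- function(aln, model) {
  q <- strsplit(aln$aln_query, "", fixed = TRUE)[[1]]
  t <- strsplit(aln$aln_target, "", fixed = TRUE)[[1]]
  s <- model$subst_scores
  sc <- 0
  in_gap <- FALSE
  for (i in seq_along(q)) {
    if (q[i] == "-" || t[i] == "-") {
      sc <- sc - if (in_gap) model$gap_extend else model$gap_open
      in_gap <- TRUE
    } else {
      sc <- sc + s[t[i], q[i]]
      in_gap <- FALSE
    }
  }
  sc
}

# Biostrings local-alignment score oracle with the same gap convention
# (ours: open + (L-1) * extend; Biostrings: opening + L * extension)
biostrings_local_score <- function(query, target, model) {
  s <- model$subst_scores
  mat <- matrix(0, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  nsc <- min(s[row(s) != col(s)])
  mat[, ] <- nsc
  mat[1:4, 1:4] <- t(s)
  pa <- Biostrings::pairwiseAlignment(
    query, target, substitutionMatrix = mat,
    gapOpening = model$gap_open - model$gap_extend,
    gapExtension = model$gap_extend, type = "local")
  Biostrings::score(pa)
}

# mutate a sequence: n substitutions at distinct positions (always to a
# different base), used to build fixtures without the simulator
mutate_seq <- function(s, n_sub = 0, del = NULL, ins = NULL) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    pos <- sample(length(v), n_sub)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  if (!is.null(del)) v <- v[-(del[1]:(del[1] + del[2] - 1L))]
  if (!is.null(ins))
    v <- append(v, sample(c("A", "C", "G", "T"), ins[2], replace = TRUE),
                after = ins[1])
  paste(v, collapse = "")
}

# build an ltr_aln object directly from gapped strings (for count/stat
# fixtures with known tallies)
make_aln <- function(aln_query, aln_target, consensus_name = "cons",
                     strand = "+", g_start = 0L, c_start = 0L, score = 0L) {
  q <- strsplit(aln_query, "", fixed = TRUE)[[1]]
  t <- strsplit(aln_target, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(t))
  op <- ifelse(t == "-", 2L, ifelse(q == "-", 3L, 1L))
  r <- rle(op)
  structure(list(consensus_name = consensus_name, strand = strand,
                 score = score,
                 g_start = g_start, g_end = g_start + sum(q != "-"),
                 c_start = c_start, c_end = c_start + sum(t != "-"),
                 ops = r$values, lens = r$lengths,
                 aln_query = aln_query, aln_target = aln_target),
            class = "ltr_aln")
}

# --- brute-force partition oracle -----------------------------------------
# Independent truncated-piece score: walk the alignment's gapped strings,
# keep columns whose genome position falls in [a, b) plus consensus-gap
# runs strictly between kept positions, and re-run the affine gap
# decomposition from scratch on the surviving columns.
oracle_piece_score <- function(aln, model, a, b) {
  q <- strsplit(aln$aln_query, "", fixed = TRUE)[[1]]
  t <- strsplit(aln$aln_target, "", fixed = TRUE)[[1]]
  gpos <- rep(NA_integer_, length(q))
  gi <- aln$g_start
  for (i in seq_along(q)) if (q[i] != "-") { gpos[i] <- gi; gi <- gi + 1L }
  keep <- !is.na(gpos) & gpos >= a & gpos < b
  # a consensus-gap column survives iff the genome-consuming columns
  # immediately flanking its run are both kept
  gcols <- which(q != "-")
  for (i in which(q == "-")) {
    lft <- gcols[gcols < i]
    rgt <- gcols[gcols > i]
    if (length(lft) && length(rgt) && keep[max(lft)] && keep[min(rgt)])
      keep[i] <- TRUE
  }
  if (!any(keep)) return(0)
  qs <- q[keep]; ts <- t[keep]
  sc <- 0; in_gap <- FALSE
  for (i in seq_along(qs)) {
    if (qs[i] == "-" || ts[i] == "-") {
      sc <- sc - if (in_gap) model$gap_extend else model$gap_open
      in_gap <- TRUE
    } else {
      sc <- sc + model$subst_scores[ts[i], qs[i]]
      in_gap <- FALSE
    }
  }
  sc
}

# exhaustive best objective over all per-position assignments
oracle_partition_best <- function(candidates, model, switch_penalty) {
  lo <- min(vapply(candidates, `[[`, 0L, "g_start"))
  hi <- max(vapply(candidates, `[[`, 0L, "g_end"))
  pos <- lo:(hi - 1L)
  np <- length(pos)
  alpha <- lapply(pos, function(p) {
    c(0L, which(vapply(candidates, function(a)
      a$g_start <= p && p < a$g_end, TRUE)))
  })
  # piece score lookup per candidate and genome range
  ptab <- list()
  for (ci in seq_along(candidates)) {
    a <- candidates[[ci]]
    tab <- matrix(NA_real_, np, np)
    for (i in seq_len(np)) for (j in i:np) {
      s <- pos[i]; e <- pos[j] + 1L
      if (s >= a$g_start && e <= a$g_end)
        tab[i, j] <- oracle_piece_score(a, model, s, e)
    }
    ptab[[ci]] <- tab
  }
  grid <- do.call(expand.grid, c(alpha, KEEP.OUT.ATTRS = FALSE))
  best <- 0
  for (r in seq_len(nrow(grid))) {
    v <- as.integer(grid[r, ])
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- rl$values != 0L
    if (!any(sel)) next
    sc <- 0
    ok <- TRUE
    for (u in which(sel)) {
      pv <- ptab[[rl$values[u]]][starts[u], ends[u]]
      if (is.na(pv)) { ok <- FALSE; break }
      sc <- sc + pv
    }
    if (!ok) next
    sc <- sc - switch_penalty * (sum(sel) - 1L)
    if (sc > best) best <- sc
  }
  best
}

# random small partition instance: a genome window with 2-4 overlapping
# synthetic candidate alignments, optionally containing gap columns
# (insertion and deletion runs are never adjacent, as in real DP output)
random_partition_instance <- function(span = 6L, n_cand = 2L, model,
                                      gap_prob = 0.3) {
  genome <- random_test_dna(span)
  cands <- list()
  for (ci in seq_len(n_cand)) {
    gs <- sample(0:(span - 2L), 1)
    ge <- sample((gs + 1L):span, 1)
    gchars <- strsplit(substr(genome, gs + 1L, ge), "", fixed = TRUE)[[1]]
    qcol <- character(0); tcol <- character(0)
    for (u in seq_along(gchars)) {
      if (u > 1 && stats::runif(1) < gap_prob / 2) { # consensus-gap column
        qcol <- c(qcol, "-"); tcol <- c(tcol, random_test_dna(1))
      }
      qcol <- c(qcol, gchars[u])
      tcol <- c(tcol, if (stats::runif(1) < 0.25) random_test_dna(1)
                      else gchars[u])
    }
    # maybe one insertion column (genome base vs gap), kept away from the
    # ends and from deletion columns
    if (length(qcol) > 2 && stats::runif(1) < gap_prob / 2) {
      ks <- seq(2L, length(qcol) - 1L)
      k <- ks[sample.int(length(ks), 1)]
      if (qcol[k] != "-" && qcol[k - 1] != "-" && qcol[k + 1] != "-")
        tcol[k] <- "-"
    }
    cands[[ci]] <- make_aln(paste(qcol, collapse = ""),
                            paste(tcol, collapse = ""),
                            consensus_name = paste0("c", ci), g_start = gs)
  }
  list(genome = genome, candidates = cands)
}

random_test_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# independent single-linkage clustering by transitive closure of the
# "within tol on every coordinate" relation
oracle_single_linkage <- function(vecs, tol) {
  n <- nrow(vecs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- max(abs(vecs[i, ] - vecs[j, ])) <= tol
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && lab[j] > lab[i]) { lab[j] <- lab[i]; changed <- TRUE }
    if (!changed) break
  }
  as.integer(factor(lab))
}

# small trained-like model with realistic score magnitudes, built from
# synthetic counts (fast, no training loop)
fixture_model <- function() {
  cnt <- matrix(60L, 4, 4, dimnames = list(c("A","C","G","T"),
                                           c("A","C","G","T")))
  diag(cnt) <- 2000L
  model_from_counts(list(subst = cnt, gap_open = 30L, gap_extend = 60L,
                         aligned_cols = 8480L))
}
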