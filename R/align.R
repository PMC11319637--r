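# R-facing wrappers over the affine-gap DP engine in src/align.cpp.
#
# Alignment objects ("ltr_aln") store: consensus_name, strand, score,
# g_start/g_end (query/genome coordinates, 0-based half-open, plus strand),
# c_start/c_end (forward-consensus coordinates), the run-length encoded path
# (ops/lens: 1 = aligned pair, 2 = query base vs gap, 3 = gap vs target
# base, in query left-to-right orientation) and the gapped aligned strings
# aln_query / aln_target (target reverse-complemented for minus strand).

# 5x5 score matrix for the engine: rows = query base, cols = target base;
# N (code 4) scores the worst off-diagonal value so it never acts as a match.
.sub5 <- function(model) {
  s <- model$subst_scores
  n_sc <- min(s[row(s) != col(s)])
  m <- matrix(as.integer(n_sc), 5, 5)
  m[1:4, 1:4] <- t(s) # engine indexes [query, target]; s is [consensus, instance]
  m
}

.hit_to_aln <- function(hit, qseq, tseq, consensus_name, strand, tlen_fwd) {
  qs <- substring(qseq, hit$s1_start + 1L, hit$s1_end)
  ts <- substring(tseq, hit$s2_start + 1L, hit$s2_end)
  qv <- strsplit(qs, "", fixed = TRUE)[[1]]
  tv <- strsplit(ts, "", fixed = TRUE)[[1]]
  opv <- expand_ops(hit$ops, hit$lens)
  nq <- cumsum(opv != 3L)
  nt <- cumsum(opv != 2L)
  aq <- ifelse(opv == 3L, "-", qv[nq])
  at <- ifelse(opv == 2L, "-", tv[nt])
  if (strand == "+") {
    c_start <- hit$s2_start; c_end <- hit$s2_end
  } else {
    c_start <- tlen_fwd - hit$s2_end; c_end <- tlen_fwd - hit$s2_start
  }
  structure(list(consensus_name = consensus_name, strand = strand,
                 score = hit$score,
                 g_start = hit$s1_start, g_end = hit$s1_end,
                 c_start = c_start, c_end = c_end,
                 ops = hit$ops, lens = hit$lens,
                 aln_query = paste(aq, collapse = ""),
                 aln_target = paste(at, collapse = "")),
            class = "ltr_aln")
}

#' @export
print.ltr_aln <- function(x, ...) {
  cat(sprintf("ltr_aln %s%s score=%d query[%d,%d) cons[%d,%d)\n",
              x$consensus_name, x$strand, x$score,
              x$g_start, x$g_end, x$c_start, x$c_end))
  invisible(x)
}

#' Best pairwise alignment of two sequences
#'
#' @param query,target sequences (character, A/C/G/T/N).
#' @param model a `scoring_model`.
#' @param mode `"local"` (Smith-Waterman style) or `"semiglobal"` (free end
#'   gaps on both sequences, best path reaching a far edge).
#' @param min_score hits below this score are discarded (local mode).
#' @param target_name stored as `consensus_name` in the result.
#' @return an `ltr_aln` object, or `NULL` if nothing clears `min_score`.
#' @export
align_pair <- function(query, target, model, mode = c("local", "semiglobal"),
                       min_score = 1L, target_name = "target") {
  mode <- match.arg(mode)
  q <- encode_dna(query); t <- encode_dna(target)
  md <- if (mode == "local") 0L else 1L
  ms <- if (mode == "local") as.integer(min_score) else -1000000L
  hits <- .align_core(q, t, .sub5(model), model$gap_open, model$gap_extend,
                      ms, md, 1L)
  if (length(hits) == 0L) return(NULL)
  .hit_to_aln(hits[[1]], query, target, target_name, "+", nchar(target))
}

#' All non-overlapping local alignments of a consensus to a genomic window
#'
#' Smith-Waterman-style affine-gap local alignment on both strands. Local
#' maxima are recovered by iterative masking of the genome footprint of each
#' reported hit; hits from the two strands are merged greedily by score so
#' that no genome base appears in two hits of the same consensus.
#'
#' @param genome_window genomic sequence (character).
#' @param consensus consensus sequence (character).
#' @param model a `scoring_model`.
#' @param min_score minimum reported alignment score.
#' @param consensus_name name recorded in the alignments.
#' @param strand `"both"`, `"+"` or `"-"`.
#' @param max_hits cap on reported hits per strand.
#' @return list of `ltr_aln`, sorted by genome start; minus-strand hits carry
#'   forward-consensus coordinates.
#' @export
local_align <- function(genome_window, consensus, model, min_score,
                        consensus_name = "consensus", strand = "both",
                        max_hits = 1000L) {
  if (nchar(genome_window) < 10L) {
    warning("window shorter than 10 bp; returning no alignments")
    return(list())
  }
  g <- encode_dna(genome_window)
  sub <- .sub5(model)
  out <- list()
  tlen <- nchar(consensus)
  for (st in intersect(if (strand == "both") c("+", "-") else strand,
                       c("+", "-"))) {
    tseq <- if (st == "+") consensus else revcomp(consensus)
    tenc <- encode_dna(tseq)
    # non-overlapping local maxima by divide and conquer: find the best
    # hit, then recurse into the flanks. Equivalent to iterative masking
    # (no local alignment can cross a claimed genome interval) but scans
    # each region O(log hits) times instead of O(hits).
    hits <- list()
    stack <- list(c(0L, length(g)))
    while (length(stack) && length(hits) < max_hits) {
      rng <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (rng[2] - rng[1] < 10L) next
      res <- .align_core(g[(rng[1] + 1L):rng[2]], tenc, sub,
                         model$gap_open, model$gap_extend,
                         as.integer(min_score), 0L, 1L)
      if (length(res) == 0L) next
      h <- res[[1]]
      h$s1_start <- h$s1_start + rng[1]
      h$s1_end <- h$s1_end + rng[1]
      hits[[length(hits) + 1L]] <- h
      stack[[length(stack) + 1L]] <- c(rng[1], h$s1_start)
      stack[[length(stack) + 1L]] <- c(h$s1_end, rng[2])
    }
    for (h in hits)
      out[[length(out) + 1L]] <- .hit_to_aln(h, genome_window, tseq,
                                             consensus_name, st, tlen)
  }
  if (length(out) == 0L) return(out)
  # greedy non-overlap across strands, by score then leftmost
  o <- order(vapply(out, `[[`, 0, "score"),
             -vapply(out, `[[`, 0L, "g_start"), decreasing = TRUE)
  kept <- list()
  occ <- matrix(0L, 0, 2)
  for (i in o) {
    a <- out[[i]]
    if (nrow(occ) == 0L ||
        all(a$g_end <= occ[, 1] | a$g_start >= occ[, 2])) {
      kept[[length(kept) + 1L]] <- a
      occ <- rbind(occ, c(a$g_start, a$g_end))
    }
  }
  kept[order(vapply(kept, `[[`, 0L, "g_start"))]
}

#' Divergence and indel fractions of one alignment
#'
#' Percent divergence = mismatched aligned columns / ungapped aligned columns
#' x 100 (N columns excluded); percent indel = gap characters / total
#' alignment columns x 100.
#' @param aln an `ltr_aln`.
#' @return list with `percent_divergence`, `percent_indel`, `n_columns`,
#'   `n_matches`, `n_mismatches`, `n_gap_chars`.
#' @export
alignment_stats <- function(aln) {
  q <- encode_gapped(aln$aln_query)
  t <- encode_gapped(aln$aln_target)
  ncol_all <- length(q)
  mcol <- q >= 0L & t >= 0L & q < 4L & t < 4L
  mm <- sum(mcol & q != t)
  mt <- sum(mcol & q == t)
  gaps <- sum(q < 0L) + sum(t < 0L)
  list(percent_divergence = if (sum(mcol)) 100 * mm / sum(mcol) else 0,
       percent_indel = if (ncol_all) 100 * gaps / ncol_all else 0,
       n_columns = ncol_all, n_matches = mt, n_mismatches = mm,
       n_gap_chars = gaps)
}
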