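# Competitive genome partition: given candidate alignments of several
# consensuses to one genomic window, choose (possibly truncated) candidate
# pieces maximising total truncated-piece score minus a penalty per adjacent
# pair of pieces from different parent alignments, with no genome base
# covered twice. This is the score-based surrogate for probabilistic
# repeat-annotation splitting, and is what exposes hybrid elements.

# Precompute per-genome-position increments for one alignment:
#  inc[i]       score added when the piece extends through position i
#  start_inc[i] score added when a piece *starts* at i (gap runs re-opened)
#  bridge[i]    cost of consensus-deletion columns immediately before i,
#               charged only when extending i-1 -> i within one piece
# plus per-column bookkeeping used to rebuild truncated consensus intervals.
.prep_candidate <- function(aln, model) {
  opv <- expand_ops(aln$ops, aln$lens)
  q <- encode_gapped(aln$aln_query)
  t <- encode_gapped(aln$aln_target)
  n <- aln$g_end - aln$g_start
  go <- model$gap_open; ge <- model$gap_extend
  sub <- .sub5(model)
  inc <- numeric(n); start_inc <- numeric(n); bridge <- numeric(n)
  gpos <- integer(length(opv)); cpos <- integer(length(opv))
  gi <- 0L; ci <- 0L
  pend_d <- 0
  k <- 1L
  for (r in seq_along(aln$ops)) {
    op <- aln$ops[r]; len <- aln$lens[r]
    if (op == 1L) { # aligned pairs
      for (u in seq_len(len)) {
        gi <- gi + 1L; ci <- ci + 1L
        sc <- sub[q[k] + 1L, t[k] + 1L]
        inc[gi] <- sc
        start_inc[gi] <- sc
        if (u == 1L && pend_d > 0) {
          bridge[gi] <- -(go + (pend_d - 1) * ge)
          pend_d <- 0
        }
        gpos[k] <- gi; cpos[k] <- ci
        k <- k + 1L
      }
    } else if (op == 2L) { # query base vs gap
      for (u in seq_len(len)) {
        gi <- gi + 1L
        inc[gi] <- if (u == 1L) -go else -ge
        start_inc[gi] <- -go
        gpos[k] <- gi; cpos[k] <- NA_integer_
        k <- k + 1L
      }
    } else { # gap vs consensus base
      pend_d <- len
      for (u in seq_len(len)) {
        ci <- ci + 1L
        gpos[k] <- NA_integer_; cpos[k] <- ci
        k <- k + 1L
      }
    }
  }
  # forward-consensus coordinate of each consumed consensus base
  cfwd <- if (aln$strand == "+") aln$c_start + cpos - 1L
          else aln$c_end - cpos
  list(aln = aln, gs = aln$g_start, ge = aln$g_end,
       inc = inc, start_inc = start_inc, bridge = bridge,
       col_gpos = gpos + aln$g_start - 1L, col_cfwd = cfwd,
       col_op = opv)
}

# truncated-piece score and consensus interval for genome range [a, b)
.piece_info <- function(pc, a, b) {
  sel_g <- !is.na(pc$col_gpos) & pc$col_gpos >= a & pc$col_gpos < b
  # D columns survive when both flanking genome positions are inside
  gseq <- pc$col_gpos
  lastg <- gseq
  for (i in seq_along(lastg)) if (is.na(lastg[i]) && i > 1) lastg[i] <- lastg[i - 1]
  nextg <- gseq
  for (i in rev(seq_along(nextg))) if (is.na(nextg[i]) && i < length(nextg))
    nextg[i] <- nextg[i + 1]
  sel_d <- pc$col_op == 3L & !is.na(lastg) & !is.na(nextg) &
    lastg >= a & lastg < b & nextg >= a & nextg < b
  sel <- sel_g | sel_d
  cp <- pc$col_cfwd[sel & !is.na(pc$col_cfwd)]
  i0 <- a - pc$gs + 1L; i1 <- b - pc$gs
  sc <- pc$start_inc[i0]
  if (i1 > i0) sc <- sc + sum(pc$inc[(i0 + 1L):i1]) +
      sum(pc$bridge[(i0 + 1L):i1])
  list(score = sc,
       c_start = if (length(cp)) min(cp) else NA_integer_,
       c_end = if (length(cp)) max(cp) + 1L else NA_integer_)
}

#' Partition candidate alignments into non-overlapping annotation segments
#'
#' Dynamic program over genome positions choosing, at each base, one covering
#' candidate alignment or none, maximising the sum of truncated-piece scores
#' (each piece rescored from its surviving alignment columns, gap runs
#' re-opened where truncation splits them) minus `switch_penalty` for every
#' consecutive pair of assigned pieces. Charging the penalty between
#' same-parent pieces as well keeps the optimum from shredding one alignment
#' into fragments around isolated mismatches; switches between different
#' consensuses are what the penalty prices, and hybrids emerge when a
#' competing consensus outscores it. Among equal-score solutions fewer
#' pieces are preferred.
#'
#' @param candidates list of `ltr_aln` on one genomic window.
#' @param model the `scoring_model` the candidates were produced with.
#' @param switch_penalty non-negative cost per adjacent different-parent
#'   piece pair; default twice the model gap-open cost.
#' @param min_segment_length segments shorter than this are dropped from the
#'   output (sub-seed fragments are noise).
#' @return data.frame of segments sorted by genome start: genome_start,
#'   genome_end, consensus_name, consensus_start, consensus_end, strand,
#'   segment_score, parent (index into `candidates`), plus attribute
#'   `total_score` (the optimised objective before length filtering).
#' @export
partition_alignments <- function(candidates, model,
                                 switch_penalty = 2 * model$gap_open,
                                 min_segment_length = 20L) {
  if (length(switch_penalty) != 1L || is.na(switch_penalty) ||
      switch_penalty < 0)
    stop("configuration error: switch_penalty must be a single ",
         "non-negative number")
  empty <- data.frame(genome_start = integer(), genome_end = integer(),
                      consensus_name = character(),
                      consensus_start = integer(), consensus_end = integer(),
                      strand = character(), segment_score = numeric(),
                      parent = integer(), stringsAsFactors = FALSE)
  attr(empty, "total_score") <- 0
  if (length(candidates) == 0L) return(empty)
  pcs <- lapply(candidates, .prep_candidate, model = model)
  k <- length(pcs)
  lo <- min(vapply(pcs, `[[`, 0L, "gs"))
  hi <- max(vapply(pcs, `[[`, 0L, "ge"))
  pos <- lo:(hi - 1L)
  Tn <- length(pos)
  eps <- 1e-6 # tie-break: fewer switches
  # states: in-candidate 1..k; gap with last-parent 0..k
  vin <- rep(-Inf, k)
  vgap <- c(0, rep(-Inf, k)) # index 1 = "no piece yet", 1+c = last parent c
  tb_in <- matrix(NA_integer_, Tn, k)   # predecessor code for in-states
  tb_gap <- matrix(NA_integer_, Tn, k + 1) # 0 = stay gap, c = close piece c
  # predecessor codes for in-states: 0 = extend; positive c = start after
  # piece c; negative -(l+1) = start from gap state with last-parent l
  covers <- lapply(pcs, function(p) p$gs <= pos & pos < p$ge)
  for (ti in seq_len(Tn)) {
    i <- pos[ti]
    vin_new <- rep(-Inf, k)
    vgap_new <- vgap
    for (l in 0:k) {
      cand <- if (l == 0) -Inf else vin[l]
      if (cand > vgap[l + 1]) { vgap_new[l + 1] <- cand; tb_gap[ti, l + 1] <- l }
      else tb_gap[ti, l + 1] <- 0L
    }
    for (c in seq_len(k)) {
      if (!covers[[c]][ti]) next
      p <- pcs[[c]]
      ii <- i - p$gs + 1L
      best <- -Inf; pred <- NA_integer_
      if (ii > 1L && is.finite(vin[c])) {
        v <- vin[c] + p$inc[ii] + p$bridge[ii]
        if (v > best) { best <- v; pred <- 0L }
      }
      for (l in 0:k) {
        if (!is.finite(vgap[l + 1])) next
        pen <- if (l == 0) 0 else switch_penalty + eps
        v <- vgap[l + 1] - pen + p$start_inc[ii]
        if (v > best) { best <- v; pred <- -(l + 1L) }
      }
      # piece of d ends at i-1, piece of c starts at i (adjacent pieces);
      # d == c excluded: a contiguous same-candidate run is one piece
      for (d in seq_len(k)) {
        if (d == c || !is.finite(vin[d])) next
        v <- vin[d] - switch_penalty - eps + p$start_inc[ii]
        if (v > best) { best <- v; pred <- d }
      }
      vin_new[c] <- best
      tb_in[ti, c] <- pred
    }
    vin <- vin_new
    vgap <- vgap_new
  }
  fin <- c(vgap, vin)
  bi <- which.max(fin)
  # traceback: assignment per position (0 = none)
  assign <- integer(Tn)
  if (bi <= k + 1) { st_type <- "gap"; st <- bi - 1L } else {
    st_type <- "in"; st <- bi - (k + 1L)
  }
  ti <- Tn
  while (ti >= 1L) {
    if (st_type == "gap") {
      prev <- tb_gap[ti, st + 1]
      if (!is.na(prev) && prev > 0L) { st_type <- "in"; st <- prev
        # the close happened entering ti, so position ti is already gap;
        # the in-state applies to ti - 1
      }
      ti <- ti - 1L
    } else {
      assign[ti] <- st
      pred <- tb_in[ti, st]
      if (is.na(pred)) break
      if (pred == 0L) { ti <- ti - 1L }
      else if (pred > 0L) { st <- pred; ti <- ti - 1L }
      else { st_type <- "gap"; st <- -pred - 1L; ti <- ti - 1L }
    }
  }
  # pieces = maximal runs of equal nonzero assignment
  segs <- list()
  r <- rle(assign)
  endi <- cumsum(r$lengths)
  starti <- endi - r$lengths + 1L
  for (u in seq_along(r$values)) {
    c <- r$values[u]
    if (c == 0L) next
    a <- pos[starti[u]]; b <- pos[endi[u]] + 1L
    info <- .piece_info(pcs[[c]], a, b)
    segs[[length(segs) + 1L]] <-
      data.frame(genome_start = a, genome_end = b,
                 consensus_name = pcs[[c]]$aln$consensus_name,
                 consensus_start = info$c_start, consensus_end = info$c_end,
                 strand = pcs[[c]]$aln$strand,
                 segment_score = info$score, parent = c,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty
  out <- out[order(out$genome_start), , drop = FALSE]
  rownames(out) <- NULL
  # clean objective value (without tie-break epsilons): piece scores minus
  # switch penalty per consecutive piece pair
  total <- sum(out$segment_score)
  if (nrow(out) > 1) total <- total - switch_penalty * (nrow(out) - 1)
  out <- out[out$genome_end - out$genome_start >= min_segment_length, ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_score") <- total
  out
}

#' Annotate a genome by competitive alignment to a consensus library
#'
#' Aligns every consensus to overlapping windows of the genome with
#' [local_align()] and resolves competing candidates with
#' [partition_alignments()], so that no genome base is assigned to more than
#' one consensus base.
#'
#' @param genome genome sequence (character).
#' @param consensus_library named character vector of consensus sequences.
#' @param model a `scoring_model`.
#' @param min_score minimum candidate alignment score; default corresponds
#'   to roughly 30 matched bases under the model.
#' @param switch_penalty see [partition_alignments()].
#' @param window,overlap window length and overlap (bp); the overlap should
#'   exceed the longest expected element so no element is split.
#' @param min_segment_length shortest reported segment.
#' @return data.frame of annotation segments (as [partition_alignments()]),
#'   genome-wide coordinates, no two segments overlapping.
#' @export
annotate_genome <- function(genome, consensus_library, model,
                            min_score = NULL,
                            switch_penalty = 2 * model$gap_open,
                            window = 50000L, overlap = 2000L,
                            min_segment_length = 20L) {
  if (length(consensus_library) == 0L) stop("empty consensus library")
  if (is.null(names(consensus_library)))
    stop("consensus_library must be named")
  if (is.null(min_score))
    min_score <- round(30 * mean(diag(model$subst_scores)))
  n <- nchar(genome)
  starts <- seq(0L, max(0L, n - 1L), by = max(1L, window - overlap))
  starts <- starts[starts == 0L | starts + overlap < n]
  all_segs <- list()
  for (ws in starts) {
    we <- min(n, ws + window)
    win <- substr(genome, ws + 1L, we)
    cands <- list()
    for (cn in names(consensus_library)) {
      hits <- local_align(win, consensus_library[[cn]], model,
                          min_score = min_score, consensus_name = cn)
      for (h in hits) {
        h$g_start <- h$g_start + ws
        h$g_end <- h$g_end + ws
        cands[[length(cands) + 1L]] <- h
      }
    }
    if (length(cands) == 0L) next
    seg <- partition_alignments(cands, model, switch_penalty,
                                min_segment_length)
    if (nrow(seg)) all_segs[[length(all_segs) + 1L]] <- seg
  }
  if (length(all_segs) == 0L)
    return(partition_alignments(list(), model, switch_penalty,
                                min_segment_length))
  segs <- do.call(rbind, all_segs)
  segs$parent <- NULL
  # window-overlap duplicates: same genome interval + consensus -> keep one;
  # residual cross-window overlaps resolved greedily by score
  segs <- segs[!duplicated(segs[c("genome_start", "genome_end",
                                  "consensus_name")]), , drop = FALSE]
  segs <- segs[order(-segs$segment_score), , drop = FALSE]
  keep <- logical(nrow(segs))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(segs))) {
    if (all(segs$genome_end[i] <= occ_s | segs$genome_start[i] >= occ_e)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, segs$genome_start[i])
      occ_e <- c(occ_e, segs$genome_end[i])
    }
  }
  segs <- segs[keep, , drop = FALSE]
  segs <- segs[order(segs$genome_start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Write annotation segments as BED6+
#'
#' Columns: chrom, start, end, name (consensus), score, strand, plus
#' consensus_start, consensus_end.
#' @param segments data.frame from [annotate_genome()].
#' @param path output file.
#' @param chrom chromosome name to write.
#' @return invisibly, `path`.
#' @export
write_annotation_bed <- function(segments, path, chrom = "chr1") {
  bed <- data.frame(chrom = chrom, start = segments$genome_start,
                    end = segments$genome_end,
                    name = segments$consensus_name,
                    score = round(segments$segment_score),
                    strand = segments$strand,
                    consensus_start = segments$consensus_start,
                    consensus_end = segments$consensus_end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
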