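# Consensus building: seed from the highest-scoring instance of an
# all-vs-all comparison, then refine by per-column majority over
# instance-to-consensus alignments until the sequence stops changing.

new_consensus_record <- function(name, sequence, source_id = NA_character_,
                                 rounds = 0L, support = NULL,
                                 converged = NA) {
  structure(list(name = name, sequence = toupper(sequence),
                 length = nchar(sequence), source_id = source_id,
                 rounds = rounds,
                 support = support %||% rep(0L, nchar(sequence)),
                 converged = converged),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("consensus_record %s: %d bp, seeded from %s, %d round(s)%s\n",
              x$name, x$length, x$source_id, x$rounds,
              if (isFALSE(x$converged)) " (not converged)" else ""))
  invisible(x)
}

#' Seed a consensus from the highest-scoring instance
#'
#' All-vs-all local alignment of the instances; pairwise scores below
#' `min_score` are discarded and the instance maximising the sum of kept
#' scores to all others becomes the seed. Ties break deterministically to
#' the earlier instance in input order. This mirrors self-comparison with a
#' high minimum score cutoff followed by picking the top-scoring instance.
#'
#' @param instances named character vector (>= 2 sequences).
#' @param model a `scoring_model`.
#' @param min_score pairwise alignments below this score are ignored.
#' @param name name given to the consensus.
#' @return a `consensus_record`.
#' @export
seed_consensus <- function(instances, model, min_score = 2000,
                           name = "consensus") {
  if (length(instances) < 2L)
    stop("need at least 2 instances to seed a consensus")
  if (is.null(names(instances)))
    names(instances) <- paste0("inst", seq_along(instances))
  n <- length(instances)
  enc <- lapply(instances, encode_dna)
  sub <- .sub5(model)
  tot <- numeric(n)
  any_pair <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sc <- .align_score(enc[[i]], enc[[j]], sub, model$gap_open,
                       model$gap_extend)
    if (sc >= min_score) {
      any_pair <- TRUE
      tot[i] <- tot[i] + sc
      tot[j] <- tot[j] + sc
    }
  }
  if (!any_pair)
    stop("no instance pair aligns above min_score = ", min_score,
         "; lower min_score or check the instance set")
  k <- which.max(tot) # which.max takes the first maximum: input-order tie-break
  new_consensus_record(name, instances[[k]], source_id = names(instances)[k])
}

#' Per-column alignment profile of instances against a consensus
#'
#' Semi-globally aligns every instance to the consensus and tallies, per
#' consensus column, base votes, gap votes and coverage, plus each
#' instance's insertion runs keyed by consensus junction. This is the
#' shared substrate of [refine_consensus()] and [detect_cohort()].
#'
#' @param consensus_seq consensus sequence (character).
#' @param instances named character vector of instances.
#' @param model a `scoring_model`.
#' @return list with `votes` (4 x L), `gap_votes`, `coverage`,
#'   `insertions` (per instance), `alignments` (named list of `ltr_aln`).
#' @export
consensus_column_profile <- function(consensus_seq, instances, model) {
  L <- nchar(consensus_seq)
  votes <- matrix(0L, 4, L)
  gap_votes <- integer(L)
  coverage <- integer(L)
  insertions <- list() # per instance: data.frame(junction, len, bases)
  alignments <- list()
  for (id in names(instances)) {
    a <- align_pair(instances[[id]], consensus_seq, model, "semiglobal",
                    target_name = "consensus")
    if (is.null(a) || a$score <= 0) next
    alignments[[id]] <- a
    q <- encode_gapped(a$aln_query)
    t <- encode_gapped(a$aln_target)
    ci <- a$c_start # 0-based position of next consensus base
    ins <- list()
    k <- 1L
    while (k <= length(q)) {
      if (t[k] >= 0L) { # consensus base consumed
        j <- ci + 1L
        coverage[j] <- coverage[j] + 1L
        if (q[k] >= 0L) {
          if (q[k] < 4L) votes[q[k] + 1L, j] <- votes[q[k] + 1L, j] + 1L
        } else gap_votes[j] <- gap_votes[j] + 1L
        ci <- ci + 1L
        k <- k + 1L
      } else { # insertion run in the instance
        st <- k
        while (k <= length(q) && t[k] < 0L) k <- k + 1L
        ins[[length(ins) + 1L]] <-
          data.frame(junction = ci, len = k - st,
                     bases = paste(c(.BASES, "N")[q[st:(k - 1L)] + 1L],
                                   collapse = ""),
                     stringsAsFactors = FALSE)
      }
    }
    insertions[[id]] <- if (length(ins)) do.call(rbind, ins) else
      data.frame(junction = integer(), len = integer(), bases = character(),
                 stringsAsFactors = FALSE)
  }
  list(votes = votes, gap_votes = gap_votes, coverage = coverage,
       insertions = insertions, alignments = alignments)
}

#' Refine a consensus by iterative majority over instance alignments
#'
#' Each round semi-globally aligns every instance to the current consensus
#' and edits it column by column: a column is replaced by the majority
#' instance base when that base is carried by strictly more than half of the
#' covering instances, deleted when more than half gap it, and an insertion
#' column block is added at a junction where more than half of the covering
#' instances insert a run of the same length (filled by majority base).
#' Columns covered by fewer than `min_coverage` instances are never edited.
#' Iteration stops when a round changes nothing or `max_rounds` is reached.
#'
#' @param consensus a `consensus_record` or character sequence.
#' @param instances named character vector of instance sequences
#'   (consensus-strand oriented).
#' @param model a `scoring_model`.
#' @param max_rounds maximum refinement rounds.
#' @param min_coverage columns covered by fewer instances are left alone.
#' @return a `consensus_record` with `rounds`, per-column `support` and
#'   `converged` filled in.
#' @export
refine_consensus <- function(consensus, instances, model, max_rounds = 10L,
                             min_coverage = 3L) {
  rec <- if (inherits(consensus, "consensus_record")) consensus
         else new_consensus_record("consensus", consensus)
  if (is.null(names(instances)))
    names(instances) <- paste0("inst", seq_along(instances))
  cur <- rec$sequence
  converged <- FALSE
  rounds <- 0L
  prof <- NULL
  for (r in seq_len(max_rounds)) {
    prof <- consensus_column_profile(cur, instances, model)
    if (length(prof$alignments) == 0L)
      stop("consensus does not align to any instance")
    L <- nchar(cur)
    cv <- strsplit(cur, "", fixed = TRUE)[[1]]
    ins_all <- do.call(rbind, prof$insertions)
    ins_by_j <- if (!is.null(ins_all) && nrow(ins_all))
      split(ins_all, ins_all$junction) else list()
    out <- character(0)
    for (j in seq_len(L)) {
      cov <- prof$coverage[j]
      piece <- cv[j]
      if (cov >= min_coverage) {
        if (prof$gap_votes[j] * 2L > cov) {
          piece <- character(0) # majority of covering instances gap it
        } else {
          v <- prof$votes[, j]
          b <- which.max(v)
          if (v[b] * 2L > cov && .BASES[b] != cv[j]) piece <- .BASES[b]
        }
      }
      # insertion block after column j: modal same-length run in >50% of
      # instances covering the junction
      ins <- ins_by_j[[as.character(j)]]
      jcov <- if (j < L) min(prof$coverage[j], prof$coverage[j + 1L])
              else prof$coverage[j]
      if (!is.null(ins) && nrow(ins) && jcov >= min_coverage) {
        lens <- table(ins$len)
        lmode <- as.integer(names(lens)[which.max(lens)])
        nmode <- max(lens)
        if (nmode * 2L > jcov) {
          runs <- ins$bases[ins$len == lmode]
          bm <- vapply(seq_len(lmode), function(p) {
            bs <- substr(runs, p, p)
            names(which.max(table(factor(bs, .BASES))))
          }, "")
          piece <- c(piece, bm)
        }
      }
      out <- c(out, piece)
    }
    newseq <- paste(out, collapse = "")
    rounds <- r
    if (newseq == cur) { converged <- TRUE; break }
    cur <- newseq
  }
  # support = final coverage per column of the returned sequence
  prof_final <- consensus_column_profile(cur, instances, model)
  new_consensus_record(rec$name, cur, source_id = rec$source_id,
                       rounds = rounds, support = prof_final$coverage,
                       converged = converged)
}
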