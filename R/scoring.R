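# Scoring model: observed substitution/gap rates between repeat instances and
# consensus sequences, converted to integer-scaled log-odds alignment scores.

#' Construct a scoring model
#'
#' A scoring model bundles observed substitution probabilities, gap rates and
#' the integer log-odds scores derived from them. It is the currency of every
#' alignment step in the package. `subst_scores[x, y]` scores consensus base
#' `x` aligned to instance/genome base `y`; a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param subst_scores 4x4 integer matrix of log-odds scores (rows/cols
#'   A,C,G,T; rows index the consensus base).
#' @param subst_probs 4x4 matrix of conditional substitution probabilities;
#'   each row sums to 1.
#' @param background length-4 base composition vector.
#' @param gap_open,gap_extend positive integer gap costs.
#' @param gap_open_prob observed probability of opening a gap per aligned
#'   column; `gap_extend_prob` is the probability of extending a gap given
#'   one is open.
#' @param gap_extend_prob see `gap_open_prob`.
#' @param scale natural-log units per score unit (bits = scale / ln 2).
#' @param converged,rounds training diagnostics.
#' @return an object of class `scoring_model`.
#' @export
scoring_model <- function(subst_scores, subst_probs, background,
                          gap_open, gap_extend,
                          gap_open_prob, gap_extend_prob, scale,
                          converged = NA, rounds = NA_integer_) {
  stopifnot(is.matrix(subst_scores), all(dim(subst_scores) == c(4, 4)),
            is.matrix(subst_probs), all(dim(subst_probs) == c(4, 4)),
            length(background) == 4, gap_open > 0, gap_extend > 0)
  if (max(abs(rowSums(subst_probs) - 1)) > 1e-6)
    stop("rows of subst_probs must sum to 1")
  dimnames(subst_scores) <- dimnames(subst_probs) <- list(.BASES, .BASES)
  names(background) <- .BASES
  structure(list(subst_scores = round(subst_scores),
                 subst_probs = subst_probs,
                 background = background / sum(background),
                 gap_open = as.integer(round(gap_open)),
                 gap_extend = as.integer(round(gap_extend)),
                 gap_open_prob = gap_open_prob,
                 gap_extend_prob = gap_extend_prob,
                 scale = scale, converged = converged, rounds = rounds),
            class = "scoring_model")
}

#' Permissive bootstrap scoring model
#'
#' Match +1 / mismatch -1, gap open 7, gap extend 1. Any reasonably similar
#' instance set aligns under this model, which makes it a safe first round
#' for [train_model()].
#' @return a `scoring_model`.
#' @export
default_model <- function() {
  sc <- matrix(-1L, 4, 4); diag(sc) <- 1L
  pr <- matrix(0.05, 4, 4); diag(pr) <- 0.85
  scoring_model(sc, pr, rep(0.25, 4), gap_open = 7, gap_extend = 1,
                gap_open_prob = 0.02, gap_extend_prob = 0.5,
                scale = log(2))
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("scoring_model: scale =", signif(x$scale, 4),
      "ln/unit; gap open/extend =", x$gap_open, "/", x$gap_extend, "\n")
  print(x$subst_scores)
  invisible(x)
}

#' Tally substitution and gap events from alignments
#'
#' Exact counts over a set of instance-to-consensus alignments. Ambiguous
#' bases (N) are excluded from all tallies. A gap run of length L counts one
#' open and L - 1 extends (the affine decomposition). Gap runs longer than
#' `max_gap_run` are excluded from the gap tallies: such gaps reflect
#' structural differences between instance and consensus (hybrid joins,
#' subfamily diagnostic indels, truncations), not the per-site indel
#' process whose rate is being estimated.
#'
#' @param alignments list of alignments as produced by [align_pair()] or
#'   [local_align()].
#' @param max_gap_run longest gap run counted as indel events (bp).
#' @return list with `subst` (4x4 counts, rows = consensus base, cols =
#'   instance base), `gap_open`, `gap_extend`, `aligned_cols`.
#' @export
count_events <- function(alignments, max_gap_run = 20L) {
  if (length(alignments) == 0L) stop("no alignments provided (empty list)")
  subst <- matrix(0L, 4, 4, dimnames = list(.BASES, .BASES))
  g_open <- 0L; g_ext <- 0L; cols <- 0L
  for (a in alignments) {
    q <- encode_gapped(a$aln_query)
    t <- encode_gapped(a$aln_target)
    mcol <- q >= 0L & t >= 0L
    ok <- mcol & q < 4L & t < 4L
    if (any(ok))
      subst <- subst + unclass(table(factor(t[ok], 0:3), factor(q[ok], 0:3)))
    cols <- cols + sum(ok)
    for (v in list(q, t)) {
      r <- rle(v < 0L)
      gaps <- r$lengths[r$values]
      gaps <- gaps[gaps <= max_gap_run]
      g_open <- g_open + length(gaps)
      g_ext <- g_ext + sum(gaps - 1L)
    }
  }
  list(subst = subst, gap_open = g_open, gap_extend = g_ext,
       aligned_cols = cols)
}

# gapped string -> codes, gap = -1
encode_gapped <- function(s) {
  v <- encode_dna(gsub("-", "Z", s))
  v[substring(s, seq_len(nchar(s)), seq_len(nchar(s))) == "-"] <- -1L
  v
}

#' Build a scoring model from event counts
#'
#' Probabilities use a pseudocount of 0.5 per substitution cell and per gap
#' event; log-odds scores are `round(ln(p_xy / (q_x q_y)) / scale)` where
#' `p_xy` is the joint aligned-pair probability and `q` the marginal base
#' composition. The scale defaults to eighth-bit units and is widened if any
#' score magnitude would exceed `max_abs_score`.
#'
#' @param counts output of [count_events()].
#' @param pseudocount added to every substitution cell and gap tally.
#' @param max_abs_score cap on integer score magnitude.
#' @return a `scoring_model`.
#' @export
model_from_counts <- function(counts, pseudocount = 0.5, max_abs_score = 120) {
  cm <- counts$subst + pseudocount
  joint <- cm / sum(cm)
  q <- (rowSums(joint) + colSums(joint)) / 2
  lods <- log(joint / outer(q, q))
  open_p <- (counts$gap_open + pseudocount) / (counts$aligned_cols + 2 * pseudocount)
  ext_p <- (counts$gap_extend + pseudocount) /
    (counts$gap_open + counts$gap_extend + 2 * pseudocount)
  raw_open <- -log(open_p)
  raw_ext <- -log(ext_p)
  scale <- log(2) / 8
  mx <- max(abs(lods), raw_open, raw_ext)
  if (mx / scale > max_abs_score) scale <- mx / max_abs_score
  scoring_model(round(lods / scale), cm / rowSums(cm), q,
                gap_open = max(2, round(raw_open / scale)),
                gap_extend = max(1, round(raw_ext / scale)),
                gap_open_prob = open_p, gap_extend_prob = ext_p,
                scale = scale)
}

#' Read and write scoring models as JSON
#'
#' @param model a `scoring_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   `scoring_model`.
#' @export
write_model <- function(model, path) {
  x <- unclass(model)
  x$subst_scores <- lapply(1:4, function(i) unname(model$subst_scores[i, ]))
  x$subst_probs <- lapply(1:4, function(i) unname(model$subst_probs[i, ]))
  x$background <- unname(model$background)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scoring_model(matrix(unlist(x$subst_scores), 4, 4, byrow = TRUE),
                matrix(unlist(x$subst_probs), 4, 4, byrow = TRUE),
                x$background, x$gap_open, x$gap_extend,
                x$gap_open_prob, x$gap_extend_prob, x$scale,
                converged = x$converged %||% NA,
                rounds = x$rounds %||% NA_integer_)
}

#' Train a scoring model from instances and consensuses
#'
#' Iterates align -> count -> rescore until the observed rates change by
#' less than `tol`, starting from a permissive model. Each round aligns every
#' instance to its best-matching consensus with [local_align()] and feeds the
#' event tallies to [model_from_counts()].
#'
#' @param sequences character vector of repeat instances.
#' @param consensuses named character vector of consensus sequences.
#' @param init_model starting `scoring_model` (default [default_model()]).
#' @param max_rounds maximum align/count iterations.
#' @param tol convergence threshold on the max absolute change of any
#'   substitution or gap probability.
#' @param min_score_frac round-1 alignment score floor, as a fraction of
#'   instance length times the mean diagonal score.
#' @param symmetrize if TRUE, counts are symmetrised under
#'   reverse-complement relabelling so the model is strand symmetric.
#' @return a trained `scoring_model` with `converged` and `rounds` set.
#' @export
train_model <- function(sequences, consensuses, init_model = default_model(),
                        max_rounds = 10, tol = 1e-4, min_score_frac = 0.2,
                        symmetrize = FALSE) {
  stopifnot(length(sequences) > 0, length(consensuses) > 0)
  model <- init_model
  prev <- NULL
  rounds <- 0L
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    alns <- list()
    dmean <- mean(diag(model$subst_scores))
    for (s in sequences) {
      ms <- max(10, round(min_score_frac * nchar(s) * dmean))
      best <- NULL
      for (cn in names(consensuses)) {
        h <- local_align(s, consensuses[[cn]], model, min_score = ms,
                         consensus_name = cn, max_hits = 1)
        if (length(h) && (is.null(best) || h[[1]]$score > best$score))
          best <- h[[1]]
      }
      if (!is.null(best)) alns[[length(alns) + 1L]] <- best
    }
    if (length(alns) == 0L) {
      if (r == 1L)
        stop("no alignment above threshold in round 1; ",
             "use a more permissive init model or lower min_score_frac")
      break
    }
    cnt <- count_events(alns)
    if (symmetrize) {
      comp <- c(4, 3, 2, 1) # A<->T, C<->G (1-based index map)
      rcc <- cnt$subst[comp, comp]
      cnt$subst <- cnt$subst + rcc
      cnt$gap_open <- 2L * cnt$gap_open
      cnt$gap_extend <- 2L * cnt$gap_extend
      cnt$aligned_cols <- 2L * cnt$aligned_cols
    }
    model <- model_from_counts(cnt)
    rounds <- r
    cur <- c(model$subst_probs, model$gap_open_prob, model$gap_extend_prob)
    if (!is.null(prev) && max(abs(cur - prev)) < tol) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  model$converged <- converged
  model$rounds <- rounds
  model
}
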