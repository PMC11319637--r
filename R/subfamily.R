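# Subfamily discovery: find cohorts of instances whose alignments to the
# family consensus consistently stop matching at a shared position (shared
# deletions, insertions or truncations), split them off as new subfamilies
# with their own consensus, and iterate until no cohort remains.

new_subfamily_model <- function(name, consensus, parent, feature, members,
                                generation = 1L) {
  structure(list(name = name, consensus = consensus, parent = parent,
                 feature = feature, members = members,
                 generation = generation),
            class = "subfamily_model")
}

#' @export
print.subfamily_model <- function(x, ...) {
  ft <- if (is.null(x$feature)) "none" else x$feature$type
  cat(sprintf("subfamily_model %s (parent %s, gen %d): %d members, feature %s\n",
              x$name, x$parent, x$generation, length(x$members), ft))
  invisible(x)
}

# unaligned-consensus features of one instance alignment:
# shared_termination (prefix/suffix truncation), shared_deletion (internal
# consensus block skipped), shared_insertion (instance-side run at a
# consensus junction; interval = [junction, junction + length))
.alignment_features <- function(aln, consensus_length, min_len) {
  feats <- list()
  add <- function(type, s, e) feats[[length(feats) + 1L]] <<-
    data.frame(type = type, start = s, end = e, stringsAsFactors = FALSE)
  if (aln$c_start >= min_len) add("shared_termination", 0L, aln$c_start)
  if (consensus_length - aln$c_end >= min_len)
    add("shared_termination", aln$c_end, consensus_length)
  q <- encode_gapped(aln$aln_query)
  t <- encode_gapped(aln$aln_target)
  ci <- aln$c_start
  k <- 1L
  while (k <= length(q)) {
    if (t[k] >= 0L) {
      if (q[k] < 0L) { # deletion run in the instance
        st <- ci
        while (k <= length(q) && t[k] >= 0L && q[k] < 0L) {
          ci <- ci + 1L; k <- k + 1L
        }
        if (ci - st >= min_len) add("shared_deletion", st, ci)
      } else { ci <- ci + 1L; k <- k + 1L }
    } else { # insertion run
      st <- k
      while (k <= length(q) && t[k] < 0L) k <- k + 1L
      if (k - st >= min_len)
        add("shared_insertion", ci, ci + (k - st))
    }
  }
  if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Detect a cohort of instances sharing an alignment-termination feature
#'
#' For every instance alignment, extracts the consensus blocks its alignment
#' skips — internal deletions, prefix/suffix truncations, and instance-side
#' insertion runs at a consensus junction — keeping features of at least
#' `boundary_tol` bp. Features of each type are clustered across instances
#' by single linkage on their interval endpoints (Chebyshev distance, cut at
#' `boundary_tol`); the largest cluster by distinct supporting instances is
#' returned if it reaches `min_support`.
#'
#' @param alignments named list of instance-to-consensus `ltr_aln` (plus
#'   strand, e.g. from [consensus_column_profile()]).
#' @param consensus_length length of the consensus the instances were
#'   aligned to.
#' @param min_support smallest cohort worth splitting.
#' @param boundary_tol endpoint clustering tolerance; features shorter than
#'   this are ignored as alignment noise.
#' @return a `split_cohort` (list with `members`, `feature_type`,
#'   `consensus_interval`, `support`, `dispersion`) or `NULL`.
#' @export
detect_cohort <- function(alignments, consensus_length, min_support = 10L,
                          boundary_tol = 10L) {
  if (length(alignments) == 0L) return(NULL)
  ids <- names(alignments) %||% paste0("inst", seq_along(alignments))
  fl <- list()
  for (i in seq_along(alignments)) {
    f <- .alignment_features(alignments[[i]], consensus_length,
                             boundary_tol)
    if (nrow(f)) {
      f$id <- ids[i]
      fl[[length(fl) + 1L]] <- f
    }
  }
  if (length(fl) == 0L) return(NULL)
  feats <- do.call(rbind, fl)
  best <- NULL
  for (ty in unique(feats$type)) {
    f <- feats[feats$type == ty, , drop = FALSE]
    cl <- if (nrow(f) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(f[c("start", "end")],
                                              method = "maximum"),
                                  method = "single"), h = boundary_tol)
    for (k in unique(cl)) {
      g <- f[cl == k, , drop = FALSE]
      support <- length(unique(g$id))
      if (support < min_support) next
      cand <- list(members = sort(unique(g$id)), feature_type = ty,
                   consensus_interval = c(stats::median(g$start),
                                          stats::median(g$end)),
                   support = support,
                   dispersion = max(stats::mad(g$start, constant = 1),
                                    stats::mad(g$end, constant = 1)))
      if (is.null(best) || cand$support > best$support ||
          (cand$support == best$support &&
           cand$consensus_interval[1] < best$consensus_interval[1]))
        best <- cand
    }
  }
  if (!is.null(best)) class(best) <- "split_cohort"
  best
}

#' Split a cohort off a family as a new subfamily
#'
#' Removes the cohort members from the family, builds their own consensus
#' (seed + majority refinement), and re-refines the parent consensus from
#' the remaining members.
#'
#' @param instances named character vector: all family instances.
#' @param consensus the family `consensus_record` (or sequence).
#' @param cohort a `split_cohort` from [detect_cohort()].
#' @param model a `scoring_model`.
#' @param name name of the new subfamily.
#' @param seed_min_score pairwise floor for [seed_consensus()].
#' @param generation recorded in the new model.
#' @return list with `new` (a `subfamily_model`, `low_support` flagged when
#'   the cohort has fewer than 5 members), `parent_consensus` (re-refined
#'   `consensus_record`), `remaining` (ids left in the parent).
#' @export
split_family <- function(instances, consensus, cohort, model,
                         name = "sub1", seed_min_score = 2000,
                         generation = 1L) {
  if (length(cohort$members) == 0L) stop("empty cohort")
  if (!all(cohort$members %in% names(instances)))
    stop("cohort contains instances not in the family")
  if (length(cohort$members) == length(instances))
    stop("cohort equals family: a split must leave a parent")
  mem <- instances[cohort$members]
  rest <- instances[setdiff(names(instances), cohort$members)]
  cons_new <- if (length(mem) == 1L)
    new_consensus_record(name, mem[[1]], source_id = names(mem))
  else {
    seed <- seed_consensus(mem, model, min_score = seed_min_score,
                           name = name)
    refine_consensus(seed, mem, model)
  }
  cons_new$name <- name
  rec <- if (inherits(consensus, "consensus_record")) consensus
         else new_consensus_record("parent", consensus)
  parent_cons <- if (length(rest) >= 1L)
    refine_consensus(rec, rest, model) else rec
  sm <- new_subfamily_model(name, cons_new, parent = rec$name,
                            feature = list(type = cohort$feature_type,
                                           consensus_interval =
                                             cohort$consensus_interval),
                            members = cohort$members,
                            generation = generation)
  sm$low_support <- cohort$support < 5L
  list(new = sm, parent_consensus = parent_cons,
       remaining = names(rest))
}

#' Iteratively split a family into subfamilies
#'
#' Repeats refine consensus -> detect cohort -> split, processing every
#' family (the original and each newly created subfamily) until no family
#' yields a cohort or `max_iterations` passes elapse. Cohorts are split
#' largest first, one per family per pass. Every input instance ends in
#' exactly one subfamily; the residual parent keeps the family name.
#'
#' @param instances named character vector of family instances
#'   (consensus-strand oriented).
#' @param model a `scoring_model`.
#' @param consensus optional starting `consensus_record`; seeded and
#'   refined from the instances when NULL.
#' @param family_name name of the root family.
#' @param min_support smallest cohort split off; default
#'   `max(10, ceiling(0.05 * family size))`, re-evaluated per family.
#' @param boundary_tol see [detect_cohort()].
#' @param max_iterations cap on whole-queue passes.
#' @param seed_min_score pairwise floor for consensus seeding.
#' @return list of `subfamily_model` (residual parent first); attribute
#'   `converged` is FALSE if `max_iterations` stopped the loop.
#' @export
iterate_splitting <- function(instances, model, consensus = NULL,
                              family_name = "fam", min_support = NULL,
                              boundary_tol = 10L, max_iterations = 10L,
                              seed_min_score = 2000) {
  if (is.null(names(instances)))
    names(instances) <- paste0("inst", seq_along(instances))
  supp_rule <- function(n) min_support %||% max(10L, ceiling(0.05 * n))
  root_cons <- if (is.null(consensus)) {
    seed <- seed_consensus(instances, model, min_score = seed_min_score,
                           name = family_name)
    refine_consensus(seed, instances, model)
  } else consensus
  root_cons$name <- family_name
  fams <- list(list(name = family_name, consensus = root_cons,
                    members = names(instances), generation = 0L,
                    feature = NULL, parent = NA_character_))
  converged <- FALSE
  n_sub <- 0L
  for (it in seq_len(max_iterations)) {
    any_split <- FALSE
    fi <- 1L
    while (fi <= length(fams)) {
      fam <- fams[[fi]]
      mem <- instances[fam$members]
      if (length(mem) < 2L) { fi <- fi + 1L; next }
      cons <- refine_consensus(fam$consensus, mem, model)
      cons$name <- fam$name
      fams[[fi]]$consensus <- cons
      prof <- consensus_column_profile(cons$sequence, mem, model)
      cohort <- detect_cohort(prof$alignments, cons$length,
                              min_support = supp_rule(length(mem)),
                              boundary_tol = boundary_tol)
      if (!is.null(cohort) &&
          length(cohort$members) < length(mem)) {
        n_sub <- n_sub + 1L
        nm <- paste0(family_name, "_sub", n_sub)
        sp <- split_family(mem, cons, cohort, model, name = nm,
                          seed_min_score = seed_min_score,
                          generation = fam$generation + 1L)
        fams[[fi]]$members <- sp$remaining
        fams[[fi]]$consensus <- sp$parent_consensus
        fams[[fi]]$consensus$name <- fam$name
        fams[[length(fams) + 1L]] <-
          list(name = nm, consensus = sp$new$consensus,
               members = cohort$members,
               generation = fam$generation + 1L,
               feature = sp$new$feature, parent = fam$name)
        any_split <- TRUE
      }
      fi <- fi + 1L
    }
    if (!any_split) { converged <- TRUE; break }
  }
  out <- lapply(fams, function(f)
    new_subfamily_model(f$name, f$consensus, parent = f$parent,
                        feature = f$feature, members = f$members,
                        generation = f$generation))
  attr(out, "converged") <- converged
  out
}

#' Pairwise distinctness report of subfamily consensuses
#'
#' All-vs-all local alignment of the subfamily consensuses, returning every
#' match above `min_score` (not only the best), with divergence and indel
#' percentages per pair. Pairs whose best match shows divergence + indel at
#' or below `distinct_floor` are flagged non-distinct.
#'
#' @param models list of `subfamily_model` (or named character vector of
#'   consensus sequences).
#' @param model a `scoring_model`.
#' @param min_score report matches at or above this score.
#' @param distinct_floor percent threshold (divergence + indel) below which
#'   a pair is flagged.
#' @return data.frame: query, target, n_matches, score,
#'   percent_divergence, percent_indel, distinct.
#' @export
verify_subfamily_distinctness <- function(models, model, min_score = 2000,
                                          distinct_floor = 2) {
  seqs <- if (is.character(models)) models else
    stats::setNames(vapply(models, function(m) m$consensus$sequence, ""),
                    vapply(models, `[[`, "", "name"))
  if (length(seqs) < 2L) stop("need at least 2 consensuses")
  rows <- list()
  nms <- names(seqs)
  for (i in seq_len(length(seqs) - 1L)) for (j in (i + 1L):length(seqs)) {
    hits <- local_align(seqs[[i]], seqs[[j]], model, min_score = min_score,
                        consensus_name = nms[j], strand = "+")
    if (length(hits) == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(query = nms[i], target = nms[j], n_matches = 0L,
                   score = NA_real_, percent_divergence = NA_real_,
                   percent_indel = NA_real_, distinct = TRUE,
                   stringsAsFactors = FALSE)
      next
    }
    best <- hits[[which.max(vapply(hits, `[[`, 0, "score"))]]
    st <- alignment_stats(best)
    rows[[length(rows) + 1L]] <-
      data.frame(query = nms[i], target = nms[j],
                 n_matches = length(hits), score = best$score,
                 percent_divergence = round2(st$percent_divergence),
                 percent_indel = round2(st$percent_indel),
                 distinct = st$percent_divergence + st$percent_indel >
                   distinct_floor,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
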