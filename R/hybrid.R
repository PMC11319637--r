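# Hybrid element detection: assemble annotation segments into elements,
# flag elements whose parts align to different repeat families, and cluster
# recurrent hybrids by composition and breakpoint position.

#' Assemble annotation segments into elements
#'
#' Consecutive segments separated by at most `max_gap` genome bases merge
#' into one element. An element is a hybrid iff its segments come from at
#' least two distinct families (family = consensus name, optionally grouped
#' through `family_map`, e.g. mapping several consensus names to one
#' family). Adjacent segments from the same family collapse into one
#' composition part; breakpoints record, for each adjacent pair of
#' composition parts, the consensus coordinate where the left family's
#' match ends and the right family's begins. Elements whose segments all lie on the minus strand are
#' reported in consensus-forward order so plus- and minus-strand copies of
#' the same hybrid share a composition signature.
#'
#' @param segments data.frame from [annotate_genome()] /
#'   [partition_alignments()], sorted by genome start, non-overlapping.
#' @param max_gap largest genome gap (bp) bridged within one element.
#' @param family_map optional named character vector mapping consensus names
#'   to family names.
#' @return list of elements; each a list with `genome_start`, `genome_end`,
#'   `segments` (data.frame), `composition` (ordered family names),
#'   `is_hybrid`, and `breakpoints` (data.frame with left_family,
#'   left_consensus_end, right_family, right_consensus_start,
#'   genome_position).
#' @export
assemble_elements <- function(segments, max_gap = 100L, family_map = NULL) {
  if (nrow(segments) == 0L) return(list())
  if (is.unsorted(segments$genome_start))
    stop("segments must be sorted by genome start")
  if (any(segments$genome_start[-1] < segments$genome_end[-nrow(segments)]))
    stop("segments must be non-overlapping")
  fam <- function(x) if (is.null(family_map)) x else
    ifelse(is.na(family_map[x]), x, family_map[x])
  grp <- cumsum(c(1L, as.integer(
    segments$genome_start[-1] - segments$genome_end[-nrow(segments)] >
      max_gap)))
  out <- list()
  for (g in unique(grp)) {
    seg <- segments[grp == g, , drop = FALSE]
    # minus-strand elements: traverse right-to-left so composition and
    # breakpoints are in consensus-forward (element 5' -> 3') order
    if (nrow(seg) > 1L && all(seg$strand == "-"))
      seg_o <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    else seg_o <- seg
    segfam <- fam(seg_o$consensus_name)
    # a breakpoint is where one family is replaced by *another*: runs of
    # adjacent same-family segments collapse to one composition part
    runs <- rle(segfam)
    comp <- runs$values
    run_end <- cumsum(runs$lengths)   # last segment index of each run
    run_start <- run_end - runs$lengths + 1L
    bps <- NULL
    if (length(comp) > 1L) {
      nr <- length(comp)
      li <- run_end[-nr]; ri <- run_start[-1]
      gp <- if (all(seg_o$strand == "-"))
        seg_o$genome_start[li] else seg_o$genome_end[li]
      bps <- data.frame(left_family = comp[-nr],
                        left_consensus_end = seg_o$consensus_end[li],
                        right_family = comp[-1],
                        right_consensus_start = seg_o$consensus_start[ri],
                        genome_position = gp,
                        stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <-
      list(genome_start = min(seg$genome_start),
           genome_end = max(seg$genome_end),
           segments = seg, composition = comp,
           is_hybrid = length(unique(comp)) >= 2L,
           breakpoints = bps %||%
             data.frame(left_family = character(),
                        left_consensus_end = integer(),
                        right_family = character(),
                        right_consensus_start = integer(),
                        genome_position = integer(),
                        stringsAsFactors = FALSE))
  }
  out
}

# flattened breakpoint-coordinate vector of one hybrid element
.bp_vector <- function(el) {
  as.numeric(rbind(el$breakpoints$left_consensus_end,
                   el$breakpoints$right_consensus_start))
}

#' Cluster recurrent hybrid elements by composition and breakpoints
#'
#' Hybrids sharing an ordered composition signature are clustered by
#' single linkage under the Chebyshev (maximum-coordinate) distance over
#' their breakpoint coordinate vectors, cut at `breakpoint_tol`. Each class
#' reports median breakpoints, member count and per-coordinate median
#' absolute deviation so the "roughly fixed breakpoint" claim can be
#' audited.
#'
#' @param hybrids list of hybrid elements from [assemble_elements()].
#' @param breakpoint_tol single-linkage threshold (bp).
#' @return list of classes sorted by member count (descending); each a list
#'   with `composition`, `representative_breakpoints` (data.frame),
#'   `member_count`, `members` (indices into `hybrids`), `dispersion`
#'   (max per-coordinate MAD).
#' @export
cluster_hybrids <- function(hybrids, breakpoint_tol = 15) {
  if (length(hybrids) == 0L) return(list())
  sig <- vapply(hybrids, function(e) paste(e$composition, collapse = ">"),
                "")
  classes <- list()
  for (s in unique(sig)) {
    idx <- which(sig == s)
    vecs <- do.call(rbind, lapply(hybrids[idx], .bp_vector))
    cl <- if (length(idx) == 1L) 1L else {
      d <- stats::dist(vecs, method = "maximum")
      stats::cutree(stats::hclust(d, method = "single"),
                    h = breakpoint_tol)
    }
    for (k in unique(cl)) {
      mem <- idx[cl == k]
      v <- vecs[cl == k, , drop = FALSE]
      med <- apply(v, 2, stats::median)
      mad <- apply(v, 2, function(x) stats::median(abs(x - stats::median(x))))
      bp0 <- hybrids[[mem[1]]]$breakpoints
      rep_bp <- data.frame(left_family = bp0$left_family,
                           left_consensus_end = med[c(TRUE, FALSE)],
                           right_family = bp0$right_family,
                           right_consensus_start = med[c(FALSE, TRUE)],
                           stringsAsFactors = FALSE)
      classes[[length(classes) + 1L]] <-
        list(composition = hybrids[[mem[1]]]$composition,
             representative_breakpoints = rep_bp,
             member_count = length(mem), members = mem,
             dispersion = if (length(mem) > 1L) max(mad) else 0)
    }
  }
  classes[order(vapply(classes, `[[`, 0L, "member_count"),
                decreasing = TRUE)]
}

#' Promote a recurrent hybrid class to a new family model
#'
#' Builds a consensus from the member element sequences (seeded with
#' [seed_consensus()] and refined with [refine_consensus()]) and returns a
#' subfamily model that records the parent families and the class's median
#' breakpoints as its diagnostic feature. The returned consensus can be
#' added to an annotation library like any family consensus.
#'
#' @param class one class from [cluster_hybrids()].
#' @param instance_sequences named character vector of the member element
#'   sequences, consensus-strand oriented.
#' @param model a `scoring_model`.
#' @param name name of the new family.
#' @param min_copies refuse promotion below this member count.
#' @param seed_min_score pairwise floor for [seed_consensus()].
#' @return a `subfamily_model` (see [iterate_splitting()]).
#' @export
promote_class_to_family <- function(class, instance_sequences, model,
                                    name = "hybrid_family",
                                    min_copies = 20L,
                                    seed_min_score = 2000) {
  if (class$member_count < min_copies)
    stop("refusing to promote a hybrid class with ", class$member_count,
         " members (< min_copies = ", min_copies, ")")
  seed <- seed_consensus(instance_sequences, model,
                         min_score = seed_min_score, name = name)
  cons <- refine_consensus(seed, instance_sequences, model)
  cons$name <- name
  new_subfamily_model(name = name, consensus = cons,
                      parent = paste(unique(class$composition),
                                     collapse = "+"),
                      feature = list(type = "hybrid_breakpoints",
                                     breakpoints =
                                       class$representative_breakpoints),
                      members = names(instance_sequences),
                      generation = 1L)
}

#' Extract element sequences from a genome
#'
#' Returns each element's genomic sequence oriented to the consensus strand
#' (elements whose segments are all minus strand are reverse complemented).
#' @param elements list from [assemble_elements()].
#' @param genome genome sequence the segments were annotated on.
#' @return named character vector (`elem_<i>`).
#' @export
element_sequences <- function(elements, genome) {
  out <- character(length(elements))
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    s <- substr(genome, el$genome_start + 1L, el$genome_end)
    if (all(el$segments$strand == "-")) s <- revcomp(s)
    out[i] <- s
  }
  stats::setNames(out, paste0("elem_", seq_along(elements)))
}

#' Tabulate elements
#' @param elements list from [assemble_elements()].
#' @return data.frame with one row per element: genome_start, genome_end,
#'   n_segments, composition, is_hybrid.
#' @export
elements_table <- function(elements) {
  do.call(rbind, lapply(seq_along(elements), function(i) {
    el <- elements[[i]]
    data.frame(element = i, genome_start = el$genome_start,
               genome_end = el$genome_end,
               n_segments = nrow(el$segments),
               composition = paste(el$composition, collapse = ">"),
               is_hybrid = el$is_hybrid, stringsAsFactors = FALSE)
  })) %||% data.frame()
}
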