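# Insertion-age analysis: count, per subfamily, how many focal-genome
# instances have an ortholog in each other species (via a liftover-style
# interval mapping table), and bracket each instance's insertion age by the
# oldest split it crosses on a ladder species tree.

#' Cross-species shared-instance counts per subfamily
#'
#' A focal instance counts as shared with species S iff the mapping table
#' carries its interval to S and the mapped interval overlaps an annotation
#' of the same subfamily in S by at least `min_overlap` of the mapped
#' length. Columns are ordered focal first, then species by divergence age;
#' a non-monotone row (counts increasing with age) is reported in the
#' `monotone` attribute.
#'
#' @param annotations named list of data.frames (one per species, focal
#'   included) with columns `start`, `end`, `subfamily`.
#' @param mapping data.frame with columns focal_start, focal_end, species,
#'   mapped_start, mapped_end (e.g. from [orthology_map()], or built from
#'   UCSC liftOver output).
#' @param species_order species names ordered by divergence age
#'   (youngest split first), excluding the focal species.
#' @param min_overlap minimum fraction of the mapped interval covered.
#' @return integer matrix rows = subfamily, cols = focal + species;
#'   attribute `monotone` (logical per row).
#' @export
shared_counts <- function(annotations, mapping, species_order,
                          min_overlap = 0.5) {
  missing_sp <- setdiff(species_order, names(annotations))
  if (length(missing_sp))
    stop("species missing from the annotation set: ",
         paste(missing_sp, collapse = ", "))
  foc <- annotations[["focal"]]
  if (is.null(foc)) stop("annotations must include a 'focal' entry")
  subs <- sort(unique(foc$subfamily))
  out <- matrix(0L, length(subs), 1L + length(species_order),
                dimnames = list(subs, c("focal", species_order)))
  for (i in seq_len(nrow(foc))) {
    sf <- foc$subfamily[i]
    out[sf, "focal"] <- out[sf, "focal"] + 1L
    for (sp in species_order) {
      mp <- mapping[mapping$species == sp &
                      pmin(mapping$focal_end, foc$end[i]) -
                      pmax(mapping$focal_start, foc$start[i]) >
                      0.5 * (foc$end[i] - foc$start[i]), , drop = FALSE]
      if (nrow(mp) == 0L) next
      ann_sp <- annotations[[sp]]
      if (is.null(ann_sp)) next
      ann_sp <- ann_sp[ann_sp$subfamily == sf, , drop = FALSE]
      shared <- FALSE
      for (k in seq_len(nrow(mp))) {
        if (nrow(ann_sp) == 0L) break
        ov <- pmax(0, pmin(ann_sp$end, mp$mapped_end[k]) -
                     pmax(ann_sp$start, mp$mapped_start[k]))
        if (any(ov >= min_overlap *
                  (mp$mapped_end[k] - mp$mapped_start[k]))) {
          shared <- TRUE
          break
        }
      }
      if (shared) out[sf, sp] <- out[sf, sp] + 1L
    }
  }
  attr(out, "monotone") <-
    apply(out[, -1, drop = FALSE], 1,
          function(x) all(diff(x) <= 0)) &
    out[, 1] >= apply(out[, -1, drop = FALSE], 1, max)
  out
}

#' Bracket an instance's insertion age from its sharing pattern
#'
#' On a ladder species tree with split ages `split_ages` (youngest first),
#' an instance shared with the first k outgroups but not the (k+1)-th was
#' inserted between those two splits: `min_age` is the age of the oldest
#' crossed split (0 if shared with none) and `max_age` the next older split
#' (Inf if shared with all). A presence pattern that skips a younger
#' species while present in an older one cannot arise by a single insertion
#' and is flagged (`homoplasy = TRUE`, bracket NA).
#'
#' @param shared logical vector over the outgroup species, ordered youngest
#'   split first.
#' @param split_ages numeric split ages, same order, strictly increasing.
#' @return list with `min_age`, `max_age`, `homoplasy`.
#' @export
bracket_age <- function(shared, split_ages) {
  stopifnot(length(shared) == length(split_ages))
  if (length(shared) == 0L)
    return(list(min_age = 0, max_age = Inf, homoplasy = FALSE))
  if (any(diff(shared) > 0)) # absent young, present old
    return(list(min_age = NA_real_, max_age = NA_real_, homoplasy = TRUE))
  k <- sum(shared)
  list(min_age = if (k == 0L) 0 else split_ages[k],
       max_age = if (k == length(split_ages)) Inf else split_ages[k + 1L],
       homoplasy = FALSE)
}
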