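# Instance phylogeny: select full-length LTR instances, build a
# reference-anchored alignment matrix, trim sparse columns, compute
# pairwise distances and a neighbor-joining tree, and score subfamily
# cohesion on it.

#' Select full-length LTR instances
#'
#' Keeps sequences longer than `min_length` bp that start with TG and end
#' with CA (the canonical retroviral LTR terminal dinucleotides), preserving
#' input order. The length test is strict (> `min_length`).
#'
#' @param instances named character vector.
#' @param min_length minimum exclusive length (bp).
#' @return the kept subset, order preserved.
#' @export
select_full_length <- function(instances, min_length = 300L) {
  u <- toupper(instances)
  keep <- nchar(u) > min_length &
    substr(u, 1L, 2L) == "TG" &
    substr(u, nchar(u) - 1L, nchar(u)) == "CA"
  instances[keep]
}

#' Reference-anchored multiple alignment of instances
#'
#' Aligns each instance independently to the reference consensus
#' (semi-global); reference positions define shared columns and
#' instance-specific insertion runs become insertion columns (gaps in all
#' other rows), merged across instances when they occur at the same
#' reference junction. Instances that do not align above `min_score` are
#' excluded and listed in the `excluded` attribute.
#'
#' @param instances named character vector.
#' @param reference the reference consensus sequence.
#' @param model a `scoring_model`.
#' @param min_score exclusion floor for the semi-global alignment score.
#' @return character matrix (rows = instances, columns = alignment columns
#'   over A,C,G,T,-,N) with attributes `provenance` (0-based reference
#'   position of each column, NA for insertion columns) and `excluded`.
#' @export
build_reference_msa <- function(instances, reference, model,
                                min_score = 0) {
  if (is.null(names(instances)))
    names(instances) <- paste0("inst", seq_along(instances))
  L <- nchar(reference)
  rows <- list()
  inserts <- list() # id -> data.frame(junction, len, bases)
  excluded <- character(0)
  for (id in names(instances)) {
    a <- align_pair(instances[[id]], reference, model, "semiglobal",
                    target_name = "reference")
    if (is.null(a) || a$score <= min_score) {
      excluded <- c(excluded, id)
      next
    }
    base <- rep("-", L)
    q <- encode_gapped(a$aln_query)
    t <- encode_gapped(a$aln_target)
    ci <- a$c_start
    ins <- list()
    k <- 1L
    while (k <= length(q)) {
      if (t[k] >= 0L) {
        if (q[k] >= 0L) base[ci + 1L] <- c(.BASES, "N")[q[k] + 1L]
        ci <- ci + 1L
        k <- k + 1L
      } else {
        st <- k
        while (k <= length(q) && t[k] < 0L) k <- k + 1L
        ins[[length(ins) + 1L]] <-
          data.frame(junction = ci, len = k - st,
                     bases = paste(c(.BASES, "N")[q[st:(k - 1L)] + 1L],
                                   collapse = ""),
                     stringsAsFactors = FALSE)
      }
    }
    rows[[id]] <- base
    inserts[[id]] <- if (length(ins)) do.call(rbind, ins) else NULL
  }
  if (length(rows) == 0L) stop("no instance aligned to the reference")
  ids <- names(rows)
  # merged insertion columns: one block per junction, width = longest run
  allins <- do.call(rbind, inserts)
  ins_width <- if (is.null(allins)) integer(0) else
    vapply(split(allins$len, allins$junction), max, 0L)
  junctions <- as.integer(names(ins_width))
  total_cols <- L + sum(ins_width)
  mat <- matrix("-", length(ids), total_cols,
                dimnames = list(ids, NULL))
  prov <- rep(NA_integer_, total_cols)
  # column layout: reference position j occupies a column; insertion block
  # at junction j sits after reference column j (junction 0 = before all)
  # layout: insertion block of junction j sits immediately after reference
  # column j (junction 0 before everything); inserted runs left-aligned
  width_at <- stats::setNames(rep(0L, L + 1L), 0:L) # index = junction 0..L
  if (length(junctions)) width_at[as.character(junctions)] <- ins_width
  wv <- unname(width_at)
  col_of_ref <- seq_len(L) + cumsum(wv[seq_len(L)]) # 1-based matrix column
  for (r in seq_along(ids)) {
    id <- ids[r]
    mat[r, col_of_ref] <- rows[[id]]
    di <- inserts[[id]]
    if (!is.null(di)) for (u in seq_len(nrow(di))) {
      j <- di$junction[u]
      st0 <- if (j == 0L) 1L else col_of_ref[j] + 1L
      bs <- strsplit(di$bases[u], "", fixed = TRUE)[[1]]
      mat[r, st0:(st0 + di$len[u] - 1L)] <- bs
    }
  }
  prov[col_of_ref] <- 0:(L - 1L)
  attr(mat, "provenance") <- prov
  attr(mat, "excluded") <- excluded
  mat
}

#' Drop alignment columns with too few non-gap characters
#'
#' A column is kept iff its non-gap fraction is at least `gt` (so with 100
#' rows and `gt = 0.01`, one non-gap character suffices). Idempotent;
#' column provenance is preserved.
#'
#' @param mat matrix from [build_reference_msa()] (or any character matrix
#'   with "-" gaps).
#' @param gt minimum non-gap fraction in `[0, 1]`.
#' @return the filtered matrix.
#' @export
filter_columns <- function(mat, gt = 0.01) {
  stopifnot(gt >= 0, gt <= 1)
  frac <- colMeans(mat != "-")
  keep <- frac >= gt
  out <- mat[, keep, drop = FALSE]
  pr <- attr(mat, "provenance")
  if (!is.null(pr)) attr(out, "provenance") <- pr[keep]
  attr(out, "excluded") <- attr(mat, "excluded")
  out
}

#' Pairwise distances from an alignment matrix
#'
#' Gap and N columns are dropped per pair (pairwise deletion); the chosen
#' correction is applied via [ape::dist.dna()]. Pairs where the correction
#' is inapplicable (saturation) are set to the maximum finite distance and
#' flagged; pairs with no comparable columns stay NaN and are flagged
#' undefined.
#'
#' @param mat character matrix (rows = instances).
#' @param correction `"p"`, `"jukes-cantor"` or `"kimura2p"`.
#' @return list with `d` (symmetric matrix), `saturated` and `undefined`
#'   (logical matrices).
#' @export
msa_distances <- function(mat,
                          correction = c("p", "jukes-cantor", "kimura2p")) {
  correction <- match.arg(correction)
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  dnb <- ape::as.DNAbin(apply(tolower(mat), 2, identity))
  mod <- c(p = "raw", `jukes-cantor` = "JC69", kimura2p = "K80")[correction]
  d <- as.matrix(ape::dist.dna(dnb, model = mod, pairwise.deletion = TRUE))
  # comparable-column counts distinguish saturation from emptiness
  ok <- t(apply(mat, 1, function(r) r %in% .BASES))
  ncmp <- ok %*% t(ok)
  bad <- !is.finite(d)
  undefined <- bad & ncmp == 0
  saturated <- bad & ncmp > 0
  if (any(saturated)) {
    mx <- if (any(is.finite(d))) max(d[is.finite(d)]) else 1
    d[saturated] <- mx
  }
  diag(d) <- 0
  list(d = d, saturated = saturated, undefined = undefined)
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Canonical neighbor joining on a distance matrix; negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch, keeping
#' leaf-to-leaf path lengths. Unrooted by default.
#'
#' @param d symmetric distance matrix (or the list from [msa_distances()]).
#' @param midpoint_root if TRUE, midpoint-root the tree.
#' @return list with `tree` (an [ape::phylo]) and `newick` (character).
#' @export
nj_tree <- function(d, midpoint_root = FALSE) {
  if (is.list(d) && !is.matrix(d)) d <- d$d
  if (nrow(d) < 3L) stop("need at least 3 taxa for neighbor joining")
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative edges: zero them and add the deficit to the sister edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) tr$edge.length[sibs[1]] <-
        tr$edge.length[sibs[1]] + deficit
  }
  if (midpoint_root) {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("midpoint rooting needs the phangorn package")
    tr <- phangorn::midpoint(tr)
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Subfamily cohesion on a tree
#'
#' Fraction of leaves whose nearest other leaf by patristic (path) distance
#' belongs to the same subfamily; ties count as cohesive if any nearest
#' leaf matches.
#'
#' @param tree an [ape::phylo].
#' @param labels named character vector: tip label -> subfamily.
#' @return list with `cohesion` (overall fraction) and `per_subfamily`.
#' @export
subfamily_cohesion <- function(tree, labels) {
  pd <- ape::cophenetic.phylo(tree)
  tips <- rownames(pd)
  lab <- labels[tips]
  hit <- logical(length(tips))
  for (i in seq_along(tips)) {
    dd <- pd[i, -i]
    nn <- names(dd)[dd == min(dd)]
    hit[i] <- any(lab[nn] == lab[i])
  }
  list(cohesion = mean(hit),
       per_subfamily = tapply(hit, lab, mean))
}
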