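# Pairwise divergence/indel statistics in the CrossMatch-style convention:
# divergence excludes gap columns from its denominator, the indel percentage
# uses all alignment columns.

# round half-up to 2 decimals (reporting convention)
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Pairwise divergence and indel statistics of two sequences
#'
#' Aligns `a` to `b` under `mode` and reports percent divergence
#' (mismatched aligned columns / ungapped aligned columns x 100) and
#' percent indel (gap characters / total alignment columns x 100), both
#' rounded half-up to 2 decimals. In local mode an alignment below
#' `min_score` yields a "no significant match" row rather than an error.
#'
#' @param a,b sequences (character), or named length-1 vectors.
#' @param model a `scoring_model`.
#' @param mode `"local"` or `"semiglobal"`.
#' @param min_score score floor for local mode.
#' @param query,target names used in the report.
#' @return one-row data.frame: query, target, score, percent_divergence,
#'   percent_indel, alignment_length, query_start, query_end, target_start,
#'   target_end, no_match.
#' @export
pairwise_stats <- function(a, b, model, mode = c("local", "semiglobal"),
                           min_score = 1L,
                           query = names(a) %||% "query",
                           target = names(b) %||% "target") {
  mode <- match.arg(mode)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- align_pair(unname(a), unname(b), model, mode,
                    min_score = min_score, target_name = target)
  if (is.null(aln) || (mode == "local" && aln$score < min_score))
    return(data.frame(query = query, target = target, score = NA_real_,
                      percent_divergence = NA_real_,
                      percent_indel = NA_real_,
                      alignment_length = NA_integer_,
                      query_start = NA_integer_, query_end = NA_integer_,
                      target_start = NA_integer_, target_end = NA_integer_,
                      no_match = TRUE, stringsAsFactors = FALSE))
  st <- alignment_stats(aln)
  data.frame(query = query, target = target, score = aln$score,
             percent_divergence = round2(st$percent_divergence),
             percent_indel = round2(st$percent_indel),
             alignment_length = st$n_columns,
             query_start = aln$g_start, query_end = aln$g_end,
             target_start = aln$c_start, target_end = aln$c_end,
             no_match = FALSE, stringsAsFactors = FALSE)
}

#' Sequence lengths of a consensus set
#'
#' @param x path to a FASTA file, or a named character vector of sequences.
#' @return data.frame with `name` and `length` (bp, Ns included).
#' @export
length_report <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    stats::setNames(as.character(s), names(s))
  } else x
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  data.frame(name = names(seqs) %||% character(0),
             length = if (length(seqs)) nchar(unname(seqs)) else integer(0),
             stringsAsFactors = FALSE)
}
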