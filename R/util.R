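# Shared low-level helpers: base encoding, reverse complement, interval math.

.BASES <- c("A", "C", "G", "T")

# character string -> integer codes 0..3, N/other -> 4
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  lut <- integer(256) + 4L
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  if (nchar(x) == 0L) return(integer(0))
  lut[utf8ToInt(x)]
}

decode_dna <- function(codes) {
  paste(c(.BASES, "N")[codes + 1L], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# fraction of interval [s1,e1) covered by [s2,e2); 0-based half-open
interval_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  w <- pmax(1, e1 - s1)
  ov / w
}

# base-level recall/precision of predicted intervals vs truth intervals
# (both data.frames with start/end, 0-based half-open, single sequence)
interval_base_metrics <- function(pred, truth, genome_len) {
  cov <- function(df) {
    v <- logical(genome_len)
    if (nrow(df)) for (i in seq_len(nrow(df))) {
      s <- max(0L, df$start[i]); e <- min(genome_len, df$end[i])
      if (e > s) v[(s + 1L):e] <- TRUE
    }
    v
  }
  p <- cov(pred); t <- cov(truth)
  list(recall = if (any(t)) sum(p & t) / sum(t) else NA_real_,
       precision = if (any(p)) sum(p & t) / sum(p) else NA_real_)
}

# expand a run-length encoded alignment path into per-column op codes
expand_ops <- function(ops, lens) rep.int(ops, lens)

`%||%` <- function(a, b) if (is.null(a)) b else a
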