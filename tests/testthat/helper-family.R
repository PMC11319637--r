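# Family fixture shared by the subfamily and acceptance tests: n_parent
# copies of a master plus cohorts carrying a fixed diagnostic indel, every
# copy independently mutated at the given substitution count.
make_family <- function(master, n_parent, cohorts, n_sub = 20) {
  seqs <- character(0)
  labels <- character(0)
  for (i in seq_len(n_parent)) {
    seqs <- c(seqs, mutate_seq(master, n_sub))
    labels <- c(labels, "parent")
  }
  ci <- 0
  for (co in cohorts) {
    ci <- ci + 1
    founder <- mutate_seq(master, 0, del = co$del, ins = co$ins)
    for (i in seq_len(co$n)) {
      seqs <- c(seqs, mutate_seq(founder, n_sub))
      labels <- c(labels, paste0("cohort", ci))
    }
  }
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  list(seqs = seqs, labels = setNames(labels, names(seqs)))
}
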