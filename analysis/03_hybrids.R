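#!/usr/bin/env Rscript
# Step 3: assemble elements, detect recurrent hybrids, promote the top class.
#
# Annotation segments are merged into elements; elements whose parts match
# different families are hybrids. Hybrids sharing an ordered composition are
# clustered by breakpoint position (single linkage, Chebyshev distance);
# the dominant class -- the recurrent A-B-A hybrid -- is promoted to a new
# family with its own consensus. Outputs: elements table, class table, and
# the promoted consensus FASTA.

source("analysis/00_config.R")
dir.create("results", showWarnings = FALSE)

sim <- study_sim()
seqs <- sim_copy_sequences(sim)
model <- train_model(seqs, sim$masters, tol = 1e-3)
ann <- annotate_genome(sim$genomes[["focal"]], sim$masters, model)
els <- assemble_elements(ann)
tab <- elements_table(els)
write.table(tab, "results/elements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("element compositions:\n")
print(table(tab$composition))

hyb <- els[vapply(els, `[[`, TRUE, "is_hybrid")]
cls <- cluster_hybrids(hyb)
cls_tab <- do.call(rbind, lapply(seq_along(cls), function(i) {
  k <- cls[[i]]
  data.frame(class = i, composition = paste(k$composition, collapse = ">"),
             members = k$member_count, dispersion_bp = k$dispersion,
             breakpoints = paste(
               sprintf("%s:%g|%s:%g",
                       k$representative_breakpoints$left_family,
                       k$representative_breakpoints$left_consensus_end,
                       k$representative_breakpoints$right_family,
                       k$representative_breakpoints$right_consensus_start),
               collapse = ";"))
}))
write.table(cls_tab, "results/hybrid_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(head(cls_tab, 3))

top <- cls[[1]]
esq <- element_sequences(hyb[top$members], sim$genomes[["focal"]])
prom <- promote_class_to_family(top, esq, model, name = "aba_like_rec",
                                min_copies = 20)
cat("promoted", prom$name, ":", prom$consensus$length, "bp consensus from",
    top$member_count, "members\n")
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(setNames(prom$consensus$sequence, prom$name)),
  "results/promoted_hybrid_consensus.fa")
ps <- pairwise_stats(prom$consensus$sequence, sim$founders[["aba_like"]],
                     model, "semiglobal")
cat(sprintf("promoted consensus vs true founder: %.2f%% divergence, %.2f%% indel\n",
            ps$percent_divergence, ps$percent_indel))
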