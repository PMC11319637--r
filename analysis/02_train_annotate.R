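#!/usr/bin/env Rscript
# Step 2: train alignment rates and competitively annotate the focal genome.
#
# Substitution and gap rates between the simulated repeat copies and the
# two family masters are estimated by the align/count/rescore loop, turned
# into integer log-odds scores, and the focal genome is partitioned among
# the two masters so that each genome base is assigned to at most one
# consensus base. Outputs: model JSON, annotation BED6+, and base-level
# recall/precision against the simulated truth.

source("analysis/00_config.R")
dir.create("results", showWarnings = FALSE)

sim <- study_sim()
seqs <- sim_copy_sequences(sim)
model <- train_model(seqs, sim$masters, tol = 1e-3)
cat("trained model (", model$rounds, "rounds, converged =",
    model$converged, "):\n")
print(model)
write_model(model, "results/model.json")

ann <- annotate_genome(sim$genomes[["focal"]], sim$masters, model)
cat(nrow(ann), "annotation segments on the focal genome\n")
write_annotation_bed(ann, "results/annotation_focal.bed")

iv <- sim$intervals[sim$intervals$species == "focal", ]
glen <- nchar(sim$genomes[["focal"]])
cov <- function(st, en) {
  v <- logical(glen)
  for (i in seq_along(st)) if (en[i] > st[i]) v[(st[i] + 1):en[i]] <- TRUE
  v
}
pv <- cov(ann$genome_start, ann$genome_end)
tv <- cov(iv$start, iv$end)
cat(sprintf("base-level recall %.3f, precision %.3f vs truth\n",
            sum(pv & tv) / sum(tv), sum(pv & tv) / sum(pv)))
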