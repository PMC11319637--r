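#!/usr/bin/env Rscript
# Step 1: simulate the study system and write genomes + truth.
#
# See analysis/00_config.R for the generative conditions. Outputs one
# genome FASTA per species, BED6+ truth per species, a per-copy truth TSV,
# breakpoint table, and the family/founder sequences, under results/sim/.

source("analysis/00_config.R")

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- study_sim()
print(sim)
cat("copies per subfamily:\n")
print(table(sim$truth$subfamily))
cat("species presence patterns:\n")
print(table(sim$truth$species_presence))

write_genomes(sim, out)
write_truth(sim, out)
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(sim$masters), file.path(out, "masters.fa"))
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(sim$founders), file.path(out, "founders.fa"))
cat("wrote", out, "\n")
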