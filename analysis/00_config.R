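# Shared study configuration for the analysis scripts. Sourced by every
# step; simulation is deterministic, so each step can rebuild the same
# genomes from this config rather than passing binary objects around.
#
# The system mirrors an MLT2-like LTR landscape: two family masters
# (453 bp and 550 bp), a recurrent three-part hybrid with fixed breakpoints
# (A 5' end, B middle, A 3' end), a diagnostic-deletion cohort inside the
# B family (subB3-like, around position 200), a diagnostic-deletion cohort
# inside the hybrid family (subaba-like, around position 300), and a
# three-split ladder species tree. Time is in units where sub_rate * time
# is the expected per-site divergence.

library(ltrsubfam)

study_config <- function(seed = 2024L) {
  simulation_config(
    seed = seed,
    family_lengths = c(mlt2a_like = 453L, mlt2b_like = 550L),
    bursts = data.frame(time = 10,
                        family = c("mlt2a_like", "mlt2b_like"),
                        n_copies = 25),
    hybrid_events = list(
      list(time = 7, family_a = "mlt2a_like", family_b = "mlt2b_like",
           breakpoint_a = 180, breakpoint_b = 120, breakpoint_b2 = 420,
           breakpoint_a2 = 280, n_copies = 60, name = "aba_like")),
    subfamily_events = list(
      list(time = 5, type = "deletion", position = 200, length = 30,
           n_copies = 30, family = "mlt2b_like", name = "subB3_like"),
      list(time = 5, type = "deletion", position = 300, length = 22,
           n_copies = 30, family = "aba_like", name = "subaba_like")),
    sub_rate = 0.01, indel_rate = 0.001,
    speciation_times = c(4, 7, 10),
    background_length = 250, gc_content = 0.42)
}

study_sim <- function(seed = 2024L) simulate_genomes(study_config(seed))
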