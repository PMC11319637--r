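---
title: "Discovering LTR retrotransposon subfamilies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering LTR retrotransposon subfamilies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long terminal repeats (LTRs) of endogenous retroviruses — the motivating
system is the MLT2 group of HERVL LTRs, with tens of thousands of copies in
the human genome — are classified into families by alignment to curated
consensus sequences. Two systematic errors hide diversity in such
annotations. First, when one genomic region resembles several consensuses,
single-best-hit annotation silently picks one and conceals *hybrid
elements*: copies that are genuinely mosaics of two families joined at
recurrent breakpoints, descended from a recombinant founder that amplified.
Second, a family's copy set may contain *subfamilies*: cohorts descended
from a distinct ancestral variant, recognisable because their alignments to
the family consensus consistently stop matching at a shared position (a
diagnostic deletion, insertion or truncation). This package implements the
full discovery loop: train alignment rates, competitively partition the
genome among consensuses, detect recurrent hybrids, split families into
subfamilies, rebuild consensuses, and characterise the results by
divergence statistics, phylogeny and cross-species insertion age.

Everything is exercised on a bundled genome simulator with machine-readable
truth, so each stage has a measurable recovery target.

## Scoring model

`train_model()` estimates substitution and gap rates between repeat
instances and consensuses by an align/count/rescore loop, starting from a
permissive +1/−1 model (gap open 7, extend 1). Each round aligns every
instance to its best-matching consensus, tallies a 4×4 substitution count
matrix and affine gap events (a run of length L is one open and L−1
extends), and converts the rates to integer log-odds scores
`round(ln(p_xy / (q_x q_y)) / scale)`, with a pseudocount of 0.5 per cell
so no score is −∞. The scale defaults to eighth-bit units and widens
automatically so no score magnitude exceeds 120, keeping the dynamic
program in small integers; it is recorded in the model. Iteration stops
when no rate moves by more than `tol` (default 1e−4); on desk-scale data
any reasonable start converges in 2–4 rounds.

One estimation detail matters: gap runs longer than `max_gap_run`
(default 20 bp) are excluded from the gap tallies. Instances aligned to a
single-family consensus can contain very long gaps that are *structural* —
hybrid joins, subfamily diagnostic indels, truncations — not draws from the
per-site indel process. Counting them inflates the gap-open probability
several-fold, which makes gap costs so cheap that alignments bridge
unrelated sequence; with the cap, trained costs on simulated data come out
near open ≈ 45–55, extend ≈ 2–5 in eighth-bit units, and alignments stay
tight.

## Competitive genome partition

`local_align()` produces Smith–Waterman-style affine-gap local alignments
of each consensus to a genomic window, on both strands, reporting *all*
non-overlapping local maxima above a score floor. Internally the engine
finds the best hit and then recurses into the two flanks; because no local
alignment can cross a claimed genome interval, this is equivalent to
iterative masking but scans each region only O(log hits) times.

`partition_alignments()` then assigns each genome base to at most one
consensus base. It maximises, over all ways of cutting the candidate
alignments into contiguous pieces and laying them out without overlap,

> Σ (truncated piece scores) − switch_penalty × (adjacent piece pairs)

where a truncated piece is rescored from its surviving columns (gap runs
re-opened where a cut splits them, consensus-gap runs kept only when both
flanking genome positions survive). Two design points deserve note:

* The penalty is charged between *every* consecutive pair of pieces, not
  only pairs from different parent alignments. If same-parent pieces were
  free, the optimum would split an alignment around every isolated
  mismatch (dropping a negative column costs nothing), shredding the
  annotation; we observed exactly this degenerate behaviour before
  adopting the uniform penalty. Family switches are still what the penalty
  prices in practice, since contiguous same-candidate runs are one piece.
* Among equal-score solutions, fewer pieces win (an infinitesimal
  tie-break in the dynamic program).

The default `switch_penalty` is twice the trained gap-open cost. The
partition dynamic program is exact; the test suite checks it against
exhaustive enumeration over all per-position assignments on 1000 random
small instances, scoring pieces with an independent implementation of the
truncation rule. `annotate_genome()` applies the partition per overlapping
window (default 50 kb windows, 2 kb overlap — the overlap must exceed the
longest expected element) and resolves window-boundary duplicates.

## Hybrid elements

`assemble_elements()` merges segments within `max_gap` (default 100 bp)
into elements. Adjacent segments matching the *same* family collapse into
one composition part — a breakpoint is by definition the consensus position
at which one family's match is replaced by *another* family's. Elements
lying entirely on the minus strand are reported in consensus-forward
order so both strands of the same hybrid share a composition signature.
`cluster_hybrids()` groups hybrids with identical ordered compositions and
single-links them on the Chebyshev distance over their breakpoint
coordinate vectors, cut at `breakpoint_tol` (default 15 bp; the paper-scale
claim is only that breakpoints are "roughly fixed", so the per-coordinate
median absolute deviation is reported for auditing).
`promote_class_to_family()` turns a recurrent class (≥ `min_copies`
members, default 20) into a new family: consensus seeded and refined from
the member sequences, parent families and median breakpoints recorded as
the diagnostic feature.

## Consensus building

`seed_consensus()` mirrors self-comparison with a high minimum score:
all-vs-all local alignment, scores below `min_score` (default 2000, about
130–260 well-matched bases under trained models) discarded, and the
instance with the largest summed score to the others becomes the seed;
ties break to input order. `refine_consensus()` then iterates: semi-global
alignment of every instance to the consensus; per column, an edit needs a
strict majority (> 50%) of covering instances — replacement by the majority
base, deletion when a majority gaps the column, and insertion of a block at
a junction where a majority inserts a run of the same modal length.
Columns covered by fewer than `min_coverage` (default 3) instances are
never edited, which guards consensus edges against erosion. Ties keep the
current base: stability over churn. Iteration stops at a fixed point
(typically 2–3 rounds); on 50 copies at 5% substitution the refined
consensus is within 1% of the true ancestral sequence, and at zero noise it
is exact.

## Subfamily discovery

`detect_cohort()` extracts, per instance, the consensus blocks its
alignment skips: internal deletions, prefix/suffix truncations, and
insertion runs keyed to a consensus junction, ignoring features shorter
than `boundary_tol` (default 10 bp, indistinguishable from alignment
noise). Features of the same type are single-linkage clustered on their
interval endpoints within `boundary_tol`; the largest cluster with support
≥ `min_support` becomes the split cohort. The default
`min_support = max(10, 5% of family size)` operationalises "a significant
number of sequences" and is configurable.

`split_family()` removes the cohort, builds its consensus, and re-refines
the parent from the remainder; a split that would empty the parent is an
error. `iterate_splitting()` repeats refine → detect → split on every
family, including newly created ones (so a promoted hybrid family can
itself split, the aba→subaba pattern), until nothing is detected. Splits
are greedy largest-first; there is no simultaneous multi-way split. The
residual parent keeps the family name; subfamilies are named
`<family>_sub1`, `_sub2`, …

On the bundled conditions (130 instances, planted cohorts of 40 and 30
with ≥ 20 bp diagnostic indels, 8% divergence) the loop returns exactly
three subfamilies at ≥ 0.9 member precision and recall, and across 100
homogeneous families the false-split rate is ≤ 5%.

## Statistics

`pairwise_stats()` reports the CrossMatch-style convention: percent
divergence = mismatched aligned columns / *ungapped* aligned columns × 100;
percent indel = gap characters / *total* alignment columns × 100. The two
denominators differ on purpose; published repeat statistics follow this
convention and it is fixed and documented here. Percentages are rounded
half-up to two decimals for reporting. Local-mode comparisons below the
score floor return an explicit "no significant match" row, not an error.

## Phylogeny

`select_full_length()` keeps instances longer than 300 bp (strict, per
"larger than") that start TG and end CA, the canonical retroviral terminal
dinucleotides. `build_reference_msa()` aligns each instance independently
to a reference consensus; consensus positions define shared columns and
instance insertions become insertion columns merged by exact junction.
This reference-anchored construction scales linearly, and it makes the
subfamily signal explicit: a diagnostic deletion appears as a shared gap
block in cohort rows. The cost relative to progressive MSA is that
insertion columns from different junctions are never aligned to each
other; for divergence-level questions on a common reference this is
immaterial. `filter_columns()` keeps columns whose non-gap fraction is at
least `gt` (default 0.01 — with 100 rows one non-gap character suffices,
matching the "at least 1%" rule), and is idempotent.

Distances use pairwise deletion and a choice of p, Jukes–Cantor or Kimura
2-parameter corrections via `ape::dist.dna()`; saturated pairs are set to
the maximum finite distance and flagged, pairs with zero comparable columns
stay undefined and flagged. `nj_tree()` is canonical neighbor joining
(`ape::nj()`), with negative branch lengths clamped to zero and the deficit
moved to the sister branch. Neighbor joining replaces approximate
maximum likelihood deliberately: it is deterministic, dependency-free and
oracle-testable (additive matrices are recovered exactly), and the claim
being checked — instances of the same subfamily cluster together — is
robust to the tree method. The test statistic is the *cohesion*: the
fraction of leaves whose nearest leaf by path length belongs to the same
subfamily. Bootstrap support is out of scope.

## Insertion age

`shared_counts()` counts, per subfamily, how many focal-genome instances
have an ortholog in each other species: the instance's interval is carried
across by a liftover-style mapping table (the simulator emits one from
truth; real analyses can supply UCSC liftOver output) and counts as shared
when the mapped interval overlaps a same-subfamily annotation by at least
`min_overlap` (default 0.5, focal-side fraction — the simplest auditable
rule). Counts must be non-increasing with divergence age on a ladder tree;
violations are surfaced via the `monotone` attribute. `bracket_age()`
converts a presence pattern into an age bracket: oldest crossed split ≤
insertion age < next older split, with non-monotone patterns flagged as
homoplasy/loss rather than forced into a bracket.

## The simulator and what it does (not) show

`simulate_genomes()` is the package's test substrate and defines the study
conditions. An ancestral master per family (TG…CA termini) amplifies in
bursts on a ladder species tree; a copy of age *t* accumulates
Binomial(L, sub_rate·t) substitutions (always to a different base, so the
logged count is the mismatch count) and Poisson(L·indel_rate·t) indels
with geometric lengths (the field reports no canonical indel length law
for MLT2; geometric with p = 0.3 is a modelling choice, mean ≈ 3 bp).
Subfamily founders apply an exact diagnostic indel at a fixed consensus
position and additionally carry *founder drift*: the substitutions accrued
between the family's origin (its oldest burst) and the founder's birth.
Drift is what makes a subfamily a distinct ancestral variant; without it,
copies of an indel-only founder are equidistant from everything in
substitution space and no tree method could cluster them. Hybrid founders
are exact joins of the family consensuses at fixed breakpoints (two-part
A–B or three-part A–B–A), plus the same drift when configured younger than
their parents' origin. Copies insert on random strands at orthologous
positions in every species whose split is younger than the copy.

Defaults: master lengths 453/550 bp (MLT2A2/MLT2B3-like), sub_rate 0.01
per site per time unit (so age 8 ⇒ 8% divergence), indel_rate 0.001,
background 250–300 bp of 42% GC intergenic sequence between insertions,
ladder splits at ages 4/7/10. Deliberately not modelled: selection, gene
conversion, CpG hypermutation, nested insertions, lineage-specific rate
variation after speciation (orthologous copies share one mutated
sequence). Consequently, passing tests show the *pipeline logic* is
correct under the stated generative model; they do not show robustness to
CpG-driven rate heterogeneity or to segmental duplications in real
genomes.

## Numerical choices and degenerate inputs

* Gap cost convention everywhere: first gap character costs `gap_open`,
  each further one `gap_extend` (so a 3-bp gap is one open, two extends).
* Alignment windows shorter than 10 bp warn and return no hits; an empty
  consensus library is an error; an empty alignment list to
  `count_events()` is an error distinct from zero counts.
* Segments shorter than 20 bp are dropped from annotations (sub-seed
  fragments are noise).
* `detect_cohort()` returning nothing is a result, not an error; a cohort
  equal to the whole family refuses to split.
* N bases never score as matches (they get the worst off-diagonal score)
  and are excluded from all substitution and divergence tallies.
* The problem sizes in the tests and the acceptance script — 1000
  enumeration instances, 100 hybrid copies, 130-instance families, 100
  null families of 40 copies, 75-instance trees — were chosen as the
  smallest sets at which the recovery statistics stabilise; they run on a
  laptop-class single core in minutes.

## Known limitations

The partition is score-optimal, not probability-based: it approximates a
posterior split with a fixed switch penalty, trading calibrated
probabilities for determinism and an exhaustive-enumeration oracle.
Training is a point estimate without per-family or position-specific
rates, and no low-complexity masking is applied. The reference-anchored
MSA cannot represent homology between insertions of different instances.
Real liftover chains are not parsed; cross-species sharing needs a
precomputed interval mapping. Trees are built per homologous clan: under
pairwise deletion, distances between sequences with no alignable columns
are undefined, so instance sets anchored to different, unrelated
references get separate trees (in real MLT2 data all subfamilies share
ancestry and one tree suffices; the simulator's family masters are
independent random sequences and do not). None of these affect the discovery loop's
correctness on the simulator; all of them matter when calibrating absolute
ages or rates on real genomes.
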