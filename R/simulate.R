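# Genome simulator: LTR families amplifying in bursts on a ladder species
# tree, with subfamily founders carrying fixed diagnostic indels, recurrent
# hybrid founders joining two family consensuses at fixed breakpoints, and
# machine-readable truth for every inserted copy.

#' Simulation configuration
#'
#' Defines the generative model: one master consensus per family (TG...CA
#' termini), amplification bursts whose copies accumulate age-proportional
#' substitutions and indels, subfamily founders carrying an exact diagnostic
#' indel at a fixed consensus position shared by the whole cohort, recurrent
#' hybrid founders joining two family consensuses at fixed breakpoints, and a
#' ladder species tree (focal lineage with successively older outgroup
#' splits) so copies inserted after a split are lineage specific.
#'
#' Time is in divergence units: a copy of age `a` has expected
#' `sub_rate * a` substitutions per site, so `sub_rate = 0.01` and age 8
#' give 8% divergence from the founder.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @param master_length master consensus length (bp) of the default family.
#' @param family_lengths named integer vector of family master lengths.
#' @param n_copies_per_burst,burst_times convenience: each burst time gets
#'   this many copies of the first family. Use `bursts` for full control.
#' @param bursts optional data.frame with columns `time`, `family`,
#'   `n_copies` overriding the convenience fields.
#' @param sub_rate substitutions per site per time unit.
#' @param indel_rate indel events per site per time unit.
#' @param indel_length_geometric_p geometric length parameter of aging
#'   indels (mean length `1/p`).
#' @param subfamily_events list; each element a list with `time`,
#'   `type` ("deletion" or "insertion"), `position` (0-based consensus
#'   position), `length`, `n_copies`, optional `family` (a family name or a
#'   hybrid event name, so hybrids can spawn subfamilies) and `name`.
#' @param hybrid_events list; each element a list with `time`, `family_a`,
#'   `family_b`, `breakpoint_a`, `breakpoint_b`, `n_copies`, optional
#'   `breakpoint_b2`/`breakpoint_a2` (three-part A-B-A join) and `name`.
#' @param speciation_times ascending split ages of the ladder tree; split i
#'   creates outgroup species i.
#' @param background_length bp of random intergenic sequence between
#'   insertions.
#' @param gc_content background and master GC fraction.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              master_length = 500L,
                              family_lengths = c(famA = master_length),
                              n_copies_per_burst = 20L,
                              burst_times = 5,
                              bursts = NULL,
                              sub_rate = 0.01,
                              indel_rate = 0.001,
                              indel_length_geometric_p = 0.3,
                              subfamily_events = list(),
                              hybrid_events = list(),
                              speciation_times = numeric(),
                              background_length = 300L,
                              gc_content = 0.42) {
  if (is.null(names(family_lengths)))
    stop("family_lengths must be named")
  if (any(c(sub_rate, indel_rate) < 0))
    stop("rates must be >= 0")
  if (indel_length_geometric_p <= 0 || indel_length_geometric_p > 1)
    stop("indel_length_geometric_p must be in (0, 1]")
  if (is.null(bursts)) {
    bursts <- data.frame(time = burst_times,
                         family = names(family_lengths)[1],
                         n_copies = n_copies_per_burst,
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("time", "family", "n_copies") %in% names(bursts)))
  if (!all(bursts$family %in% names(family_lengths)))
    stop("burst family not in family_lengths")
  oldest <- if (nrow(bursts)) max(bursts$time) else Inf
  # hybrid founder lengths, so subfamily events may target a hybrid family
  hyb_len <- numeric(0)
  hi <- 0L
  for (ev in hybrid_events) {
    hi <- hi + 1L
    nm <- ev$name %||% paste0("hybrid", hi)
    La <- if (ev$family_a %in% names(family_lengths))
      family_lengths[[ev$family_a]] else NA
    Lb <- if (ev$family_b %in% names(family_lengths))
      family_lengths[[ev$family_b]] else NA
    if (!is.na(La) && !is.na(Lb))
      hyb_len[nm] <- if (is.null(ev$breakpoint_b2))
        ev$breakpoint_a + (Lb - ev$breakpoint_b)
      else ev$breakpoint_a + (ev$breakpoint_b2 - ev$breakpoint_b) +
        (La - ev$breakpoint_a2)
  }
  for (ev in subfamily_events) {
    fam <- ev$family %||% names(family_lengths)[1]
    L <- if (fam %in% names(family_lengths)) family_lengths[[fam]]
         else if (fam %in% names(hyb_len)) hyb_len[[fam]]
         else stop("unknown subfamily parent family ", fam)
    if (!ev$type %in% c("deletion", "insertion"))
      stop("subfamily event type must be deletion or insertion")
    if (ev$position < 2 || ev$position + ev$length > L - 2)
      stop("diagnostic feature must lie strictly inside the consensus ",
           "(position + length <= master_length - 2)")
    if (ev$time > oldest)
      stop("configuration error: subfamily event at time ", ev$time,
           " is older than the oldest amplification burst (", oldest, ")")
  }
  for (ev in hybrid_events) {
    for (f in c(ev$family_a, ev$family_b))
      if (!f %in% names(family_lengths)) stop("unknown hybrid family ", f)
    La <- family_lengths[[ev$family_a]]; Lb <- family_lengths[[ev$family_b]]
    if (ev$breakpoint_a <= 0 || ev$breakpoint_a >= La ||
        ev$breakpoint_b < 0 || ev$breakpoint_b >= Lb)
      stop("hybrid breakpoints must lie within the family consensuses")
    if (!is.null(ev$breakpoint_b2) &&
        (ev$breakpoint_b2 <= ev$breakpoint_b || ev$breakpoint_b2 > Lb ||
         is.null(ev$breakpoint_a2) || ev$breakpoint_a2 >= La))
      stop("three-part hybrid breakpoints are inconsistent")
    if (ev$time > oldest)
      stop("configuration error: hybrid event at time ", ev$time,
           " is older than the oldest amplification burst (", oldest, ")")
  }
  if (is.unsorted(speciation_times, strictly = TRUE) && length(speciation_times) > 1)
    stop("speciation_times must be strictly increasing (ages)")
  structure(list(seed = as.integer(seed), family_lengths = family_lengths,
                 bursts = bursts, sub_rate = sub_rate,
                 indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 subfamily_events = subfamily_events,
                 hybrid_events = hybrid_events,
                 speciation_times = speciation_times,
                 background_length = as.integer(background_length),
                 gc_content = gc_content),
            class = "sim_config")
}

# master with canonical retroviral termini
.make_master <- function(len, gc) {
  paste0("TG", random_dna(len - 4L, gc), "CA")
}

.mutate_copy <- function(seq, age, cfg) {
  L <- nchar(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- stats::rbinom(1L, L, min(1, cfg$sub_rate * age))
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    for (p in pos) v[p] <- sample(setdiff(.BASES, v[p]), 1L)
  }
  n_ind <- stats::rpois(1L, L * cfg$indel_rate * age)
  if (n_ind > 0) {
    for (k in seq_len(n_ind)) {
      len <- stats::rgeom(1L, cfg$indel_length_geometric_p) + 1L
      if (stats::runif(1) < 0.5 && length(v) > len + 4L) { # deletion
        p <- sample.int(length(v) - len, 1L)
        v <- v[-(p:(p + len - 1L))]
      } else { # insertion
        p <- sample.int(length(v), 1L)
        ins <- sample(.BASES, len, replace = TRUE)
        v <- append(v, ins, after = p)
      }
    }
  }
  list(seq = paste(v, collapse = ""), n_sub = n_sub, n_ind = n_ind)
}

#' Simulate per-species genomes with known repeat truth
#'
#' Every copy starts from its founder sequence (family master, subfamily
#' founder with the diagnostic indel applied, or hybrid founder joined
#' exactly at the configured breakpoints), accumulates `sub_rate * age`
#' substitutions per site and `indel_rate * age` indel events per site, and
#' is inserted on a random strand at an orthologous position in every
#' species whose split from the focal lineage is younger than the copy.
#'
#' @param config a [simulation_config()].
#' @return object of class `ltr_sim`: `genomes` (named character, one
#'   sequence per species), `truth` (one row per copy: copy_id, family,
#'   subfamily, insertion_time, strand, n_subst, n_indel, length,
#'   species_presence), `intervals` (copy_id, species, start, end; 0-based
#'   half-open), `breakpoints` (copy_id, consensus_name,
#'   consensus_position), `masters`, `founders`, `species`, `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  masters <- vapply(cfg$family_lengths, .make_master, "",
                    gc = cfg$gc_content)
  founders <- character(0)
  # assemble the copy roster: (founder sequence, family, subfamily, time, bp)
  roster <- list()
  add <- function(founder, family, subfam, time, n, bps = NULL) {
    for (i in seq_len(n))
      roster[[length(roster) + 1L]] <<- list(founder = founder,
                                             family = family,
                                             subfamily = subfam,
                                             time = time, bps = bps)
  }
  for (i in seq_len(nrow(cfg$bursts)))
    add(masters[[cfg$bursts$family[i]]], cfg$bursts$family[i],
        cfg$bursts$family[i], cfg$bursts$time[i], cfg$bursts$n_copies[i])
  # family origin = oldest burst of that family; founders arising later on
  # the family lineage carry their own drift substitutions accumulated
  # since the origin, which is what makes a subfamily a distinct ancestral
  # variant (and lets trees cluster its copies)
  origin <- vapply(names(cfg$family_lengths), function(f) {
    tt <- cfg$bursts$time[cfg$bursts$family == f]
    if (length(tt)) max(tt) else NA_real_
  }, 0)
  hi <- 0L
  for (ev in cfg$hybrid_events) {
    hi <- hi + 1L
    nm <- ev$name %||% paste0("hybrid", hi)
    ma <- masters[[ev$family_a]]; mb <- masters[[ev$family_b]]
    if (is.null(ev$breakpoint_b2)) {
      fs <- paste0(substr(ma, 1, ev$breakpoint_a),
                   substr(mb, ev$breakpoint_b + 1, nchar(mb)))
      bps <- data.frame(consensus_name = c(ev$family_a, ev$family_b),
                        consensus_position = c(ev$breakpoint_a, ev$breakpoint_b),
                        stringsAsFactors = FALSE)
    } else {
      fs <- paste0(substr(ma, 1, ev$breakpoint_a),
                   substr(mb, ev$breakpoint_b + 1, ev$breakpoint_b2),
                   substr(ma, ev$breakpoint_a2 + 1, nchar(ma)))
      bps <- data.frame(consensus_name = c(ev$family_a, ev$family_b,
                                           ev$family_b, ev$family_a),
                        consensus_position = c(ev$breakpoint_a, ev$breakpoint_b,
                                               ev$breakpoint_b2, ev$breakpoint_a2),
                        stringsAsFactors = FALSE)
    }
    par_origin <- suppressWarnings(max(origin[c(ev$family_a, ev$family_b)],
                                       na.rm = TRUE))
    drift <- max(0, (if (is.finite(par_origin)) par_origin else ev$time) -
                   ev$time)
    if (drift > 0) fs <- .mutate_copy(fs, drift, cfg)$seq
    founders[nm] <- fs
    origin[nm] <- ev$time
    add(fs, nm, nm, ev$time, ev$n_copies, bps)
  }
  si <- 0L
  for (ev in cfg$subfamily_events) {
    si <- si + 1L
    fam <- ev$family %||% names(cfg$family_lengths)[1]
    nm <- ev$name %||% paste0(fam, "_sub", si)
    m <- if (fam %in% names(masters)) masters[[fam]] else founders[[fam]]
    fs <- if (ev$type == "deletion") {
      paste0(substr(m, 1, ev$position), substr(m, ev$position + ev$length + 1, nchar(m)))
    } else {
      paste0(substr(m, 1, ev$position), random_dna(ev$length, cfg$gc_content),
             substr(m, ev$position + 1, nchar(m)))
    }
    drift <- max(0, (if (is.na(origin[fam])) ev$time else origin[fam]) - ev$time)
    if (drift > 0) fs <- .mutate_copy(fs, drift, cfg)$seq
    founders[nm] <- fs
    add(fs, fam, nm, ev$time, ev$n_copies)
  }
  n <- length(roster)
  species <- c("focal",
               if (length(cfg$speciation_times))
                 paste0("outgroup", seq_along(cfg$speciation_times)))
  # mutate copies and decide strand/presence
  ord <- if (n > 1) sample.int(n) else seq_len(n)
  copies <- vector("list", n)
  for (k in seq_len(n)) {
    r <- roster[[ord[k]]]
    mut <- .mutate_copy(r$founder, r$time, cfg)
    idx <- which(cfg$speciation_times < r$time)
    pres <- c("focal", if (length(idx)) paste0("outgroup", idx))
    copies[[k]] <- c(r, mut, list(strand = sample(c("+", "-"), 1L),
                                  presence = pres,
                                  copy_id = sprintf("copy_%04d", k)))
  }
  blocks <- replicate(n + 1L, random_dna(cfg$background_length, cfg$gc_content))
  genomes <- stats::setNames(character(length(species)), species)
  ivs <- list()
  for (sp in species) {
    parts <- character(0)
    pos <- 0L
    for (k in seq_len(n)) {
      parts <- c(parts, blocks[k])
      pos <- pos + nchar(blocks[k])
      cp <- copies[[k]]
      if (sp %in% cp$presence) {
        s <- if (cp$strand == "+") cp$seq else revcomp(cp$seq)
        parts <- c(parts, s)
        ivs[[length(ivs) + 1L]] <- data.frame(copy_id = cp$copy_id,
                                              species = sp, start = pos,
                                              end = pos + nchar(s),
                                              stringsAsFactors = FALSE)
        pos <- pos + nchar(s)
      }
    }
    parts <- c(parts, blocks[n + 1L])
    genomes[sp] <- paste(parts, collapse = "")
  }
  truth <- do.call(rbind, lapply(copies, function(cp)
    data.frame(copy_id = cp$copy_id, family = cp$family,
               subfamily = cp$subfamily, insertion_time = cp$time,
               strand = cp$strand, n_subst = cp$n_sub, n_indel = cp$n_ind,
               length = nchar(cp$seq),
               species_presence = paste(cp$presence, collapse = ","),
               stringsAsFactors = FALSE)))
  if (is.null(truth))
    truth <- data.frame(copy_id = character(), family = character(),
                        subfamily = character(), insertion_time = numeric(),
                        strand = character(), n_subst = integer(),
                        n_indel = integer(), length = integer(),
                        species_presence = character(),
                        stringsAsFactors = FALSE)
  bptab <- do.call(rbind, lapply(copies, function(cp)
    if (!is.null(cp$bps)) cbind(data.frame(copy_id = cp$copy_id,
                                           stringsAsFactors = FALSE), cp$bps)))
  if (is.null(bptab))
    bptab <- data.frame(copy_id = character(), consensus_name = character(),
                        consensus_position = numeric(),
                        stringsAsFactors = FALSE)
  intervals <- if (length(ivs)) do.call(rbind, ivs) else
    data.frame(copy_id = character(), species = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  structure(list(genomes = genomes, truth = truth, intervals = intervals,
                 breakpoints = bptab, masters = masters, founders = founders,
                 species = species, config = cfg),
            class = "ltr_sim")
}

#' @export
print.ltr_sim <- function(x, ...) {
  cat(sprintf("ltr_sim: %d copies, %d species, genome %d bp (focal)\n",
              nrow(x$truth), length(x$species), nchar(x$genomes[["focal"]])))
  invisible(x)
}

#' Extract the focal-genome sequences of simulated copies
#'
#' Returns copies oriented to the consensus strand (minus-strand insertions
#' are reverse complemented), named by copy id.
#' @param sim an `ltr_sim`.
#' @param copy_ids subset of copy ids (default all present in focal).
#' @return named character vector of sequences.
#' @export
sim_copy_sequences <- function(sim, copy_ids = NULL) {
  iv <- sim$intervals[sim$intervals$species == "focal", , drop = FALSE]
  if (!is.null(copy_ids)) iv <- iv[iv$copy_id %in% copy_ids, , drop = FALSE]
  g <- sim$genomes[["focal"]]
  out <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    s <- substr(g, iv$start[i] + 1L, iv$end[i])
    st <- sim$truth$strand[match(iv$copy_id[i], sim$truth$copy_id)]
    out[i] <- if (st == "+") s else revcomp(s)
  }
  stats::setNames(out, iv$copy_id)
}

#' Write simulation truth to BED6+ and TSV files
#'
#' One BED6+ file per species (name = copy id, score 0, extra columns
#' subfamily label and insertion time) plus `truth.tsv` (one row per copy)
#' and `breakpoints.tsv`. Coordinates follow BED convention (0-based
#' half-open). The files round-trip losslessly through [read_truth()].
#'
#' @param sim an `ltr_sim` (or a compatible list with `truth`, `intervals`,
#'   `breakpoints`, `species`).
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written file paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in sim$species) {
    iv <- sim$intervals[sim$intervals$species == sp, , drop = FALSE]
    i <- match(iv$copy_id, sim$truth$copy_id)
    p <- file.path(dir, paste0(sp, ".bed"))
    if (nrow(iv) == 0L) {
      file.create(p)
    } else {
      bed <- data.frame(chrom = "chr1", start = iv$start, end = iv$end,
                        name = iv$copy_id, score = 0L,
                        strand = sim$truth$strand[i],
                        subfamily = sim$truth$subfamily[i],
                        insertion_time = sim$truth$insertion_time[i])
      utils::write.table(bed, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "breakpoints.tsv")
  utils::write.table(sim$breakpoints, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  writeLines(sim$species, file.path(dir, "species.txt"))
  invisible(c(paths, file.path(dir, "species.txt")))
}

#' Read truth files written by [write_truth()]
#' @param dir directory containing the files.
#' @return list with `truth`, `intervals`, `breakpoints`, `species`.
#' @export
read_truth <- function(dir) {
  species <- readLines(file.path(dir, "species.txt"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(copy_id = "character"))
  bp <- utils::read.table(file.path(dir, "breakpoints.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(copy_id = "character"))
  ivs <- list()
  for (sp in species) {
    p <- file.path(dir, paste0(sp, ".bed"))
    if (file.size(p) == 0) next
    bed <- utils::read.table(p, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    ivs[[sp]] <- data.frame(copy_id = as.character(bed[[4]]), species = sp,
                            start = bed[[2]], end = bed[[3]],
                            stringsAsFactors = FALSE)
  }
  intervals <- if (length(ivs)) do.call(rbind, c(ivs, make.row.names = FALSE))
  else data.frame(copy_id = character(), species = character(),
                  start = integer(), end = integer(),
                  stringsAsFactors = FALSE)
  list(truth = truth, intervals = intervals, breakpoints = bp,
       species = species)
}

#' Write simulated genomes as one FASTA per species
#' @param sim an `ltr_sim`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_genomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in sim$species) {
    p <- file.path(dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(sim$genomes[sp], "chr1")), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Orthology mapping table from simulation truth
#'
#' Focal-genome interval of every copy mapped to its orthologous interval in
#' each species where it is present; the simulated stand-in for a liftover
#' chain. Columns: focal_chrom, focal_start, focal_end, copy_id, species,
#' mapped_chrom, mapped_start, mapped_end.
#' @param sim an `ltr_sim`.
#' @return data.frame mapping table.
#' @export
orthology_map <- function(sim) {
  foc <- sim$intervals[sim$intervals$species == "focal", , drop = FALSE]
  oth <- sim$intervals[sim$intervals$species != "focal", , drop = FALSE]
  m <- match(oth$copy_id, foc$copy_id)
  keep <- !is.na(m)
  data.frame(focal_chrom = "chr1", focal_start = foc$start[m[keep]],
             focal_end = foc$end[m[keep]], copy_id = oth$copy_id[keep],
             species = oth$species[keep], mapped_chrom = "chr1",
             mapped_start = oth$start[keep], mapped_end = oth$end[keep],
             stringsAsFactors = FALSE)
}
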