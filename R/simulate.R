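# Synthetic ortholog families with known signal peptide histories.
#
# The generator evolves protein families along a species tree under a simple
# per-branch event model: a lineage carrying a signal peptide may lose it, a
# lineage without one may gain it, and each event proceeds either by a
# whole-segment indel (the N-terminal segment is inserted or deleted as a
# unit, leaving alignment gaps) or by point substitutions (the segment keeps
# its length and residues are mutated to create or destroy the tripartite
# architecture). Because the indel history is simulated explicitly, the true
# multiple alignment, the true per-node states and the planted events are all
# known exactly and are emitted as ground truth.

SP_N_ALPHABET <- c("K", "R", "N", "Q", "S", "T", "A")
SP_H_ALPHABET <- c("A", "L", "V", "I", "F", "M")
SP_C_ALPHABET <- c("S", "T", "N", "Q", "G")
POLAR_BREAKERS <- c("D", "E", "N", "Q", "P")

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' chosen to mirror a desk-scale version of an enterobacterial ortholog
#' dataset: 153 species with lifestyle fractions 120:21:12
#' (free-living : endosymbiont : commensal), endosymbiont genomes several
#' times smaller than free-living ones, signal peptide losses four times more
#' frequent than gains, and a 4:1 indel-to-substitution mechanism mix.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_species Number of species (at least 3).
#' @param lifestyle_fractions Probabilities for free-living, endosymbiont and
#'   commensal lifestyles (must sum to 1).
#' @param n_families Number of ortholog families to simulate.
#' @param family_size_range Minimum (at least 3) and maximum family size.
#' @param ancestor_sp_prob Probability that a family's root carries a signal
#'   peptide.
#' @param sp_gain_rate,sp_loss_rate Per-branch probabilities of a gain on a
#'   signal-peptide-free lineage and of a loss on a signal-peptide-bearing
#'   lineage.
#' @param mechanism_mix Probability that an event proceeds by whole-segment
#'   indel rather than by substitutions.
#' @param start_error_rate Fraction of signal-peptide-bearing members whose
#'   annotated gene start is corrupted (moved downstream past the signal
#'   peptide).
#' @param start_shift_range Extra residues past the signal peptide within
#'   which the corrupting downstream start is searched.
#' @param predictor_noise Named numeric vector of per-tool call flip
#'   probabilities (`signalp`, `phobius`, `tatp`).
#' @param substitution_rate Per-site per-branch background substitution
#'   probability (mature sequence only; active signal peptides change only
#'   through events).
#' @param tat_fraction Fraction of secreted-ancestor families whose signal
#'   peptide is of the twin-arginine (Tat) type.
#' @param seq_len_range Length range of the mature (body) sequence.
#' @param genome_size_mean,genome_size_sd Named vectors (per lifestyle) for
#'   the nominal genome sizes.
#' @param context_nt Genomic context emitted on each side of a coding
#'   sequence.
#' @return Object of class `sp_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 153L,
                       lifestyle_fractions = c(free_living = 120, endosymbiont = 21,
                                               commensal = 12) / 153,
                       n_families = 500L,
                       family_size_range = c(3L, 153L),
                       ancestor_sp_prob = 0.15,
                       sp_gain_rate = 0.005,
                       sp_loss_rate = 0.02,
                       mechanism_mix = 0.8,
                       start_error_rate = 0.1,
                       start_shift_range = c(0L, 30L),
                       predictor_noise = c(signalp = 0, phobius = 0, tatp = 0),
                       substitution_rate = 0.02,
                       tat_fraction = 0.02,
                       seq_len_range = c(120L, 360L),
                       genome_size_mean = c(free_living = 3596, endosymbiont = 1066,
                                            commensal = 3730),
                       genome_size_sd = c(free_living = 600, endosymbiont = 250,
                                          commensal = 600),
                       context_nt = 300L) {
  cfg <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    lifestyle_fractions = lifestyle_fractions,
    n_families = as.integer(n_families),
    family_size_range = as.integer(family_size_range),
    ancestor_sp_prob = ancestor_sp_prob,
    sp_gain_rate = sp_gain_rate, sp_loss_rate = sp_loss_rate,
    mechanism_mix = mechanism_mix,
    start_error_rate = start_error_rate,
    start_shift_range = as.integer(start_shift_range),
    predictor_noise = predictor_noise,
    substitution_rate = substitution_rate,
    tat_fraction = tat_fraction,
    seq_len_range = as.integer(seq_len_range),
    genome_size_mean = genome_size_mean,
    genome_size_sd = genome_size_sd,
    context_nt = as.integer(context_nt)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sp_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_species < 3L) abort("invalid configuration: n_species must be >= 3")
  probs <- c(cfg$lifestyle_fractions, cfg$ancestor_sp_prob, cfg$mechanism_mix,
             cfg$start_error_rate, cfg$predictor_noise, cfg$tat_fraction,
             cfg$substitution_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("invalid configuration: all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$lifestyle_fractions) - 1) > 1e-8) {
    abort("invalid configuration: lifestyle_fractions must sum to 1")
  }
  if (cfg$sp_gain_rate < 0 || cfg$sp_loss_rate < 0) {
    abort("invalid configuration: rates must be nonnegative")
  }
  if (cfg$family_size_range[1] < 3L) {
    abort("invalid configuration: family_size_range minimum must be >= 3")
  }
  invisible(cfg)
}

#' @export
print.sp_sim_config <- function(x, ...) {
  cat(sprintf("<sp_sim_config> %d species, %d families, seed %d\n",
              x$n_species, x$n_families, x$seed))
  invisible(x)
}

# ---- taxonomy and species tree --------------------------------------------

# join a list of (newick string, is_leaf) subtrees pairwise at random into a
# single binary rooted subtree with positive branch lengths
join_random <- function(parts, depth_scale = 1) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 1L)
    rest <- setdiff(seq_along(parts), i)
    j <- rest[sample.int(length(rest), 1L)]
    bl <- stats::runif(2, 0.02, 0.3) * depth_scale
    merged <- sprintf("(%s:%g,%s:%g)", parts[[i]], bl[1], parts[[j]], bl[2])
    parts <- c(parts[-c(i, j)], merged)
  }
  parts[[1]]
}

#' Simulate a taxonomy and species tree
#'
#' Creates `n_species` species nested into genera and families of one order,
#' with a rooted bifurcating species tree whose clades are consistent with
#' the taxonomy (each genus is a clade, each family a clade of genera).
#' Lifestyles are assigned independently per species according to
#' `lifestyle_fractions`, and nominal genome sizes are drawn per lifestyle
#' (endosymbiont genomes have a much smaller mean).
#'
#' @param config An [sim_config()] object.
#' @return List with `species` (tibble: `species_id`, `order`, `family`,
#'   `genus`, `lifestyle`, `lifestyle_code`, `genome_size`) and `tree` (rooted
#'   binary `phylo`, tips = species ids).
#' @export
simulate_taxonomy <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_species
    n_genera <- max(2L, ceiling(n / 6))
    n_fams <- max(2L, ceiling(n_genera / 5))
    genus_of_species <- sort(c(seq_len(n_genera),
                               sample.int(n_genera, n - n_genera, replace = TRUE)))
    family_of_genus <- sort(c(seq_len(n_fams),
                              sample.int(n_fams, n_genera - n_fams, replace = TRUE)))

    species_id <- sprintf("s%03d", seq_len(n))
    genus <- sprintf("g%02d", genus_of_species)
    family <- sprintf("f%02d", family_of_genus[genus_of_species])

    lifestyles <- names(config$lifestyle_fractions)
    lifestyle <- sample(lifestyles, n, replace = TRUE,
                        prob = config$lifestyle_fractions)
    gsize <- round(stats::rnorm(n, config$genome_size_mean[lifestyle],
                                config$genome_size_sd[lifestyle]))
    gsize <- pmax(gsize, 150L)

    species <- tibble(
      species_id = species_id, order = "o1", family = family, genus = genus,
      lifestyle = lifestyle,
      lifestyle_code = c(free_living = 0L, endosymbiont = 1L,
                         commensal = 2L)[lifestyle],
      genome_size = as.integer(gsize)
    )

    # genus subtrees, then family subtrees, then the order backbone
    genus_parts <- map_chr(unique(genus), function(g) {
      sp <- species_id[genus == g]
      if (length(sp) == 1L) sp else join_random(as.list(sp), depth_scale = 0.5)
    })
    names(genus_parts) <- unique(genus)
    fam_of <- setNames(family[match(unique(genus), genus)], unique(genus))
    family_parts <- map_chr(unique(fam_of), function(f) {
      gp <- genus_parts[names(fam_of)[fam_of == f]]
      if (length(gp) == 1L) gp else join_random(as.list(gp), depth_scale = 1)
    })
    newick <- if (length(family_parts) == 1L) {
      sprintf("%s;", family_parts[[1]])
    } else {
      sprintf("%s;", join_random(as.list(family_parts), depth_scale = 1.5))
    }
    tree <- ape::read.tree(text = newick)
    tree$edge.length[tree$edge.length <= 0] <- 1e-3
    list(species = species, tree = tree)
  })
}

# ---- signal peptide construction and destruction --------------------------

# sample a fresh tripartite signal peptide; returns list(chars, cp)
sample_signal_peptide <- function(tat = FALSE) {
  repeat {
    n_len <- sample(2:5, 1L)
    h_len <- sample(8:14, 1L)
    c_len <- sample(3:6, 1L)
    if (tat) n_len <- 7L
    cp <- 1L + n_len + h_len + c_len
    if (cp >= 15L && cp <= 40L) break
  }
  if (tat) {
    n_reg <- c("S", "R", "R", "Q", "F", "L", "K")
  } else {
    n_reg <- sample(SP_N_ALPHABET, n_len, replace = TRUE)
    n_reg[1] <- sample(c("K", "R"), 1L)
    # avoid accidental twin-arginine pairs
    for (i in seq_len(n_len - 1L)) {
      if (n_reg[i] == "R" && n_reg[i + 1L] == "R") n_reg[i + 1L] <- "K"
    }
  }
  h_reg <- sample(SP_H_ALPHABET, h_len, replace = TRUE, prob = c(2, 3, 3, 3, 2, 1))
  c_reg <- sample(SP_C_ALPHABET, c_len, replace = TRUE)
  chars <- c("M", n_reg, h_reg, c_reg)
  chars[cp - 2L] <- "A"
  chars[cp - 1L] <- sample(c("Q", "S", "E", "T"), 1L)
  chars[cp] <- "A"
  list(chars = chars, cp = cp)
}

# convert an existing N-terminal segment into a signal peptide by targeted
# point substitutions, keeping its length (substitution-mechanism gains)
make_sp_by_mutation <- function(chars, cp) {
  stopifnot(length(chars) >= cp, cp >= 15L)
  chars[1] <- "M"
  # positively charged n-region: one basic residue, no acidic ones
  n_end <- 4L
  acidic <- which(chars[2:n_end] %in% c("D", "E")) + 1L
  chars[acidic] <- sample(c("N", "Q", "S", "T"), length(acidic), replace = TRUE)
  if (!any(chars[2:n_end] %in% c("K", "R"))) chars[2] <- "K"
  # hydrophobic core: an 8-residue window inside the segment
  h_start <- n_end + 1L
  h_end <- min(cp - 3L, h_start + 7L)
  for (i in h_start:h_end) {
    if (!chars[i] %in% SP_H_ALPHABET) chars[i] <- sample(c("L", "V", "I", "A"), 1L)
  }
  # cleavage motif
  chars[cp - 2L] <- "A"
  chars[cp] <- "A"
  # avoid accidental twin-arginine pairs
  for (i in 2:(min(34L, length(chars)) - 1L)) {
    if (chars[i] == "R" && chars[i + 1L] == "R") chars[i + 1L] <- "K"
  }
  chars
}

# destroy a signal peptide in place by substitutions: remove all basic
# residues from the n-region, interrupt the hydrophobic core, and break the
# cleavage motif (substitution-mechanism losses)
destroy_sp <- function(chars, cp) {
  basic <- which(chars[2:5] %in% c("K", "R")) + 1L
  chars[basic] <- sample(c("D", "E", "N", "Q"), length(basic), replace = TRUE)
  core <- seq(6L, cp - 1L, by = 2L)
  chars[core] <- sample(POLAR_BREAKERS, length(core), replace = TRUE)
  chars[cp] <- "D"
  if (cp - 2L >= 1L) chars[cp - 2L] <- "E"
  chars
}

# ---- per-family evolution --------------------------------------------------

# a lineage record carries the mutable sequence state along the tree
new_lineage <- function(body, sp = NULL, kind = "none", block_id = NA_integer_) {
  list(body = body, body_del = 0L, kind = kind, block_id = block_id,
       block = sp$chars, cp = sp$cp %||% NA_integer_,
       state = if (kind == "none") 0L else 1L)
}

lineage_effective_body <- function(rec) {
  if (rec$body_del > 0L) rec$body[-seq_len(rec$body_del)] else rec$body
}

lineage_chars <- function(rec) {
  if (rec$kind %in% c("block", "dead_block")) {
    c(rec$block, lineage_effective_body(rec))
  } else {
    lineage_effective_body(rec)
  }
}

# write a (possibly edited) character vector back into the record
lineage_writeback <- function(rec, chars) {
  if (rec$kind %in% c("block", "dead_block")) {
    nb <- length(rec$block)
    rec$block <- chars[seq_len(nb)]
    body_part <- chars[-seq_len(nb)]
  } else {
    body_part <- chars
  }
  rec$body[(rec$body_del + 1L):length(rec$body)] <- body_part
  rec
}

# make a leaf consistent with its true state: the heuristic must agree with
# the planted state and the Tat detector must stay quiet (unless the family
# is a Tat family). Edits are lineage-local substitutions.
repair_leaf <- function(rec, tat_family = FALSE) {
  for (iter in 1:30) {
    chars <- lineage_chars(rec)
    seqstr <- paste(chars, collapse = "")
    tat_hit <- detect_tat_motif(seqstr)
    if (!tat_family && tat_hit) {
      sub <- head(chars, 35L)
      rr <- which(sub[-length(sub)] == "R" & sub[-1] == "R")[1]
      chars[rr + 1L] <- "K"
      rec <- lineage_writeback(rec, chars)
      next
    }
    hs <- heuristic_sp_score(seqstr)
    called <- hs$score > 0.5
    if (rec$state == 1L && !called) {
      # pathological drift: rewrite the signal peptide region outright
      chars[seq_len(rec$cp)] <- make_sp_by_mutation(chars[seq_len(rec$cp)], rec$cp)
      rec <- lineage_writeback(rec, chars)
      next
    }
    if (rec$state == 0L && called) {
      # break the spuriously detected architecture at its cleavage point
      chars[hs$cleavage_pos] <- "D"
      if (hs$cleavage_pos > 2L) chars[hs$cleavage_pos - 2L] <- "E"
      rec <- lineage_writeback(rec, chars)
      next
    }
    return(rec)
  }
  abort("leaf repair did not converge")  # nocov
}

# evolve one family along its (pruned, rooted, binary) tree
evolve_family <- function(config, tree, root_sp, tat) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L

  body_len <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), 1L)
  body <- sample(AMINO_ACIDS, body_len, replace = TRUE)

  recs <- vector("list", n_nodes)
  next_block <- 1L
  if (root_sp) {
    sp <- sample_signal_peptide(tat = tat)
    recs[[root]] <- new_lineage(body, sp, kind = "block", block_id = next_block)
    block_lengths <- c(sp$cp)
    next_block <- 2L
  } else {
    recs[[root]] <- new_lineage(body)
    block_lengths <- integer(0)
  }

  events <- list()
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]

  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1]; ch <- pre[k, 2]
    rec <- recs[[p]]

    # background substitutions on the unprotected part of the body
    eff <- (rec$body_del + 1L):length(rec$body)
    protected <- integer(0)
    if (rec$kind == "body" && rec$state == 1L) {
      protected <- eff[seq_len(rec$cp)]
    }
    candidates <- setdiff(eff, protected)
    hits <- candidates[stats::runif(length(candidates)) < config$substitution_rate]
    if (length(hits) > 0L) {
      rec$body[hits] <- vapply(rec$body[hits], function(a) {
        sample(setdiff(AMINO_ACIDS, a), 1L)
      }, character(1))
    }
    if (rec$kind == "dead_block") {
      bh <- which(stats::runif(length(rec$block)) < config$substitution_rate)
      if (length(bh) > 0L) {
        rec$block[bh] <- vapply(rec$block[bh], function(a) {
          sample(setdiff(AMINO_ACIDS, a), 1L)
        }, character(1))
      }
    }

    # at most one signal peptide event per branch
    if (!tat) {
      if (rec$state == 1L && stats::runif(1) < config$sp_loss_rate) {
        mech <- if (stats::runif(1) < config$mechanism_mix) "indel" else "substitution"
        if (mech == "indel") {
          if (rec$kind == "block") {
            rec$kind <- "none"; rec$block <- NULL; rec$block_id <- NA_integer_
          } else {
            rec$body_del <- rec$body_del + rec$cp
          }
          rec$cp <- NA_integer_
        } else {
          if (rec$kind == "block") {
            rec$block <- destroy_sp(rec$block, rec$cp)
            rec$kind <- "dead_block"
          } else {
            idx <- (rec$body_del + 1L):(rec$body_del + rec$cp)
            rec$body[idx] <- destroy_sp(rec$body[idx], rec$cp)
            rec$kind <- "none"
          }
          rec$cp <- NA_integer_
        }
        rec$state <- 0L
        events[[length(events) + 1L]] <-
          tibble(parent = p, child = ch, type = "loss", mechanism = mech)
      } else if (rec$state == 0L && stats::runif(1) < config$sp_gain_rate) {
        if (rec$kind == "dead_block") {
          mech <- "substitution"
          cp <- length(rec$block)
          rec$block <- make_sp_by_mutation(rec$block, cp)
          rec$kind <- "block"; rec$cp <- cp
        } else {
          mech <- if (stats::runif(1) < config$mechanism_mix) "indel" else "substitution"
          eff_len <- length(rec$body) - rec$body_del
          if (mech == "substitution" && eff_len - 30L < 15L) mech <- "indel"
          if (mech == "indel") {
            sp <- sample_signal_peptide()
            rec$kind <- "block"; rec$block <- sp$chars; rec$cp <- sp$cp
            rec$block_id <- next_block
            block_lengths <- c(block_lengths, sp$cp)
            next_block <- next_block + 1L
          } else {
            cps <- 15:min(40L, eff_len - 30L)
            cp <- cps[sample.int(length(cps), 1L)]
            idx <- (rec$body_del + 1L):(rec$body_del + cp)
            rec$body[idx] <- make_sp_by_mutation(rec$body[idx], cp)
            rec$kind <- "body"; rec$cp <- cp
          }
        }
        rec$state <- 1L
        events[[length(events) + 1L]] <-
          tibble(parent = p, child = ch, type = "gain", mechanism = mech)
      }
    }
    recs[[ch]] <- rec
  }

  # repair and finalize leaves
  for (i in seq_len(ntip)) {
    rec <- recs[[i]]
    chars <- lineage_chars(rec)
    chars[1] <- "M"
    rec <- lineage_writeback(rec, chars)
    rec <- repair_leaf(rec, tat_family = tat)
    recs[[i]] <- rec
  }

  list(
    recs = recs,
    states = vapply(recs, function(r) r$state, integer(1)),
    events = if (length(events) > 0) list_rbind(events) else
      tibble(parent = integer(), child = integer(), type = character(),
             mechanism = character()),
    block_lengths = block_lengths,
    body_len = body_len
  )
}

# assemble the true MSA of a family from its lineage records
assemble_family_msa <- function(fam, tip_ids) {
  nblocks <- length(fam$block_lengths)
  body_len <- fam$body_len
  rows <- vapply(seq_along(tip_ids), function(i) {
    rec <- fam$recs[[i]]
    parts <- character(0)
    for (b in seq_len(nblocks)) {
      if (!is.na(rec$block_id) && rec$block_id == b) {
        parts <- c(parts, paste(rec$block, collapse = ""))
      } else {
        parts <- c(parts, strrep("-", fam$block_lengths[b]))
      }
    }
    body_row <- paste0(strrep("-", rec$body_del),
                       paste(rec$body[(rec$body_del + 1L):body_len], collapse = ""))
    paste0(paste(parts, collapse = ""), body_row)
  }, character(1))
  setNames(rows, tip_ids)
}

# ---- predictor emulation ---------------------------------------------------

#' Emulate the three signal peptide predictors for one protein
#'
#' Produces a SignalP-like score and call, a Phobius-like call and a
#' TatP-like call for a sequence. With zero noise the Sec calls both equal
#' the decision of [heuristic_sp_score()] at threshold 0.5 and the Tat call
#' equals [detect_tat_motif()]. Each call is then independently flipped with
#' its configured probability; the reported score is the heuristic score
#' perturbed by bounded noise and kept on the same side of 0.5 as the
#' (possibly flipped) call.
#'
#' @param sequence Amino-acid string.
#' @param predictor_noise Named numeric vector with elements `signalp`,
#'   `phobius`, `tatp` (flip probabilities).
#' @param seed Integer seed for the noise draws.
#' @return Tibble row: `signalp_score`, `signalp_call`, `phobius_call`,
#'   `tatp_call`, `cleavage_pos` (`NA` unless `signalp_call`).
#' @export
emulate_predictors <- function(sequence,
                               predictor_noise = c(signalp = 0, phobius = 0, tatp = 0),
                               seed = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string")
  }
  hs <- heuristic_sp_score(sequence)
  tat_true <- detect_tat_motif(sequence)
  with_seed(seed, {
    flips <- unname(stats::runif(3) < predictor_noise[c("signalp", "phobius", "tatp")])
    sp_call <- xor(hs$score > 0.5, flips[1])
    ph_call <- xor(hs$score > 0.5, flips[2])
    tat_call <- xor(tat_true, flips[3])
    score <- hs$score
    if (sp_call != (score > 0.5)) score <- 1 - score
    score <- min(0.999, max(0.001, score + stats::runif(1, -0.04, 0.04)))
    if ((score > 0.5) != sp_call) score <- if (sp_call) 0.52 else 0.48
    cp <- if (sp_call) {
      if (!is.na(hs$cleavage_pos)) hs$cleavage_pos else 20L
    } else NA_integer_
    tibble(signalp_score = score, signalp_call = sp_call,
           phobius_call = ph_call, tatp_call = tat_call, cleavage_pos = cp)
  })
}

# ---- alternative-start sanitization ---------------------------------------

# A protein's secretion truth must stay unambiguous under the gene start
# correction scan: no alternative in-frame start may produce a spuriously
# signal-peptide-positive N-terminus. Offending upstream starts (in random
# context) are removed by rewriting the context codon; offending downstream
# starts are removed by a synonymous codon swap (GTG/TTG) or, for ATG, by
# point substitutions that break the spurious architecture (mirrored in the
# protein and its alignment row).
sanitize_alt_starts <- function(genomic, cds_start, cds_end, chars,
                                max_down = 100L) {
  L_aa <- length(chars)
  aa_edits <- integer(0)
  for (iter in 1:60) {
    changed <- FALSE
    avail_up <- (cds_start - 1L) %/% 3L
    for (s in seq_len(avail_up)) {
      pos <- cds_start - 3L * s
      codon <- substr(genomic, pos, pos + 2L)
      if (!codon %in% START_CODONS) next
      seg <- substr(genomic, pos, cds_start - 1L)
      n <- nchar(seg)
      up_codons <- substring(seg, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
      if (any(up_codons %in% STOP_CODONS)) next  # unreachable candidate
      # the annotated start codon is no longer the initiator in the extended
      # candidate, so it translates literally (GTG -> V, TTG -> L)
      body45 <- chars
      body45[1] <- unname(Biostrings::GENETIC_CODE[[substr(genomic, cds_start,
                                                           cds_start + 2L)]])
      cand <- paste0("M",
                     paste(unname(Biostrings::GENETIC_CODE[up_codons[-1]]),
                           collapse = ""),
                     paste(head(body45, 45L), collapse = ""))
      if (heuristic_sp_score(substr(cand, 1, 45))$score > 0.5) {
        substr(genomic, pos, pos + 2L) <- "ACC"
        changed <- TRUE
      }
    }
    down_max <- min(L_aa - 10L, max_down)
    for (j in 2:down_max) {
      pos <- cds_start + 3L * (j - 1L)
      codon <- substr(genomic, pos, pos + 2L)
      if (!codon %in% START_CODONS) next
      cand <- paste0("M", paste(chars[seq(j + 1L, min(L_aa, j + 45L))],
                                collapse = ""))
      if (nchar(cand) < 15L) next
      hs <- heuristic_sp_score(substr(cand, 1, 45))
      if (hs$score <= 0.5) next
      if (codon == "GTG") {
        substr(genomic, pos, pos + 2L) <- "GTT"
      } else if (codon == "TTG") {
        substr(genomic, pos, pos + 2L) <- "CTG"
      } else {
        # ATG encodes methionine; break the spurious architecture instead
        # (candidate position p corresponds to protein position j + p - 1)
        bad <- j + hs$cleavage_pos - 1L
        for (k in unique(pmin(L_aa, c(bad, bad - 2L)))) {
          if (k > j) {
            chars[k] <- "D"
            aa_edits <- c(aa_edits, k)
          }
        }
      }
      changed <- TRUE
    }
    if (length(aa_edits) > 0L) {
      # keep the coding sequence in step with the edited protein
      codons <- codon_table_by_aa()
      for (k in unique(aa_edits)) {
        opts <- codons[[chars[k]]]
        substr(genomic, cds_start + 3L * (k - 1L), cds_start + 3L * k - 1L) <-
          opts[1]
      }
    }
    if (!changed) break
  }
  list(genomic = genomic, chars = chars, aa_edits = unique(aa_edits))
}

# ---- gene start corruption -------------------------------------------------

# back-translate an amino-acid sequence (uniform synonymous codon choice),
# add a stop codon and random genomic context on both sides
make_cds_record <- function(chars, context_nt) {
  codons <- codon_table_by_aa()
  start <- sample(START_CODONS, 1L, prob = c(0.85, 0.11, 0.04))
  rest <- vapply(chars[-1], function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stopc <- sample(STOP_CODONS, 1L)
  cds <- paste0(start, paste(rest, collapse = ""), stopc)
  up <- paste(sample(c("A", "C", "G", "T"), context_nt, replace = TRUE), collapse = "")
  down <- paste(sample(c("A", "C", "G", "T"), context_nt, replace = TRUE), collapse = "")
  list(
    genomic = paste0(up, cds, down),
    cds_start = context_nt + 1L,
    cds_end = context_nt + nchar(cds)
  )
}

#' Plant gene start annotation errors
#'
#' For a random fraction of signal-peptide-bearing members of each cluster,
#' moves the annotated gene start downstream past the signal-peptide-encoding
#' region to the next in-frame ATG/GTG/TTG, re-derives the annotated protein
#' sequence (truncating the signal peptide away), and records the true start
#' in the ground truth. Members without a reachable alternative start are
#' skipped with a message.
#'
#' @param dataset An `sp_dataset` (see [simulate_dataset()]); normally called
#'   internally by the generator.
#' @param rate Corruption probability per signal-peptide-bearing member.
#' @param shift_extra Maximum extra residues past the cleavage site within
#'   which the corrupting start is searched.
#' @param seed Integer seed.
#' @return The dataset with corrupted annotations (`proteins$sequence`,
#'   `proteins$cds_start`, `msas`) and `proteins$true_start_shift` filled in.
#' @export
plant_start_errors <- function(dataset, rate, shift_extra = 30L, seed = 1L) {
  if (rate == 0) return(dataset)
  prot <- dataset$proteins
  with_seed(seed, {
    eligible <- which(prot$true_state == 1L & !prot$tat)
    chosen <- eligible[stats::runif(length(eligible)) < rate]
    for (i in chosen) {
      aa <- prot$sequence[i]
      L <- nchar(aa)
      cp <- prot$true_cleavage[i]
      genomic <- prot$genomic[i]
      cds_start <- prot$cds_start[i]
      # next in-frame start codon past the signal peptide
      j_max <- min(L - 10L, cp + shift_extra)
      if (j_max <= cp + 1L) next
      found <- NA_integer_
      for (j in (cp + 1L):j_max) {
        codon <- substr(genomic, cds_start + 3L * (j - 1L), cds_start + 3L * (j - 1L) + 2L)
        if (codon %in% START_CODONS) { found <- j; break }
      }
      if (is.na(found)) {
        inform(sprintf("no alternative in-frame start for %s; skipped",
                       prot$protein_id[i]))
        next
      }
      shift <- found - 1L
      new_start <- cds_start + 3L * shift
      new_aa <- translate_cds(substr(genomic, new_start, prot$cds_end[i]))
      prot$true_start_shift[i] <- shift
      prot$cds_start[i] <- new_start
      prot$sequence[i] <- new_aa
      # update the emitted MSA row: truncated residues become gaps and the
      # new first residue reads M
      cid <- prot$cluster_id[i]
      row <- strsplit(dataset$msas[[cid]][[prot$protein_id[i]]], "", fixed = TRUE)[[1]]
      res_cols <- which(row != "-")
      row[res_cols[seq_len(shift)]] <- "-"
      row[res_cols[shift + 1L]] <- "M"
      dataset$msas[[cid]][[prot$protein_id[i]]] <- paste(row, collapse = "")
    }
  })
  dataset$proteins <- prot
  dataset
}

# ---- gene ontology ---------------------------------------------------------

# small synthetic GO-like DAG (is_a edges only), one namespace, with a
# secretion-related branch and an intracellular branch plus a diamond
simulate_go_dag <- function() {
  edges <- tibble(
    child = c("GO:0000002", "GO:0000003",
              "GO:0000011", "GO:0000012", "GO:0000013", "GO:0000014",
              "GO:0000021", "GO:0000022", "GO:0000023", "GO:0000024",
              "GO:0000031", "GO:0000031", "GO:0000032"),
    parent = c("GO:0000001", "GO:0000001",
               "GO:0000002", "GO:0000002", "GO:0000011", "GO:0000011",
               "GO:0000003", "GO:0000003", "GO:0000021", "GO:0000021",
               "GO:0000012", "GO:0000022", "GO:0000031")
  )
  terms <- tibble(
    term_id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000011",
                "GO:0000012", "GO:0000013", "GO:0000014", "GO:0000021",
                "GO:0000022", "GO:0000023", "GO:0000024", "GO:0000031",
                "GO:0000032"),
    name = c("biological_process", "secretion", "intracellular process",
             "protein transport", "cell adhesion", "outer membrane assembly",
             "pilus organization", "nucleic acid process", "metabolic process",
             "nucleotide binding process", "translation",
             "envelope biogenesis", "peptidoglycan turnover")
  )
  list(terms = terms, edges = edges)
}

GO_SECRETED_TERMS <- c("GO:0000011", "GO:0000012", "GO:0000013", "GO:0000014",
                       "GO:0000031")
GO_INTRACELL_TERMS <- c("GO:0000021", "GO:0000022", "GO:0000023", "GO:0000024",
                        "GO:0000032")

# ---- whole-dataset simulation ---------------------------------------------

#' Simulate a complete ground-truth-labelled dataset
#'
#' Generates species (taxonomy, tree, lifestyles, genome sizes), ortholog
#' families evolved along the pruned species tree with planted signal peptide
#' gain/loss events of both mechanisms, per-protein coding sequences with
#' genomic context, planted gene start annotation errors, noisy predictor
#' calls, and GO-style functional annotations.
#'
#' @param config An [sim_config()] object.
#' @return Object of class `sp_dataset`: a list with `config`, `species`,
#'   `species_tree`, `proteins`, `membership`, `predictions`, `msas`,
#'   `trees`, `go`, `annotations` and `truth` (per-family node states,
#'   planted events, true alignments and starts).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  tax <- simulate_taxonomy(config)
  seeds <- seed_stream(config$seed + 1L, config$n_families + 5L)

  families <- vector("list", config$n_families)
  with_seed(seeds[1], {
    fam_meta <- tibble(
      cluster_id = sprintf("C%04d", seq_len(config$n_families)),
      root_sp = stats::runif(config$n_families) < config$ancestor_sp_prob
    ) %>%
      mutate(tat = .data$root_sp &
               stats::runif(config$n_families) < config$tat_fraction)
  })

  prot_rows <- vector("list", config$n_families)
  msas <- list()
  trees <- list()
  truth_fams <- list()

  for (f in seq_len(config$n_families)) {
    cid <- fam_meta$cluster_id[f]
    fam <- with_seed(seeds[f + 2L], {
      # family size and membership (weighted by genome size; secreted
      # families underrepresent endosymbionts)
      smax <- min(config$family_size_range[2], config$n_species)
      size <- 3L + stats::rnbinom(1L, size = 1.2, mu = 16)
      size <- max(config$family_size_range[1], min(size, smax))
      w <- tax$species$genome_size
      if (fam_meta$root_sp[f]) {
        w <- w * ifelse(tax$species$lifestyle == "endosymbiont", 0.4, 1)
      }
      members <- sample(tax$species$species_id, size, prob = w / sum(w))
      tree <- ape::keep.tip(tax$tree, members)
      tree <- binarize_tree(tree)
      ev <- evolve_family(config, tree, fam_meta$root_sp[f], fam_meta$tat[f])
      tip_ids <- sprintf("%s|%s", cid, tree$tip.label)
      species_of_tip <- setNames(tree$tip.label, tip_ids)
      tree$tip.label <- tip_ids
      # per-leaf coding sequences with genomic context; alternative starts
      # that would spuriously read as signal-peptide-positive are sanitized
      # (protein edits are written back before the alignment is assembled)
      cds <- map(seq_along(tip_ids), function(i) {
        chars <- lineage_chars(ev$recs[[i]])
        rec <- make_cds_record(chars, config$context_nt)
        san <- sanitize_alt_starts(rec$genomic, rec$cds_start, rec$cds_end, chars)
        if (length(san$aa_edits) > 0L) {
          ev$recs[[i]] <<- lineage_writeback(ev$recs[[i]], san$chars)
        }
        list(genomic = san$genomic, cds_start = rec$cds_start,
             cds_end = rec$cds_end)
      })
      msa <- assemble_family_msa(ev, tip_ids)
      ntip <- length(tip_ids)
      list(
        tree = tree, msa = msa,
        proteins = tibble(
          protein_id = tip_ids,
          species_id = unname(species_of_tip),
          cluster_id = cid,
          sequence = map_chr(seq_len(ntip),
                             function(i) paste(lineage_chars(ev$recs[[i]]), collapse = "")),
          genomic = map_chr(cds, "genomic"),
          cds_start = map_int(cds, "cds_start"),
          cds_end = map_int(cds, "cds_end"),
          true_state = ev$states[seq_len(ntip)],
          true_cleavage = map_int(seq_len(ntip), function(i) {
            ev$recs[[i]]$cp %||% NA_integer_
          }),
          tat = fam_meta$tat[f],
          true_start_shift = 0L
        ),
        truth = list(
          node_states = ev$states,
          events = ev$events %>% mutate(cluster_id = cid, .before = 1),
          true_msa = msa,
          tat = fam_meta$tat[f],
          root_sp = fam_meta$root_sp[f]
        )
      )
    })
    prot_rows[[f]] <- fam$proteins
    msas[[cid]] <- fam$msa
    trees[[cid]] <- fam$tree
    truth_fams[[cid]] <- fam$truth
  }

  proteins <- list_rbind(prot_rows)

  dataset <- structure(list(
    config = config,
    species = tax$species,
    species_tree = tax$tree,
    proteins = proteins,
    membership = proteins %>% select("cluster_id", "protein_id"),
    msas = msas,
    trees = trees,
    truth = list(families = truth_fams)
  ), class = "sp_dataset")

  dataset <- plant_start_errors(dataset, config$start_error_rate,
                                shift_extra = config$start_shift_range[2],
                                seed = seeds[2])

  # predictor calls on the (possibly corrupted) annotated sequences
  pred_seeds <- seed_stream(config$seed + 2L, nrow(dataset$proteins))
  dataset$predictions <- list_rbind(map(seq_len(nrow(dataset$proteins)), function(i) {
    emulate_predictors(dataset$proteins$sequence[i], config$predictor_noise,
                       seed = pred_seeds[i]) %>%
      mutate(protein_id = dataset$proteins$protein_id[i], .before = 1)
  }))

  # GO-style annotations: shared per family, biased by secretion state
  dag <- simulate_go_dag()
  dataset$go <- dag
  dataset$annotations <- with_seed(seeds[3], {
    list_rbind(map(seq_len(config$n_families), function(f) {
      cid <- fam_meta$cluster_id[f]
      pool <- if (fam_meta$root_sp[f]) {
        if (stats::runif(1) < 0.75) GO_SECRETED_TERMS else GO_INTRACELL_TERMS
      } else {
        if (stats::runif(1) < 0.75) GO_INTRACELL_TERMS else GO_SECRETED_TERMS
      }
      terms <- sample(pool, sample(1:2, 1L))
      ids <- dataset$proteins$protein_id[dataset$proteins$cluster_id == cid]
      tidyr::expand_grid(protein_id = ids, term_id = terms)
    }))
  })

  dataset
}

#' @export
print.sp_dataset <- function(x, ...) {
  cat(sprintf(
    "<sp_dataset> %d species, %d families, %d proteins (seed %d)\n",
    nrow(x$species), length(x$msas), nrow(x$proteins), x$config$seed))
  invisible(x)
}
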