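# Consensus secretion-state calling and cluster classification.

#' Heuristic signal peptide score for an amino-acid sequence
#'
#' Scores the N-terminus of a protein for the tripartite Sec signal peptide
#' architecture: a short, net positively charged n-region, a central
#' hydrophobic h-region, and a polar c-region ending in a signal peptidase I
#' A-x-A-type cleavage motif. This is a transparent, rule-based scorer used
#' both by the predictor emulator of the synthetic-data generator and by the
#' gene start correction step; it is not a reimplementation of any published
#' predictor.
#'
#' A candidate cleavage point `cp` (the position of the last signal peptide
#' residue) is admissible when all of the following hold:
#' * `cp` lies within `cleavage_range` (default 15--40 residues);
#' * the residues at `cp - 2` and `cp` belong to `motif_residues`
#'   (default A, G, C -- small side chains compatible with the canonical
#'   A-x-A motif);
#' * some n-region prefix of length 2--5 has net positive charge
#'   (K/R count exceeds D/E count; the initiator M is ignored);
#' * a hydrophobic stretch of at least `h_min_len` residues with mean
#'   Kyte--Doolittle hydropathy `>= h_threshold` (default 1.6) lies between
#'   the n-region and `cp - 2`.
#'
#' The returned score exceeds 0.5 if and only if at least one admissible
#' cleavage point exists; the smallest admissible cleavage point is reported.
#' Above 0.5 the score grows with the quality of the hydrophobic stretch.
#'
#' @param sequence Single amino-acid string (standard 20-letter alphabet).
#' @param h_threshold Minimum mean Kyte--Doolittle hydropathy of the h-region.
#' @param h_min_len Minimum h-region length in residues.
#' @param cleavage_range Integer vector of length 2: admissible range for the
#'   cleavage position (last signal peptide residue).
#' @param motif_residues Residues accepted at the -3 and -1 motif positions.
#' @return A list with `score` (in `[0, 1]`) and `cleavage_pos` (integer
#'   position of the last signal peptide residue, or `NA` if `score <= 0.5`).
#' @examples
#' heuristic_sp_score("MKKILLAVAVLLASSAFAAEGSTNA")
#' @export
heuristic_sp_score <- function(sequence, h_threshold = 1.6, h_min_len = 7L,
                               cleavage_range = c(15L, 40L),
                               motif_residues = c("A", "G", "C")) {
  chars <- check_protein_sequence(sequence)
  L <- length(chars)
  cp_min <- cleavage_range[1]
  cp_max <- min(cleavage_range[2], L)
  if (cp_max < cp_min) {
    return(list(score = 0, cleavage_pos = NA_integer_))
  }

  kd <- unname(KD_SCALE[chars])
  charge <- ifelse(chars %in% c("K", "R"), 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
  # net charge of prefix 2..k (skip initiator); n-region lengths 2..5
  n_pos_ok <- any(vapply(2:min(5L, L), function(k) sum(charge[2:k]) > 0, logical(1)))

  best <- NULL
  best_partial <- 0
  for (cp in cp_min:cp_max) {
    motif_ok <- chars[cp - 2L] %in% motif_residues && chars[cp] %in% motif_residues
    # h-region: a window of >= h_min_len residues inside positions 3..(cp-3)
    h_mean <- -Inf
    lo <- 3L
    hi <- cp - 3L
    if (hi - lo + 1L >= h_min_len) {
      seg <- kd[lo:hi]
      # best mean over all windows of length h_min_len (longer windows cannot
      # beat their best contained window of minimum length)
      cs <- cumsum(c(0, seg))
      w <- h_min_len
      means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
      h_mean <- max(means)
    }
    h_ok <- is.finite(h_mean) && h_mean >= h_threshold
    n_met <- sum(c(n_pos_ok, h_ok, motif_ok))
    best_partial <- max(best_partial, n_met)
    if (n_met == 3L && is.null(best)) {
      best <- list(cp = cp, h_mean = h_mean)
    }
  }

  if (is.null(best)) {
    return(list(score = best_partial / 3 * 0.5, cleavage_pos = NA_integer_))
  }
  quality <- min(1, max(0.1, (best$h_mean - h_threshold) / 2.9 + 0.1))
  list(score = 0.5 + 0.5 * quality, cleavage_pos = as.integer(best$cp))
}

#' Detect a twin-arginine (Tat) signal peptide motif
#'
#' Searches the first `window` residues for the twin-arginine consensus
#' (S/T)-R-R-x-F-L-K. The two arginines are invariant; the flanking positions
#' accept the degenerate residue sets given as arguments.
#'
#' @param sequence Amino-acid string.
#' @param window Number of N-terminal residues scanned (default 35).
#' @param pre Residues accepted immediately before the R-R pair.
#' @param plus2,plus3,plus4 Degenerate sets for the three positions after the
#'   variable residue that follows R-R.
#' @return `TRUE` if the motif is present.
#' @examples
#' detect_tat_motif("MSRRQFLKGLGALT")
#' detect_tat_motif("MKKILLAVAVLLA")
#' @export
detect_tat_motif <- function(sequence, window = 35L,
                             pre = c("S", "T"),
                             plus2 = c("F", "L", "I", "V", "M"),
                             plus3 = c("L", "I", "V", "F", "A", "M"),
                             plus4 = c("K", "R")) {
  chars <- check_protein_sequence(sequence)
  chars <- head(chars, window)
  L <- length(chars)
  if (L < 7L) return(FALSE)
  for (i in 2:(L - 5L)) {
    if (chars[i] == "R" && chars[i + 1L] == "R" &&
        chars[i - 1L] %in% pre &&
        chars[i + 3L] %in% plus2 &&
        chars[i + 4L] %in% plus3 &&
        chars[i + 5L] %in% plus4) {
      return(TRUE)
    }
  }
  FALSE
}

#' Consensus secretion state from a triple of predictor calls
#'
#' Combines the three predictor outputs into one of four outcomes, applied in
#' strict priority order: a positive Tat call dominates everything
#' (`"TAT"`, leading to rejection of the whole cluster downstream); agreement
#' of the two Sec predictors yields `"POSITIVE"` or `"NEGATIVE"`; disagreement
#' yields `"DISCORDANT"` (the protein is discarded downstream).
#'
#' All arguments are vectorised.
#'
#' @param signalp_call,phobius_call,tatp_call Logical vectors.
#' @return Character vector with levels `TAT`, `POSITIVE`, `NEGATIVE`,
#'   `DISCORDANT`.
#' @examples
#' consensus_state(TRUE, TRUE, FALSE)
#' consensus_state(c(TRUE, FALSE), c(FALSE, FALSE), c(FALSE, FALSE))
#' @export
consensus_state <- function(signalp_call, phobius_call, tatp_call) {
  stopifnot(is.logical(signalp_call), is.logical(phobius_call), is.logical(tatp_call))
  dplyr::case_when(
    tatp_call ~ "TAT",
    signalp_call & phobius_call ~ "POSITIVE",
    !signalp_call & !phobius_call ~ "NEGATIVE",
    TRUE ~ "DISCORDANT"
  )
}

#' Add consensus states to a predictions table
#'
#' @param predictions Tibble with columns `protein_id`, `signalp_call`,
#'   `phobius_call`, `tatp_call` (and typically `signalp_score`,
#'   `cleavage_pos`).
#' @return The input with a `consensus` column appended.
#' @export
add_consensus <- function(predictions) {
  predictions %>%
    mutate(consensus = consensus_state(.data$signalp_call, .data$phobius_call,
                                       .data$tatp_call))
}

#' Classify ortholog clusters by their members' secretion states
#'
#' Applies the cluster-level filtering and labelling rules: any member with a
#' Tat-type signal peptide rejects the whole cluster (`rejected`, reason
#' `tat`); members with discordant Sec predictions are removed; clusters with
#' fewer than `min_size` remaining members are rejected (reason `too_small`);
#' the rest are labelled `positive` (all members secreted), `negative`
#' (none), or `mixed` (both present).
#'
#' @param membership Tibble with columns `cluster_id`, `protein_id`.
#' @param predictions Predictions tibble (see [add_consensus()]); a
#'   `consensus` column is computed if absent.
#' @param min_size Minimum retained members per cluster (default 3).
#' @return Tibble with one row per cluster: `cluster_id`, `class_label`
#'   (`positive`/`negative`/`mixed`/`rejected`), `rejection_reason`
#'   (`tat`/`too_small`/`none`), `n_members` (retained members), and
#'   `retained` (list-column of retained protein ids).
#' @export
classify_clusters <- function(membership, predictions, min_size = 3L) {
  stopifnot(all(c("cluster_id", "protein_id") %in% names(membership)))
  if (!"consensus" %in% names(predictions)) predictions <- add_consensus(predictions)

  joined <- membership %>%
    inner_join(predictions %>% select("protein_id", "consensus"), by = "protein_id")
  if (nrow(joined) < nrow(membership)) {
    missing <- setdiff(membership$protein_id, predictions$protein_id)
    abort(sprintf("no prediction for %d protein(s), e.g. %s",
                  length(missing), missing[1]))
  }

  joined %>%
    group_by(.data$cluster_id) %>%
    summarise(
      has_tat = any(.data$consensus == "TAT"),
      n_pos = sum(.data$consensus == "POSITIVE"),
      n_neg = sum(.data$consensus == "NEGATIVE"),
      retained = list(.data$protein_id[.data$consensus %in% c("POSITIVE", "NEGATIVE")]),
      .groups = "drop"
    ) %>%
    mutate(
      n_members = .data$n_pos + .data$n_neg,
      class_label = dplyr::case_when(
        .data$has_tat ~ "rejected",
        .data$n_members < min_size ~ "rejected",
        .data$n_pos > 0 & .data$n_neg > 0 ~ "mixed",
        .data$n_pos > 0 ~ "positive",
        TRUE ~ "negative"
      ),
      rejection_reason = dplyr::case_when(
        .data$has_tat ~ "tat",
        .data$n_members < min_size ~ "too_small",
        TRUE ~ "none"
      ),
      retained = ifelse(.data$class_label == "rejected",
                        list(character(0)), .data$retained)
    ) %>%
    select("cluster_id", "class_label", "rejection_reason", "n_members",
           "n_pos", "n_neg", "retained")
}

#' Per-genome secretome summary and genome-size trend
#'
#' Tabulates, for every genome, the number of proteins, the number with a
#' consensus-positive signal peptide, and the secreted fraction, then fits a
#' straight line of the secreted fraction against genome size within each
#' lifestyle stratum.
#'
#' @param proteins Tibble with columns `protein_id`, `species_id`.
#' @param predictions Predictions tibble (consensus computed if absent).
#' @param species Tibble with `species_id`, `lifestyle`, and optionally
#'   `genome_size`; when `genome_size` is missing the observed protein count
#'   is used as the size variable.
#' @param count_discordant Should discordant proteins count in the per-genome
#'   denominator? Default `TRUE` (they are real gene products even though
#'   their secretion state is unresolved); set `FALSE` to restrict the
#'   denominator to reliably called proteins.
#' @return List with `per_genome` (tibble: `species_id`, `lifestyle`,
#'   `genome_size`, `n_proteins`, `n_sp`, `fraction_sp`) and `fits` (tibble:
#'   `lifestyle`, `intercept`, `slope`, `n`).
#' @export
secretome_summary <- function(proteins, predictions, species,
                              count_discordant = TRUE) {
  if (!"consensus" %in% names(predictions)) predictions <- add_consensus(predictions)
  tab <- proteins %>%
    inner_join(predictions %>% select("protein_id", "consensus"), by = "protein_id") %>%
    group_by(.data$species_id) %>%
    summarise(
      n_total = dplyr::n(),
      n_called = sum(.data$consensus %in% c("POSITIVE", "NEGATIVE")),
      n_sp = sum(.data$consensus == "POSITIVE"),
      .groups = "drop"
    ) %>%
    mutate(
      n_proteins = if (count_discordant) .data$n_total else .data$n_called,
      fraction_sp = ifelse(.data$n_proteins > 0, .data$n_sp / .data$n_proteins, 0)
    )

  sp_cols <- intersect(c("species_id", "lifestyle", "genome_size"), names(species))
  tab <- tab %>% left_join(species %>% select(dplyr::all_of(sp_cols)), by = "species_id")
  if (!"genome_size" %in% names(tab)) tab$genome_size <- tab$n_proteins

  fits <- tab %>%
    group_by(.data$lifestyle) %>%
    summarise(fit = list({
      if (dplyr::n() >= 2 && sd(.data$genome_size) > 0) {
        cf <- stats::coef(stats::lm(fraction_sp ~ genome_size,
                                    data = data.frame(fraction_sp = .data$fraction_sp,
                                                      genome_size = .data$genome_size)))
        tibble(intercept = unname(cf[1]), slope = unname(cf[2]), n = dplyr::n())
      } else {
        tibble(intercept = NA_real_, slope = NA_real_, n = dplyr::n())
      }
    }), .groups = "drop") %>%
    tidyr::unnest("fit")

  list(
    per_genome = tab %>%
      select("species_id", "lifestyle", "genome_size", "n_proteins", "n_sp",
             "fraction_sp"),
    fits = fits
  )
}
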