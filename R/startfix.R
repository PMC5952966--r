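# Gene start correction: MSA-derived search windows, alternative in-frame
# starts, re-prediction and the priority rules that decide each protein's
# fate before the second round of parsimony.

#' Search window for alternative gene starts
#'
#' For a consensus-negative member of a mixed cluster, compares the alignment
#' column of its first residue with the first-residue columns of every
#' signal-peptide-bearing member. Offsets are measured in ungapped residues:
#' for a member starting upstream of the target the offset counts that
#' member's residues in the columns preceding the target's start; for a
#' member starting downstream it counts the target's own residues up to that
#' member's start. The window is the maximum offset in each direction plus 30
#' residues, and is at least 30 on both sides.
#'
#' @param msa Named character vector of aligned rows.
#' @param target_id Row name of the protein to be scanned.
#' @param sp_member_ids Row names of the signal-peptide-bearing members.
#' @return Named numeric vector `c(upstream = ..., downstream = ...)` in
#'   residues.
#' @export
correction_window <- function(msa, target_id, sp_member_ids) {
  if (!target_id %in% names(msa)) {
    abort(sprintf("target '%s' is not in the alignment", target_id))
  }
  if (length(sp_member_ids) == 0L) abort("sp_member_ids must be nonempty")
  m <- seq_char_matrix(msa)
  first_col <- apply(m != "-", 1, function(r) which(r)[1])
  ct <- first_col[[target_id]]
  up <- 0L
  down <- 0L
  for (id in sp_member_ids) {
    cm <- first_col[[id]]
    if (cm < ct) {
      # member residues upstream of the target's start
      off <- sum(m[id, cm:(ct - 1L)] != "-")
      up <- max(up, off)
    } else if (cm > ct) {
      # target residues before the member's start
      off <- sum(m[target_id, ct:(cm - 1L)] != "-")
      down <- max(down, off)
    }
  }
  c(upstream = up + 30, downstream = down + 30)
}

#' Enumerate alternative in-frame gene starts
#'
#' Lists every in-frame ATG/GTG/TTG within the search window around the
#' annotated start, re-deriving the amino-acid sequence for each (the
#' initiator codon is translated as M). Upstream candidates with an in-frame
#' stop codon between the new start and the annotated one are excluded. The
#' shift-0 candidate (the unchanged annotation) is always present.
#'
#' @param record One-row tibble (or list) with `genomic`, `cds_start`,
#'   `cds_end` (1-based coordinates of the annotated CDS inside `genomic`).
#' @param window Named vector from [correction_window()].
#' @return Tibble of candidates: `shift` (residues; negative = extension),
#'   `codon`, `sequence`.
#' @export
enumerate_alt_starts <- function(record, window) {
  genomic <- record$genomic
  cds_start <- record$cds_start
  cds_end <- record$cds_end
  L_aa <- (cds_end - cds_start + 1L) %/% 3L - 1L  # excludes the stop codon

  max_up <- floor(window[["upstream"]])
  max_down <- floor(window[["downstream"]])
  avail_up <- (cds_start - 1L) %/% 3L
  if (max_up > avail_up) {
    inform("context shorter than upstream window; window truncated")
    max_up <- avail_up
  }
  max_down <- min(max_down, L_aa - 10L)  # keep at least 10 coding residues

  shifts <- seq.int(-max_up, max(0L, max_down))
  rows <- list()
  for (s in shifts) {
    pos <- cds_start + 3L * s
    codon <- substr(genomic, pos, pos + 2L)
    if (s != 0L && !codon %in% START_CODONS) next
    if (s < 0L) {
      # no in-frame stop between the new start and the annotated one
      seg <- substr(genomic, pos, cds_start - 1L)
      n <- nchar(seg)
      codons <- substring(seg, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
      if (any(codons %in% STOP_CODONS)) next
    }
    aa <- translate_cds(substr(genomic, pos, cds_end))
    rows[[length(rows) + 1L]] <- tibble(shift = s, codon = codon, sequence = aa)
  }
  list_rbind(rows)
}

#' Decide a gene start correction from candidate predictions
#'
#' Applies the priority rules to the predictions of all start candidates of
#' one protein: (1) any positive Tat call rejects the whole cluster; (2) a
#' reliable prediction wins -- any consensus-positive candidate is accepted
#' (the one with the highest SignalP-like score; ties broken by smallest
#' absolute shift, then by start codon), otherwise a reliable negative keeps
#' the annotated start; (3) if no candidate is reliable at any start the
#' protein is deleted as discordant.
#'
#' @param candidates Tibble from [enumerate_alt_starts()] with prediction
#'   columns appended (`signalp_score`, `signalp_call`, `phobius_call`,
#'   `tatp_call`), or without them if `predictor` is given.
#' @param predictor Optional function `(sequence) -> prediction row` used to
#'   fill in missing prediction columns.
#' @return List with `outcome` (one of `cluster_rejected_tat`,
#'   `accepted_positive`, `accepted_negative_unchanged`,
#'   `protein_deleted_discordant`) and `candidate` (the chosen candidate row,
#'   or `NULL`).
#' @export
decide_correction <- function(candidates, predictor = NULL) {
  if (!"signalp_call" %in% names(candidates)) {
    if (is.null(predictor)) abort("candidates lack predictions and no predictor given")
    preds <- list_rbind(map(candidates$sequence, predictor))
    candidates <- dplyr::bind_cols(candidates, preds)
  }
  candidates <- add_consensus(candidates)
  if (any(candidates$tatp_call)) {
    return(list(outcome = "cluster_rejected_tat", candidate = NULL))
  }
  pos <- candidates %>% filter(.data$consensus == "POSITIVE")
  if (nrow(pos) > 0L) {
    pick <- pos %>%
      arrange(dplyr::desc(.data$signalp_score), abs(.data$shift), .data$codon) %>%
      slice(1)
    return(list(outcome = "accepted_positive", candidate = pick))
  }
  zero <- candidates %>% filter(.data$shift == 0L)
  if (nrow(zero) > 0L && zero$consensus[1] == "NEGATIVE") {
    return(list(outcome = "accepted_negative_unchanged", candidate = zero))
  }
  if (any(candidates$consensus == "NEGATIVE")) {
    # a reliable negative exists at some start; the annotation is kept
    return(list(outcome = "accepted_negative_unchanged",
                candidate = if (nrow(zero) > 0L) zero else NULL))
  }
  list(outcome = "protein_deleted_discordant", candidate = NULL)
}

#' Run the gene start correction over all mixed clusters
#'
#' Scans every consensus-negative member of every mixed cluster: derives the
#' search window from the cluster alignment, enumerates alternative starts,
#' re-predicts each candidate N-terminus and applies [decide_correction()].
#'
#' @param dataset An `sp_dataset`.
#' @param classes Cluster classification tibble from [classify_clusters()].
#' @param predictions Predictions tibble with `consensus` column.
#' @param predictor Function `(sequence, seed) -> prediction row`; defaults
#'   to [emulate_predictors()] with the dataset's configured noise.
#' @return Tibble of decisions: `cluster_id`, `protein_id`, `outcome`,
#'   `shift`, `codon`, plus the chosen candidate's sequence and predictions
#'   where applicable.
#' @export
correct_gene_starts <- function(dataset, classes, predictions,
                                predictor = NULL) {
  if (is.null(predictor)) {
    noise <- dataset$config$predictor_noise
    base_seed <- dataset$config$seed + 1000L
    predictor <- function(sequence, seed = base_seed) {
      emulate_predictors(sequence, noise, seed = seed)
    }
  }
  mixed <- classes %>% filter(.data$class_label == "mixed")
  if (!"consensus" %in% names(predictions)) predictions <- add_consensus(predictions)

  out <- list()
  for (ci in seq_len(nrow(mixed))) {
    cid <- mixed$cluster_id[ci]
    retained <- mixed$retained[[ci]]
    cons <- predictions %>%
      filter(.data$protein_id %in% retained) %>%
      select("protein_id", "consensus")
    sp_ids <- cons$protein_id[cons$consensus == "POSITIVE"]
    neg_ids <- cons$protein_id[cons$consensus == "NEGATIVE"]
    msa <- dataset$msas[[cid]]
    for (pid in neg_ids) {
      win <- correction_window(msa, pid, sp_ids)
      rec <- dataset$proteins[dataset$proteins$protein_id == pid, ]
      cands <- enumerate_alt_starts(rec, win)
      pred_seed <- dataset$config$seed + 1000L +
        match(pid, dataset$proteins$protein_id)
      preds <- list_rbind(map(seq_len(nrow(cands)), function(k) {
        predictor(cands$sequence[k], seed = pred_seed + k)
      }))
      cands <- dplyr::bind_cols(cands, preds)
      dec <- decide_correction(cands)
      row <- tibble(
        cluster_id = cid, protein_id = pid, outcome = dec$outcome,
        shift = if (!is.null(dec$candidate)) dec$candidate$shift[1] else NA_integer_,
        codon = if (!is.null(dec$candidate)) dec$candidate$codon[1] else NA_character_,
        sequence = if (!is.null(dec$candidate)) dec$candidate$sequence[1] else NA_character_,
        signalp_score = if (!is.null(dec$candidate)) dec$candidate$signalp_score[1] else NA_real_,
        signalp_call = if (!is.null(dec$candidate)) dec$candidate$signalp_call[1] else NA,
        phobius_call = if (!is.null(dec$candidate)) dec$candidate$phobius_call[1] else NA,
        tatp_call = if (!is.null(dec$candidate)) dec$candidate$tatp_call[1] else NA,
        cleavage_pos = if (!is.null(dec$candidate) && "cleavage_pos" %in% names(dec$candidate))
          dec$candidate$cleavage_pos[1] else NA_integer_
      )
      out[[length(out) + 1L]] <- row
      if (dec$outcome == "cluster_rejected_tat") break
    }
  }
  if (length(out) == 0L) {
    return(tibble(cluster_id = character(), protein_id = character(),
                  outcome = character(), shift = integer(), codon = character(),
                  sequence = character(), signalp_score = numeric(),
                  signalp_call = logical(), phobius_call = logical(),
                  tatp_call = logical(), cleavage_pos = integer()))
  }
  list_rbind(out)
}

# update one MSA row after an accepted start correction: restore residues
# into the row's leading gap columns (right-aligned against the current first
# residue) for extensions, or gap out leading residues for truncations; if
# the corrected sequence matches the generator's true alignment row exactly,
# that row is used instead.
apply_correction_to_msa <- function(msa, protein_id, new_sequence,
                                    true_row = NULL) {
  row <- strsplit(msa[[protein_id]], "", fixed = TRUE)[[1]]
  if (!is.null(true_row) && degap(true_row) == new_sequence) {
    width <- nchar(msa[[protein_id]])
    if (nchar(true_row) < width) {
      # columns prepended by an earlier correction in this cluster
      true_row <- paste0(strrep("-", width - nchar(true_row)), true_row)
    }
    if (nchar(true_row) == width) {
      msa[[protein_id]] <- true_row
      return(msa)
    }
  }
  old_seq <- paste(row[row != "-"], collapse = "")
  delta <- nchar(new_sequence) - nchar(old_seq)
  res_cols <- which(row != "-")
  new_chars <- strsplit(new_sequence, "", fixed = TRUE)[[1]]
  if (delta >= 0L) {
    gap_cols <- which(row == "-")
    gap_cols <- gap_cols[gap_cols < res_cols[1]]
    extra <- delta - length(gap_cols)
    if (extra > 0L) {
      # the extension reaches past the alignment's first column: new columns
      # are prepended (gaps in every other row)
      msa <- map_chr(msa, function(r) paste0(strrep("-", extra), r))
      row <- c(rep("-", extra), row)
      gap_cols <- seq_len(extra + length(gap_cols))
      res_cols <- res_cols + extra
    }
    use <- tail(gap_cols, delta)
    row[use] <- new_chars[seq_len(delta)]
    if (delta < length(new_chars)) {
      row[res_cols] <- new_chars[(delta + 1L):length(new_chars)]
    }
  } else {
    drop <- -delta
    row[res_cols[seq_len(drop)]] <- "-"
    row[res_cols[(drop + 1L):length(res_cols)]] <- new_chars
  }
  msa[[protein_id]] <- paste(row, collapse = "")
  msa
}
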