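# End-to-end orchestration: two rounds of parsimony with gene start
# correction in between, followed by mechanism, taxonomy, identity and
# lifestyle-association analyses.

# one round of parsimony over the mixed clusters of a classified dataset
run_parsimony_round <- function(dataset, classes, predictions) {
  if (!"consensus" %in% names(predictions)) predictions <- add_consensus(predictions)
  mixed <- classes %>% filter(.data$class_label == "mixed")
  species_of <- setNames(dataset$proteins$species_id, dataset$proteins$protein_id)
  lifestyle_of <- setNames(dataset$species$lifestyle_code, dataset$species$species_id)
  taxonomy <- dataset$species %>%
    select("species_id", "genus", "family", "order")

  events <- list()
  transitions <- list()
  trees <- list()
  for (ci in seq_len(nrow(mixed))) {
    cid <- mixed$cluster_id[ci]
    retained <- mixed$retained[[ci]]
    tree <- dataset$trees[[cid]]
    if (length(retained) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, retained)
    }
    tree <- binarize_tree(tree)
    cons <- predictions %>% filter(.data$protein_id %in% retained)
    leaf_states <- setNames(as.integer(cons$consensus == "POSITIVE"),
                            cons$protein_id)
    rec <- fitch(tree, leaf_states)
    ev <- call_events(rec, cluster_id = cid)
    ev <- add_event_ranks(ev, rec$tree, taxonomy,
                          leaf_species = species_of)
    lt <- lifestyle_transitions(rec$tree,
                                lifestyle_of[species_of[rec$tree$tip.label]] %>%
                                  setNames(rec$tree$tip.label))
    events[[cid]] <- ev
    transitions[[cid]] <- lt$branches %>% mutate(cluster_id = cid, .before = 1)
    trees[[cid]] <- rec$tree
  }

  all_events <- if (length(events) > 0) list_rbind(events) else
    tibble(cluster_id = character(), parent = integer(), child = integer(),
           child_label = character(), type = character(),
           taxonomic_rank = character())
  all_transitions <- if (length(transitions) > 0) list_rbind(transitions) else
    tibble(cluster_id = character(), parent = integer(), child = integer(),
           transition = character())

  n_class <- function(cl) sum(classes$class_label == cl)

  list(
    classes = classes,
    clusters = c(negative = n_class("negative"),
                 positive = n_class("positive"),
                 mixed = n_class("mixed")),
    events = all_events,
    transitions = all_transitions,
    trees = trees,
    event_counts = c(
      gain = sum(all_events$type == "gain"),
      loss = sum(all_events$type == "loss"),
      uncertain = sum(all_events$type == "uncertain")
    )
  )
}

# apply gene start correction decisions to a dataset copy
apply_corrections <- function(dataset, decisions) {
  rejected_tat <- unique(decisions$cluster_id[decisions$outcome == "cluster_rejected_tat"])
  deleted <- decisions$protein_id[decisions$outcome == "protein_deleted_discordant"]
  accepted <- decisions %>% filter(.data$outcome == "accepted_positive")

  prot <- dataset$proteins
  preds <- dataset$predictions
  for (i in seq_len(nrow(accepted))) {
    pid <- accepted$protein_id[i]
    j <- match(pid, prot$protein_id)
    cid <- prot$cluster_id[j]
    true_row <- dataset$truth$families[[cid]]$true_msa[[pid]]
    dataset$msas[[cid]] <- apply_correction_to_msa(
      dataset$msas[[cid]], pid, accepted$sequence[i], true_row = true_row)
    prot$sequence[j] <- accepted$sequence[i]
    prot$cds_start[j] <- prot$cds_start[j] + 3L * accepted$shift[i]
    k <- match(pid, preds$protein_id)
    preds$signalp_score[k] <- accepted$signalp_score[i]
    preds$signalp_call[k] <- accepted$signalp_call[i]
    preds$phobius_call[k] <- accepted$phobius_call[i]
    preds$tatp_call[k] <- accepted$tatp_call[i]
    preds$cleavage_pos[k] <- accepted$cleavage_pos[i]
  }
  if ("consensus" %in% names(preds)) {
    preds <- preds %>% select(-"consensus") %>% add_consensus()
  }
  keep <- !prot$protein_id %in% deleted & !prot$cluster_id %in% rejected_tat
  dataset$proteins <- prot[keep, ]
  dataset$membership <- dataset$proteins %>% select("cluster_id", "protein_id")
  dataset$predictions <- preds %>%
    filter(.data$protein_id %in% dataset$proteins$protein_id)
  dataset$rejected_tat_clusters <- rejected_tat
  dataset
}

#' Second parsimony round after gene start correction
#'
#' Applies the correction decisions to the dataset (sequence and prediction
#' updates, protein deletions, Tat-based cluster rejections), re-filters and
#' re-classifies the clusters, and re-runs the parsimony analysis.
#'
#' @param dataset The `sp_dataset` used in round 1.
#' @param decisions Decisions tibble from [correct_gene_starts()].
#' @return List with the corrected `dataset`, the new `classes`, and the
#'   round result (same shape as round 1).
#' @export
run_round2 <- function(dataset, decisions) {
  dataset2 <- apply_corrections(dataset, decisions)
  preds2 <- add_consensus(dataset2$predictions)
  classes2 <- classify_clusters(dataset2$membership, preds2)
  round2 <- run_parsimony_round(dataset2, classes2, preds2)
  list(dataset = dataset2, classes = classes2, round = round2)
}

#' Round-over-round summary of clusters and events
#'
#' Pure tabulation arithmetic: per-round cluster counts (negative, positive,
#' mixed) and event counts (gain, loss, uncertain) with percentages, plus the
#' fraction of events and of mixed clusters kept in round 2. Usable on
#' pipeline rounds or on externally reported counts.
#'
#' @param round1,round2 Lists with numeric vectors `clusters` (named
#'   `negative`, `positive`, `mixed`) and `event_counts` (named `gain`,
#'   `loss`, `uncertain`).
#' @return List with `table` (tibble: one row per round and category with
#'   `count` and `percent`), `kept_event_pct` and `kept_mixed_pct`.
#' @export
tabulate_rounds <- function(round1, round2) {
  one_round <- function(r, label) {
    cl <- r$clusters; ev <- r$event_counts
    bind_rows(
      tibble(round = label, kind = "cluster",
             category = names(cl), count = as.numeric(cl),
             percent = fmt_pct(as.numeric(cl) / sum(cl))),
      tibble(round = label, kind = "event",
             category = names(ev), count = as.numeric(ev),
             percent = fmt_pct(as.numeric(ev) / sum(ev)))
    )
  }
  tab <- bind_rows(one_round(round1, "round1"), one_round(round2, "round2"))
  total1 <- sum(round1$event_counts)
  total2 <- sum(round2$event_counts)
  list(
    table = tab,
    kept_event_pct = fmt_pct(if (total1 > 0) total2 / total1 else 0),
    kept_mixed_pct = fmt_pct(
      if (round1$clusters[["mixed"]] > 0)
        round2$clusters[["mixed"]] / round1$clusters[["mixed"]] else 0)
  )
}

#' Percentages of counts relative to a total
#'
#' Small tabulation helper used throughout the reporting routines: expresses
#' counts as percentages of a total, rounded to a fixed number of digits.
#'
#' @param counts Numeric vector of counts.
#' @param total Denominator (defaults to `sum(counts)`).
#' @param digits Decimal digits (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percent_of(c(325, 1235, 852))
#' @export
percent_of <- function(counts, total = sum(counts), digits = 1) {
  fmt_pct(counts / total, digits)
}

#' Run the complete two-round analysis
#'
#' Orchestrates the full pipeline on a dataset (or simulates one from a
#' configuration): consensus calling and cluster classification, round-1
#' parsimony and event calling, gene start correction, round-2 parsimony,
#' taxonomic placement, the event-by-lifestyle contingency table, mechanism
#' classification, identity distributions, per-genome secretome summaries,
#' discrimination scores and GO enrichment.
#'
#' @param x An `sp_dataset` or an [sim_config()] object.
#' @param lr_indel_threshold,lr_substitution_range Mechanism thresholds, see
#'   [mechanism_category()].
#' @return Object of class `sp_run_report`.
#' @export
run_all <- function(x, lr_indel_threshold = 0.1,
                    lr_substitution_range = c(0.9, 1.1)) {
  dataset <- if (inherits(x, "sp_sim_config")) simulate_dataset(x) else x
  if (!inherits(dataset, "sp_dataset")) {
    abort("`x` must be an sp_dataset or sp_sim_config")
  }

  preds1 <- add_consensus(dataset$predictions)
  classes1 <- classify_clusters(dataset$membership, preds1)
  round1 <- run_parsimony_round(dataset, classes1, preds1)

  decisions <- correct_gene_starts(dataset, classes1, preds1)
  r2 <- run_round2(dataset, decisions)
  dataset2 <- r2$dataset
  classes2 <- r2$classes
  round2 <- r2$round
  preds2 <- add_consensus(dataset2$predictions)

  rounds <- tabulate_rounds(round1, round2)

  crosstab <- if (nrow(round2$events) > 0) {
    crosstab_events_lifestyle(round2$events, round2$transitions)
  } else NULL

  # member states of round-2 mixed clusters
  mixed2 <- classes2 %>% filter(.data$class_label == "mixed")
  member_states <- mixed2 %>%
    select("cluster_id", "retained") %>%
    tidyr::unnest("retained") %>%
    rename(protein_id = "retained") %>%
    inner_join(preds2 %>% select("protein_id", "consensus", "cleavage_pos"),
               by = "protein_id") %>%
    mutate(state = as.integer(.data$consensus == "POSITIVE"))

  mech <- mechanism_summary(
    round2$events, round2$trees, dataset2$msas,
    states = member_states %>% select("protein_id", "state"),
    cleavage = member_states %>% select("protein_id", "cleavage_pos"),
    indel_threshold = lr_indel_threshold,
    substitution_range = lr_substitution_range
  )

  # cleavage-site vs. remainder identity over substitution-like event pairs
  state_vec <- setNames(member_states$state, member_states$protein_id)
  cp_vec <- setNames(member_states$cleavage_pos, member_states$protein_id)
  prof_rows <- list()
  for (k in seq_len(nrow(mech$mechanisms))) {
    evk <- mech$mechanisms[k, ]
    prof <- nterm_identity_profile(evk, round2$trees[[evk$cluster_id]],
                                   dataset2$msas[[evk$cluster_id]],
                                   state_vec, cp_vec)
    if (!is.null(prof)) {
      prof_rows[[length(prof_rows) + 1L]] <- prof %>%
        mutate(cluster_id = evk$cluster_id, type = evk$type, .before = 1)
    }
  }
  nterm_profiles <- if (length(prof_rows) > 0) list_rbind(prof_rows) else NULL
  nterm_spearman <- if (!is.null(nterm_profiles) && nrow(nterm_profiles) >= 3) {
    spearman(nterm_profiles$cleavage_site_identity,
             nterm_profiles$remainder_identity)
  } else list(rho = NA_real_, p = NA_real_)

  identities <- identity_distributions(
    member_states %>% select("cluster_id", "protein_id", "state"),
    dataset2$msas
  )

  secretome <- secretome_summary(dataset2$proteins, preds2, dataset$species)

  # lifestyle discrimination on mixed clusters
  members_ls <- member_states %>%
    left_join(dataset2$proteins %>% select("protein_id", "species_id"),
              by = "protein_id") %>%
    left_join(dataset$species %>% select("species_id", "lifestyle"),
              by = "species_id")
  discrimination <- list(
    fl_endo = discrimination_analysis(members_ls, "free_living", "endosymbiont"),
    com_endo = discrimination_analysis(members_ls, "commensal", "endosymbiont"),
    fl_com = discrimination_analysis(members_ls, "free_living", "commensal")
  )
  dd <- discrimination$fl_endo %>%
    inner_join(discrimination$com_endo, by = "cluster_id",
               suffix = c("_fl", "_com"))
  discrimination$spearman_fl_com <- if (nrow(dd) >= 3)
    spearman(dd$d_fl, dd$d_com) else list(rho = NA_real_, p = NA_real_)

  # GO enrichment over cluster classes and, within mixed clusters, by state
  enrichment <- NULL
  if (!is.null(dataset$annotations) && nrow(dataset$annotations) > 0) {
    closed <- go_propagate(dataset$annotations, dataset$go)
    class_groups <- classes2 %>%
      filter(.data$class_label %in% c("positive", "negative", "mixed")) %>%
      select("cluster_id", "class_label", "retained") %>%
      tidyr::unnest("retained") %>%
      rename(protein_id = "retained", group = "class_label")
    mixed_groups <- member_states %>%
      mutate(group = ifelse(.data$state == 1L, "mixed_sp", "mixed_no_sp")) %>%
      select("protein_id", "group")
    enrichment <- list(
      by_class = go_enrichment(class_groups %>% select("protein_id", "group"),
                               closed),
      within_mixed = go_enrichment(mixed_groups, closed)
    )
  }

  # lifestyle-level distribution comparisons on the per-genome table
  pg <- secretome$per_genome
  ls_tests <- list()
  pairs <- list(c("free_living", "commensal"), c("free_living", "endosymbiont"),
                c("commensal", "endosymbiont"))
  for (p in pairs) {
    a <- pg %>% filter(.data$lifestyle == p[1])
    b <- pg %>% filter(.data$lifestyle == p[2])
    if (nrow(a) >= 2 && nrow(b) >= 2) {
      key <- paste(p, collapse = "_vs_")
      ls_tests[[key]] <- list(
        ks_size = ks_two_sample(a$n_proteins, b$n_proteins),
        ks_fraction = ks_two_sample(a$fraction_sp, b$fraction_sp),
        cvm = cvm_two_sample_multivariate(
          scale(rbind(as.matrix(pg[c("n_proteins", "fraction_sp")])))[
            pg$lifestyle == p[1], , drop = FALSE],
          scale(rbind(as.matrix(pg[c("n_proteins", "fraction_sp")])))[
            pg$lifestyle == p[2], , drop = FALSE],
          n_permutations = 499L,
          seed = dataset$config$seed + 77L
        )
      )
    }
  }

  structure(list(
    config = dataset$config,
    dataset = dataset,
    dataset_corrected = dataset2,
    classes_round1 = classes1,
    classes_round2 = classes2,
    round1 = round1,
    round2 = round2,
    decisions = decisions,
    rounds = rounds,
    crosstab = crosstab,
    mechanism = mech,
    nterm_profiles = nterm_profiles,
    nterm_spearman = nterm_spearman,
    identities = identities,
    secretome = secretome,
    discrimination = discrimination,
    enrichment = enrichment,
    lifestyle_tests = ls_tests
  ), class = "sp_run_report")
}

#' @export
print.sp_run_report <- function(x, ...) {
  cat("<sp_run_report>\n")
  cat(sprintf("  clusters round 1: %d negative, %d positive, %d mixed\n",
              x$round1$clusters[["negative"]], x$round1$clusters[["positive"]],
              x$round1$clusters[["mixed"]]))
  cat(sprintf("  clusters round 2: %d negative, %d positive, %d mixed\n",
              x$round2$clusters[["negative"]], x$round2$clusters[["positive"]],
              x$round2$clusters[["mixed"]]))
  ec1 <- x$round1$event_counts; ec2 <- x$round2$event_counts
  cat(sprintf("  events round 1: %d gain / %d loss / %d uncertain\n",
              ec1[["gain"]], ec1[["loss"]], ec1[["uncertain"]]))
  cat(sprintf("  events round 2: %d gain / %d loss / %d uncertain\n",
              ec2[["gain"]], ec2[["loss"]], ec2[["uncertain"]]))
  cat(sprintf("  kept: %.1f%% of events, %.1f%% of mixed clusters\n",
              x$rounds$kept_event_pct, x$rounds$kept_mixed_pct))
  invisible(x)
}

#' Tidy the events of a run report
#'
#' @param x An `sp_run_report`.
#' @param round Which round's events to return (default 2).
#' @param ... Unused.
#' @return Tibble of branch events with taxonomic ranks.
#' @method tidy sp_run_report
#' @export
tidy.sp_run_report <- function(x, round = 2L, ...) {
  r <- if (round == 1L) x$round1 else x$round2
  r$events
}

#' One-row summary of a run report
#'
#' @param x An `sp_run_report`.
#' @param ... Unused.
#' @return One-row tibble with cluster and event counts for both rounds and
#'   the kept fractions.
#' @method glance sp_run_report
#' @export
glance.sp_run_report <- function(x, ...) {
  tibble(
    n_clusters_mixed_r1 = x$round1$clusters[["mixed"]],
    n_clusters_mixed_r2 = x$round2$clusters[["mixed"]],
    n_gain_r1 = x$round1$event_counts[["gain"]],
    n_loss_r1 = x$round1$event_counts[["loss"]],
    n_uncertain_r1 = x$round1$event_counts[["uncertain"]],
    n_gain_r2 = x$round2$event_counts[["gain"]],
    n_loss_r2 = x$round2$event_counts[["loss"]],
    n_uncertain_r2 = x$round2$event_counts[["uncertain"]],
    kept_event_pct = x$rounds$kept_event_pct,
    kept_mixed_pct = x$rounds$kept_mixed_pct
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
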