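# Mechanism classification of gain/loss events: whole-segment indel versus
# substitution, decided by the length ratio between signal peptides and the
# aligned N-termini of relatives without one.

# ancestor test on a rooted tree: is `anc` a strict ancestor of `node`?
node_ancestry_matrix <- function(tree) {
  tips <- node_descendant_tips(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  list(parent = parent, tips = tips)
}

is_strict_ancestor <- function(parent_vec, anc, node) {
  p <- parent_vec[node]
  while (!is.na(p)) {
    if (p == anc) return(TRUE)
    p <- parent_vec[p]
  }
  FALSE
}

#' Keep only the latest events on each lineage
#'
#' Restricts a set of gain/loss events to those nearest the leaves: an event
#' is dropped when another event lies on a branch strictly inside its child
#' subtree (e.g. a gain that is later reversed by a loss). Ancestor to
#' descendant event pairs of opposite type are reported as reversals, and
#' chains of three alternating events as double reversals.
#'
#' @param events Events tibble (rows with `type` in `gain`/`loss`; other
#'   rows are ignored) for a single cluster, with `parent` and `child` node
#'   indices referring to `tree`.
#' @param tree The cluster's rooted `phylo` tree.
#' @return List with `latest` (filtered events tibble), `reversals` (tibble:
#'   `anc_child`, `desc_child`, `anc_type`, `desc_type`) and
#'   `n_double_reversals`.
#' @export
latest_events <- function(events, tree) {
  ev <- events %>% filter(.data$type %in% c("gain", "loss"))
  if (nrow(ev) == 0L) {
    return(list(latest = ev, reversals = tibble(
      anc_child = integer(), desc_child = integer(),
      anc_type = character(), desc_type = character()
    ), n_double_reversals = 0L))
  }
  anc <- node_ancestry_matrix(tree)
  n <- nrow(ev)
  # anc_mat[i, j]: event i's branch lies strictly above event j's branch
  anc_mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        anc_mat[i, j] <- ev$child[i] == ev$parent[j] ||
          is_strict_ancestor(anc$parent, ev$child[i], ev$parent[j])
      }
    }
  }
  superseded <- apply(anc_mat, 1, any)
  latest <- ev[!superseded, , drop = FALSE]

  rev_idx <- which(anc_mat & outer(ev$type, ev$type, "!="), arr.ind = TRUE)
  reversals <- tibble(
    anc_child = ev$child[rev_idx[, 1]],
    desc_child = ev$child[rev_idx[, 2]],
    anc_type = ev$type[rev_idx[, 1]],
    desc_type = ev$type[rev_idx[, 2]]
  )
  # double reversals: i above j above k with alternating types
  n_double <- 0L
  if (n >= 3L) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (anc_mat[i, j] && anc_mat[j, k] &&
          ev$type[i] != ev$type[j] && ev$type[j] != ev$type[k]) {
        n_double <- n_double + 1L
      }
    }
  }
  list(latest = latest, reversals = reversals, n_double_reversals = n_double)
}

#' Length ratio between signal peptides and aligned N-termini
#'
#' For one gain/loss event, pairs every signal-peptide-bearing descendant of
#' the event branch's parent node with every descendant lacking one. For a
#' pair (s, t) the signal peptide of s spans the alignment columns of its
#' first `cleavage_pos` residues; `lr = L_nt / L_sp` where `L_nt` is the
#' number of residues (non-gap characters) of t inside those columns and
#' `L_sp` the signal peptide length of s. An `lr` near 0 indicates a
#' whole-segment indel, near 1 a substitution-driven event. The event's `lr`
#' is the mean over pairs.
#'
#' @param event One event row (with `parent` node index).
#' @param tree The cluster tree.
#' @param msa The cluster alignment.
#' @param states Named 0/1 vector of extant states (by tip label).
#' @param cleavage_positions Named integer vector of cleavage positions for
#'   state-1 tips.
#' @return List with `lr` (mean), `pairs` (tibble: `sp_id`, `nosp_id`,
#'   `l_sp`, `l_nt`, `lr`), or `NULL` when no signal-peptide descendant has a
#'   cleavage position.
#' @export
length_ratio <- function(event, tree, msa, states, cleavage_positions) {
  tips <- node_descendant_tips(tree)[[event$parent]]
  labels <- tree$tip.label[tips]
  sp_tips <- labels[states[labels] == 1L & !is.na(cleavage_positions[labels])]
  nosp_tips <- labels[states[labels] == 0L]
  if (length(sp_tips) == 0L || length(nosp_tips) == 0L) return(NULL)

  m <- seq_char_matrix(msa)
  rows <- list()
  for (s in sp_tips) {
    cp <- cleavage_positions[[s]]
    res_cols <- which(m[s, ] != "-")
    if (length(res_cols) < cp) next
    sp_cols <- res_cols[seq_len(cp)]
    for (t in nosp_tips) {
      l_nt <- sum(m[t, sp_cols] != "-")
      rows[[length(rows) + 1L]] <- tibble(
        sp_id = s, nosp_id = t, l_sp = cp, l_nt = l_nt, lr = l_nt / cp
      )
    }
  }
  if (length(rows) == 0L) return(NULL)
  pairs <- list_rbind(rows)
  list(lr = mean(pairs$lr), pairs = pairs)
}

#' Classify an event mechanism from its length ratio
#'
#' @param lr Length ratio (nonnegative).
#' @param indel_threshold Ratios at or below this are called `indel`.
#' @param substitution_range Ratios inside this closed interval are called
#'   `substitution`; anything else is `intermediate`.
#' @return Character vector of categories.
#' @export
mechanism_category <- function(lr, indel_threshold = 0.1,
                               substitution_range = c(0.9, 1.1)) {
  dplyr::case_when(
    is.na(lr) ~ NA_character_,
    lr <= indel_threshold ~ "indel",
    lr >= substitution_range[1] & lr <= substitution_range[2] ~ "substitution",
    TRUE ~ "intermediate"
  )
}

#' N-terminal identity profile of an event
#'
#' For pairs with a length ratio between 0.9 and 1.1 (comparable N-terminal
#' lengths), computes three identities using the shorter-sequence
#' normalization: over all signal peptide columns (`nterm_identity`), over
#' the three columns at motif positions -3..-1 before the cleavage point
#' (`cleavage_site_identity`), and over the remaining signal peptide columns
#' (`remainder_identity`).
#'
#' @inheritParams length_ratio
#' @param lr_range Pairs with `lr` outside this interval are skipped.
#' @return Tibble with one row per retained pair: `sp_id`, `nosp_id`, `lr`,
#'   `nterm_identity`, `cleavage_site_identity`, `remainder_identity`.
#' @export
nterm_identity_profile <- function(event, tree, msa, states, cleavage_positions,
                                   lr_range = c(0.9, 1.1)) {
  res <- length_ratio(event, tree, msa, states, cleavage_positions)
  if (is.null(res)) return(NULL)
  pairs <- res$pairs %>%
    filter(.data$lr >= lr_range[1], .data$lr <= lr_range[2])
  if (nrow(pairs) == 0L) return(NULL)

  m <- seq_char_matrix(msa)
  col_identity <- function(a, b, cols) {
    ra <- m[a, cols]; rb <- m[b, cols]
    ident <- sum(ra == rb & ra != "-")
    shorter <- min(sum(ra != "-"), sum(rb != "-"))
    if (shorter == 0L) 0 else ident / shorter
  }
  pairs %>%
    mutate(profile = pmap(list(.data$sp_id, .data$nosp_id, .data$l_sp),
                          function(s, t, cp) {
      res_cols <- which(m[s, ] != "-")
      sp_cols <- res_cols[seq_len(cp)]
      site_cols <- res_cols[(cp - 2L):cp]
      rem_cols <- setdiff(sp_cols, site_cols)
      tibble(
        nterm_identity = col_identity(s, t, sp_cols),
        cleavage_site_identity = col_identity(s, t, site_cols),
        remainder_identity = col_identity(s, t, rem_cols)
      )
    })) %>%
    tidyr::unnest("profile") %>%
    select("sp_id", "nosp_id", "lr", "nterm_identity",
           "cleavage_site_identity", "remainder_identity")
}

#' Mechanism analysis for all events of a cluster set
#'
#' Applies the latest-event filter per cluster, computes each retained
#' event's length ratio and category, and tabulates counts per event type
#' and category.
#'
#' @param events Events tibble over all clusters (`cluster_id`, `parent`,
#'   `child`, `type`).
#' @param trees Named list of cluster trees.
#' @param msas Named list of cluster alignments.
#' @param states Tibble with `protein_id`, `state` (0/1).
#' @param cleavage Tibble with `protein_id`, `cleavage_pos`.
#' @param indel_threshold,substitution_range Passed to
#'   [mechanism_category()].
#' @return List with `mechanisms` (tibble: one row per retained event with
#'   `lr` and `category`), `summary` (counts per type and category),
#'   `reversals` (per-cluster reversal report) and `skipped` (events without
#'   a usable signal peptide descendant).
#' @export
mechanism_summary <- function(events, trees, msas, states, cleavage,
                              indel_threshold = 0.1,
                              substitution_range = c(0.9, 1.1)) {
  state_vec <- setNames(states$state, states$protein_id)
  cp_vec <- setNames(cleavage$cleavage_pos, cleavage$protein_id)

  mech_rows <- list()
  rev_rows <- list()
  skipped <- 0L
  for (cid in unique(events$cluster_id)) {
    ev_c <- events %>% filter(.data$cluster_id == cid)
    tree <- trees[[cid]]
    le <- latest_events(ev_c, tree)
    if (nrow(le$reversals) > 0L) {
      rev_rows[[length(rev_rows) + 1L]] <- le$reversals %>%
        mutate(cluster_id = cid, .before = 1)
    }
    if (nrow(le$latest) == 0L) next
    msa <- msas[[cid]]
    for (k in seq_len(nrow(le$latest))) {
      ev <- le$latest[k, ]
      lr_res <- length_ratio(ev, tree, msa, state_vec, cp_vec)
      if (is.null(lr_res)) { skipped <- skipped + 1L; next }
      mech_rows[[length(mech_rows) + 1L]] <- ev %>%
        mutate(lr = lr_res$lr,
               category = mechanism_category(lr_res$lr, indel_threshold,
                                             substitution_range))
    }
  }
  mechanisms <- if (length(mech_rows) > 0) list_rbind(mech_rows) else
    tibble(cluster_id = character(), parent = integer(), child = integer(),
           type = character(), lr = numeric(), category = character())
  summary <- mechanisms %>%
    count(.data$type, .data$category, name = "n")
  list(
    mechanisms = mechanisms,
    summary = summary,
    reversals = if (length(rev_rows) > 0) list_rbind(rev_rows) else
      tibble(cluster_id = character(), anc_child = integer(),
             desc_child = integer(), anc_type = character(),
             desc_type = character()),
    skipped = skipped
  )
}
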