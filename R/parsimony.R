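# Fitch parsimony for discrete characters on rooted trees, branch event
# calling, taxonomic placement, and the event-by-lifestyle contingency table.

# Deterministically binarize a rooted tree: polytomies are resolved in a fixed
# (lexicographic, via multi2di with random = FALSE) order with zero-length
# branches so that per-branch event accounting is well defined.
binarize_tree <- function(tree) {
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Fitch parsimony reconstruction of ancestral discrete states
#'
#' Runs the two-pass Fitch algorithm for a discrete character on a rooted
#' tree. The bottom-up pass assigns each internal node the intersection of
#' its children's state sets when nonempty, otherwise their union (each union
#' contributes one state change to the minimal change count). The top-down
#' pass sets the root's final set to its bottom-up set and each child's final
#' set to the intersection of its bottom-up set with its parent's final set
#' when nonempty, otherwise its bottom-up set.
#'
#' @param tree Rooted `phylo` tree; polytomies are resolved deterministically
#'   with zero-length branches.
#' @param leaf_states Named integer vector (names = tip labels) of observed
#'   states, each in `states`.
#' @param states Vector of possible states (default `c(0, 1)`).
#' @return Object of class `sp_fitch` with components `tree` (the binarized
#'   tree), `states`, `bottom_up` and `final` (logical node-by-state
#'   matrices), and `changes` (minimal number of state changes).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' fitch(tr, c(a = 1, b = 0, c = 0, d = 0))
#' @export
fitch <- function(tree, leaf_states, states = c(0L, 1L)) {
  stopifnot(inherits(tree, "phylo"))
  tree <- binarize_tree(tree)
  if (!ape::is.rooted(tree)) abort("fitch() requires a rooted tree")
  ntip <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(leaf_states))
  if (length(missing) > 0) {
    abort(sprintf("missing leaf state for: %s", paste(missing, collapse = ", ")))
  }
  obs <- leaf_states[tree$tip.label]
  if (!all(obs %in% states)) {
    bad <- tree$tip.label[!obs %in% states][1]
    abort(sprintf("leaf '%s' has a state outside the state space", bad))
  }

  n_states <- length(states)
  n_nodes <- ntip + tree$Nnode
  bu <- matrix(FALSE, n_nodes, n_states)
  colnames(bu) <- as.character(states)
  for (i in seq_len(ntip)) bu[i, match(obs[i], states)] <- TRUE

  post <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(post[, 2], post[, 1])
  changes <- 0L
  # postorder edge order guarantees children are complete before the parent
  for (p in unique(post[, 1])) {
    kids <- children[[as.character(p)]]
    acc <- bu[kids[1], ]
    for (k in kids[-1]) {
      inter <- acc & bu[k, ]
      if (any(inter)) {
        acc <- inter
      } else {
        acc <- acc | bu[k, ]
        changes <- changes + 1L
      }
    }
    bu[p, ] <- acc
  }

  final <- bu
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  root <- ntip + 1L
  final[root, ] <- bu[root, ]
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1]; ch <- pre[k, 2]
    inter <- bu[ch, ] & final[p, ]
    final[ch, ] <- if (any(inter)) inter else bu[ch, ]
  }

  structure(
    list(tree = tree, states = states, bottom_up = bu, final = final,
         changes = changes),
    class = "sp_fitch"
  )
}

#' @export
print.sp_fitch <- function(x, ...) {
  cat(sprintf("<sp_fitch> %d tips, states {%s}, %d minimal change(s)\n",
              ape::Ntip(x$tree), paste(x$states, collapse = ", "), x$changes))
  invisible(x)
}

# final state set of one node as a vector of states
final_set <- function(rec, node) rec$states[rec$final[node, ]]

#' Call branch-level signal peptide events from a reconstruction
#'
#' Classifies every branch of the tree into exactly one of five types from
#' the final Fitch sets of its endpoints: `gain` (`{0}` to `{1}`), `loss`
#' (`{1}` to `{0}`), `keep_sp` (both `{1}`), `stay_no_sp` (both `{0}`), or
#' `uncertain` (at least one endpoint's final set is ambiguous). The root has
#' no parent branch and generates no event.
#'
#' @param reconstruction An `sp_fitch` object for the binary signal peptide
#'   character (states 0/1).
#' @param cluster_id Optional cluster identifier stored with each event.
#' @return Tibble with one row per branch: `cluster_id`, `parent`, `child`
#'   (node indices), `child_label` (tip label or `NA`), `type`.
#' @export
call_events <- function(reconstruction, cluster_id = NA_character_) {
  stopifnot(inherits(reconstruction, "sp_fitch"))
  tree <- reconstruction$tree
  ntip <- ape::Ntip(tree)
  fin <- reconstruction$final
  amb <- rowSums(fin) > 1L
  s1 <- fin[, 2] & !amb   # final set exactly {1}
  s0 <- fin[, 1] & !amb   # final set exactly {0}

  p <- tree$edge[, 1]; ch <- tree$edge[, 2]
  type <- dplyr::case_when(
    amb[p] | amb[ch] ~ "uncertain",
    s0[p] & s1[ch] ~ "gain",
    s1[p] & s0[ch] ~ "loss",
    s1[p] & s1[ch] ~ "keep_sp",
    TRUE ~ "stay_no_sp"
  )
  tibble(
    cluster_id = cluster_id,
    parent = p,
    child = ch,
    child_label = ifelse(ch <= ntip, tree$tip.label[ch], NA_character_),
    type = type
  )
}

TAXON_RANKS <- c("species", "genus", "family", "order")

#' Taxonomic rank of an event
#'
#' Finds the lowest taxonomic rank (species < genus < family < order) at
#' which the taxonomy paths of all leaf descendants of the event's child node
#' agree. A single descendant maps to `species`; descendants spanning more
#' than one family map to `order`.
#'
#' @param child Node index (the child endpoint of the event's branch).
#' @param tree Rooted `phylo` tree whose tip labels map to species via
#'   `leaf_species`.
#' @param taxonomy Tibble with columns `species_id`, `genus`, `family`,
#'   `order`.
#' @param leaf_species Named character vector mapping tip labels to
#'   `species_id`; defaults to the tip labels themselves.
#' @return One of `"species"`, `"genus"`, `"family"`, `"order"`.
#' @export
assign_event_rank <- function(child, tree, taxonomy, leaf_species = NULL) {
  ntip <- ape::Ntip(tree)
  tips <- node_descendant_tips(tree)[[child]]
  labels <- tree$tip.label[tips]
  species <- if (is.null(leaf_species)) labels else unname(leaf_species[labels])
  tax <- taxonomy[match(species, taxonomy$species_id), , drop = FALSE]
  if (anyNA(tax$species_id)) {
    abort(sprintf("no taxonomy entry for species '%s'",
                  species[is.na(tax$species_id)][1]))
  }
  if (length(unique(tax$species_id)) == 1L) return("species")
  if (length(unique(tax$genus)) == 1L) return("genus")
  if (length(unique(tax$family)) == 1L) return("family")
  "order"
}

# vectorized rank assignment for an events table
add_event_ranks <- function(events, tree, taxonomy, leaf_species = NULL) {
  tips_by_node <- node_descendant_tips(tree)
  labels <- tree$tip.label
  rank_of <- function(child) {
    species <- labels[tips_by_node[[child]]]
    if (!is.null(leaf_species)) species <- unname(leaf_species[species])
    tax <- taxonomy[match(species, taxonomy$species_id), , drop = FALSE]
    if (length(unique(tax$species_id)) == 1L) "species"
    else if (length(unique(tax$genus)) == 1L) "genus"
    else if (length(unique(tax$family)) == 1L) "family"
    else "order"
  }
  events %>% mutate(taxonomic_rank = map_chr(.data$child, rank_of))
}

#' Lifestyle transitions along a tree by 3-state parsimony
#'
#' Applies the Fitch algorithm to the three-state lifestyle character
#' (0 = free-living, 1 = endosymbiont, 2 = commensal) and classifies every
#' branch by the child's final state set: a singleton maps to the
#' corresponding `to_*` class, anything ambiguous to `uncertain_transition`.
#'
#' @param tree Rooted `phylo` tree.
#' @param lifestyles Named integer vector (names = tip labels) with values
#'   0, 1 or 2.
#' @return List with `reconstruction` (an `sp_fitch`) and `branches` (tibble:
#'   `parent`, `child`, `transition`).
#' @export
lifestyle_transitions <- function(tree, lifestyles) {
  rec <- fitch(tree, lifestyles, states = c(0L, 1L, 2L))
  fin <- rec$final
  single <- rowSums(fin) == 1L
  cls <- rep("uncertain_transition", nrow(fin))
  cls[single & fin[, 1]] <- "to_free_living"
  cls[single & fin[, 2]] <- "to_endosymbiont"
  cls[single & fin[, 3]] <- "to_commensal"
  branches <- tibble(
    parent = rec$tree$edge[, 1],
    child = rec$tree$edge[, 2],
    transition = cls[rec$tree$edge[, 2]]
  )
  list(reconstruction = rec, branches = branches)
}

EVENT_TYPES <- c("gain", "loss", "uncertain", "keep_sp", "stay_no_sp")
TRANSITION_CLASSES <- c("to_free_living", "to_endosymbiont", "to_commensal",
                        "uncertain_transition")

#' Estimate per-branch gain and loss rates from called events
#'
#' The raw called loss:gain count ratio does not estimate the underlying rate
#' ratio: losses can only happen on branches whose parent carries a signal
#' peptide and gains only on the rest, and restricting attention to mixed
#' clusters conditions on at least one event having happened. This estimator
#' divides each event count by its opportunity count -- branches with an
#' unambiguous parent state of 1 (for losses: `loss` + `keep_sp` branches) or
#' 0 (for gains: `gain` + `stay_no_sp`) -- and adds the branches of pure
#' positive/negative clusters, which carry opportunities but no events, to
#' undo the mixed-cluster ascertainment.
#'
#' @param events Branch events of the mixed clusters (see [call_events()]).
#' @param classes Cluster classification (see [classify_clusters()]); the
#'   `positive` and `negative` clusters contribute `2n - 2` branches each.
#' @return One-row tibble: `n_loss`, `n_gain`, `loss_opportunities`,
#'   `gain_opportunities`, `loss_rate`, `gain_rate`, `ratio`.
#' @export
estimate_event_rates <- function(events, classes) {
  n <- function(t) sum(events$type == t)
  pure <- classes %>%
    filter(.data$class_label %in% c("positive", "negative")) %>%
    mutate(branches = 2L * .data$n_members - 2L)
  pos_b <- sum(pure$branches[pure$class_label == "positive"])
  neg_b <- sum(pure$branches[pure$class_label == "negative"])
  loss_opp <- n("loss") + n("keep_sp") + pos_b
  gain_opp <- n("gain") + n("stay_no_sp") + neg_b
  loss_rate <- if (loss_opp > 0) n("loss") / loss_opp else NA_real_
  gain_rate <- if (gain_opp > 0) n("gain") / gain_opp else NA_real_
  tibble(
    n_loss = n("loss"), n_gain = n("gain"),
    loss_opportunities = loss_opp, gain_opportunities = gain_opp,
    loss_rate = loss_rate, gain_rate = gain_rate,
    ratio = loss_rate / gain_rate
  )
}

#' Contingency table of signal peptide events against lifestyle transitions
#'
#' Crosses the five branch event types with the four lifestyle transition
#' classes. Each branch of each cluster tree contributes exactly one cell;
#' percentages are computed within columns (per transition class).
#'
#' @param events Events tibble with columns `cluster_id`, `parent`, `child`,
#'   `type` (see [call_events()]).
#' @param transitions Tibble with columns `cluster_id`, `parent`, `child`,
#'   `transition` (see [lifestyle_transitions()]).
#' @return List with `counts` (5x4 integer matrix), `percent` (column
#'   percentages), `row_totals` and `col_totals`.
#' @export
crosstab_events_lifestyle <- function(events, transitions) {
  joined <- events %>%
    inner_join(transitions, by = c("cluster_id", "parent", "child"))
  if (nrow(joined) != nrow(events)) {
    abort("every event branch must have a matching lifestyle transition")
  }
  counts <- table(
    factor(joined$type, levels = EVENT_TYPES),
    factor(joined$transition, levels = TRANSITION_CLASSES)
  )
  counts <- matrix(as.integer(counts), nrow = length(EVENT_TYPES),
                   dimnames = list(EVENT_TYPES, TRANSITION_CLASSES))
  crosstab_percentages(counts)
}

#' Column percentages and totals for an event-by-transition table
#'
#' Pure tabulation arithmetic on a matrix of counts with event-type rows and
#' transition-class columns, usable both on pipeline output and on externally
#' reported counts.
#'
#' @param counts Numeric matrix (rows = event types, columns = transition
#'   classes).
#' @return List with `counts`, `percent` (each cell as a percentage of its
#'   column total), `row_totals`, `col_totals`.
#' @export
crosstab_percentages <- function(counts) {
  col_totals <- colSums(counts)
  pct <- sweep(counts, 2, ifelse(col_totals > 0, col_totals, 1), "/") * 100
  pct[, col_totals == 0] <- NA_real_
  list(
    counts = counts,
    percent = pct,
    row_totals = rowSums(counts),
    col_totals = col_totals
  )
}
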