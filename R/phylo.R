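# Alignment and tree utilities: pairwise identity, neighbor-joining stand-in
# trees, and midpoint rooting.

#' Pairwise sequence identity from an alignment
#'
#' Counts alignment columns in which both rows carry the same (non-gap)
#' residue and divides by the ungapped length of the shorter of the two
#' sequences. A pair that shares no aligned columns has identity 0.
#'
#' @param msa Named character vector of aligned rows (equal length, `-` gaps).
#' @param id_a,id_b Row names to compare.
#' @return Identity in `[0, 1]`.
#' @examples
#' pairwise_identity(c(x = "AB--", y = "ABCD"), "x", "y")
#' @export
pairwise_identity <- function(msa, id_a, id_b) {
  if (!id_a %in% names(msa)) abort(sprintf("unknown sequence id '%s'", id_a))
  if (!id_b %in% names(msa)) abort(sprintf("unknown sequence id '%s'", id_b))
  a <- strsplit(msa[[id_a]], "", fixed = TRUE)[[1]]
  b <- strsplit(msa[[id_b]], "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) abort("alignment rows differ in length")
  ident <- sum(a == b & a != "-")
  shorter <- min(sum(a != "-"), sum(b != "-"))
  if (shorter == 0L) return(0)
  ident / shorter
}

# all pairwise identities of an MSA as a symmetric matrix
identity_matrix <- function(msa) {
  m <- seq_char_matrix(msa)
  n <- nrow(m)
  ungapped <- rowSums(m != "-")
  out <- matrix(1, n, n, dimnames = list(names(msa), names(msa)))
  if (n < 2L) return(out)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      ident <- sum(m[i, ] == m[j, ] & m[i, ] != "-")
      shorter <- min(ungapped[i], ungapped[j])
      out[i, j] <- out[j, i] <- if (shorter == 0L) 0 else ident / shorter
    }
  }
  out
}

#' Identity distributions for mixed clusters
#'
#' Extracts every unordered within-cluster pair from the alignments of mixed
#' clusters and assigns it to one of three samples according to the members'
#' secretion states: both secreted, neither secreted, or exactly one secreted.
#'
#' @param members Tibble with columns `cluster_id`, `protein_id`, `state`
#'   (1 = signal peptide, 0 = none).
#' @param msas Named list of alignments (named character vectors), one per
#'   cluster.
#' @param max_identity Optional upper bound: pairs with identity
#'   `>= max_identity` are dropped (e.g. `0.95` to remove near-identical
#'   pairs).
#' @return List with `pairs` (tibble: `cluster_id`, `id_a`, `id_b`,
#'   `identity`, `pair_class`) and `means` (tibble: `pair_class`, `n`,
#'   `mean_identity`).
#' @export
identity_distributions <- function(members, msas, max_identity = NULL) {
  stopifnot(all(c("cluster_id", "protein_id", "state") %in% names(members)))
  per_cluster <- members %>%
    filter(.data$cluster_id %in% names(msas)) %>%
    group_by(.data$cluster_id) %>%
    dplyr::group_split()

  pair_rows <- map(per_cluster, function(cl) {
    cid <- cl$cluster_id[1]
    msa <- msas[[cid]]
    ids <- intersect(names(msa), cl$protein_id)
    if (length(ids) < 2L) return(NULL)
    st <- setNames(cl$state, cl$protein_id)[ids]
    im <- identity_matrix(msa[ids])
    idx <- which(upper.tri(im), arr.ind = TRUE)
    tibble(
      cluster_id = cid,
      id_a = ids[idx[, 1]],
      id_b = ids[idx[, 2]],
      identity = im[idx],
      n_sp = st[idx[, 1]] + st[idx[, 2]]
    )
  })
  pairs <- list_rbind(compact(pair_rows))
  if (nrow(pairs) == 0L) {
    pairs <- tibble(cluster_id = character(), id_a = character(),
                    id_b = character(), identity = numeric(),
                    pair_class = character())
  } else {
    pairs <- pairs %>%
      mutate(pair_class = dplyr::case_when(
        .data$n_sp == 2 ~ "both_sp",
        .data$n_sp == 0 ~ "neither_sp",
        TRUE ~ "one_sp"
      )) %>%
      select(-"n_sp")
  }
  if (!is.null(max_identity)) {
    pairs <- pairs %>% filter(.data$identity < max_identity)
  }
  means <- pairs %>%
    group_by(.data$pair_class) %>%
    summarise(n = dplyr::n(), mean_identity = mean(.data$identity),
              .groups = "drop")
  list(pairs = pairs, means = means)
}

#' Neighbor-joining tree from an alignment
#'
#' Builds an unrooted neighbor-joining tree on the distance matrix
#' `1 - pairwise identity`. This is a deliberately simple stand-in for
#' externally supplied maximum-likelihood trees: no distance correction is
#' applied, and negative branch lengths produced by NJ are clamped to zero.
#'
#' @param msa Named character vector of aligned rows (at least 3).
#' @return An unrooted `phylo` tree whose tips are the alignment row names.
#' @export
build_nj_tree <- function(msa) {
  if (length(msa) < 3L) abort("neighbor joining requires at least 3 sequences")
  d <- 1 - identity_matrix(msa)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# ---- midpoint rooting ------------------------------------------------------

# adjacency list (node -> tibble of neighbor, length) from a phylo edge matrix
phylo_adjacency <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, el[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, el[k]))
  }
  adj
}

# node path between two nodes (sequence of node indices), by BFS
phylo_node_path <- function(tree, from, to) {
  adj <- phylo_adjacency(tree)
  n_nodes <- length(adj)
  parent <- rep(NA_integer_, n_nodes)
  seen <- rep(FALSE, n_nodes)
  queue <- from; seen[from] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      u <- nb[i, 1]
      if (!seen[u]) { seen[u] <- TRUE; parent[u] <- v; queue <- c(queue, u) }
    }
  }
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the exact midpoint of the longest leaf-to-leaf
#' path. The two leaves realising the tree diameter end up equidistant from
#' the root (within `tol`). Ties between diameter pairs are broken by the
#' lexicographically smallest sorted pair of leaf labels, so the result is
#' deterministic. If the midpoint falls exactly on an internal node the root
#' is attached at that node. A rooted input is unrooted first. A tree whose
#' diameter is zero is rooted at an arbitrary internal node with a warning.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Tolerance for deciding that the midpoint coincides with a node.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (ntip == 2L) {
    len <- sum(tree$edge.length)
    out <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         tree$tip.label[1], len / 2,
                                         tree$tip.label[2], len / 2))
    return(out)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)

  D <- ape::dist.nodes(tree)[1:ntip, 1:ntip, drop = FALSE]
  diam <- max(D)
  if (diam <= tol) {
    warn("tree diameter is zero; rooting at an arbitrary internal node")
    return(root_at_node(tree, ntip + 1L))
  }
  cand <- which(D >= diam - tol & upper.tri(D), arr.ind = TRUE)
  labs <- tree$tip.label
  key <- vapply(seq_len(nrow(cand)), function(i) {
    p <- sort(c(labs[cand[i, 1]], labs[cand[i, 2]]))
    paste(p, collapse = "\r")
  }, character(1))
  pick <- cand[order(key)[1], ]
  a <- pick[1]; b <- pick[2]
  if (labs[a] > labs[b]) { tmp <- a; a <- b; b <- tmp }

  path <- phylo_node_path(tree, a, b)
  # cumulative distance from a along the path
  el_lookup <- function(u, v) {
    k <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                 (tree$edge[, 1] == v & tree$edge[, 2] == u))
    tree$edge.length[k]
  }
  steps <- vapply(seq_len(length(path) - 1L),
                  function(i) el_lookup(path[i], path[i + 1L]), numeric(1))
  cum <- c(0, cumsum(steps))
  h <- D[a, b] / 2

  i <- which(cum >= h - tol)[1]  # first node at or past the midpoint
  if (abs(cum[i] - h) <= tol) {
    # midpoint coincides with node path[i]
    node <- path[i]
    if (node <= ntip) {
      # can only happen at an endpoint of a zero-length path; fall back
      node <- path[which(path > ntip)[1]]
    }
    return(root_at_node(tree, node))
  }
  u <- path[i - 1L]; v <- path[i]  # midpoint strictly inside edge (u, v)
  # orientation in the stored edge matrix decides the reroot parameters
  k <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)
  if (length(k) == 1L) {
    child <- v
    pos <- h - cum[i - 1L]          # distance from u (the stored parent)
  } else {
    child <- u
    pos <- cum[i] - h               # distance from v (the stored parent)
  }
  phytools::reroot(tree, node.number = child, position = pos)
}

# root an unrooted phylo exactly at an existing node (a zero-length root
# edge keeps the result binary)
root_at_node <- function(tree, node) {
  k <- which(tree$edge[, 2] == node)
  if (length(k) == 1L) {
    phytools::reroot(tree, node.number = node,
                     position = tree$edge.length[k])
  } else {
    # node is the stored basal node: re-root through any child edge
    child <- tree$edge[which(tree$edge[, 1] == node)[1], 2]
    phytools::reroot(tree, node.number = child, position = 0)
  }
}

# leaf tip indices below each node of a rooted tree (list indexed by node)
node_descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  tips <- vector("list", n_nodes)
  for (i in seq_len(ntip)) tips[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; c <- edges[k, 2]
    tips[[p]] <- c(tips[[p]], tips[[c]])
  }
  tips
}
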