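# Independent oracles and fixture builders used across the suite.

# canonical signal peptide fixture: M + KK n-region + hydrophobic core +
# polar c-region with A-x-A at 16..18, cleavage after position 18
CANONICAL_SP_SEQ <- paste0("MKKILLAVAVLLASSAFA", "AEGSTNAQQTRLEMNPQRSTVWYHKDE")
TAT_SP_SEQ <- paste0("MSRRQFLKGLGALTVAASLQA", "AEGSTNAQQTRLEMNPQRSTD")
NO_SP_SEQ <- "MSTDENLYFQGAMDPEFNQRDESTKNDQGERDSTNQKEDRSTQN"

# brute-force minimal parsimony changes: enumerate every internal labeling
brute_force_parsimony <- function(tree, leaf_states, states = c(0L, 1L)) {
  ntip <- ape::Ntip(tree)
  n_internal <- tree$Nnode
  obs <- leaf_states[tree$tip.label]
  grid <- expand.grid(rep(list(states), n_internal))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(obs, as.integer(grid[g, ]))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# all labeled rooted binary tree shapes on the given tips (newick strings)
all_rooted_trees <- function(tips) {
  if (length(tips) == 1L) return(tips)
  out <- character(0)
  # split the first tip off deterministically to avoid duplicates:
  # enumerate subsets containing tips[1]
  n <- length(tips)
  other <- tips[-1]
  for (k in 0:(length(other) - 1L)) {
    combs <- utils::combn(other, k, simplify = FALSE)
    for (cc in combs) {
      left <- c(tips[1], cc)
      right <- setdiff(tips, left)
      for (l in all_rooted_trees(left)) {
        for (r in all_rooted_trees(right)) {
          out <- c(out, sprintf("(%s,%s)", l, r))
        }
      }
    }
  }
  out
}

# random rooted binary tree with branch lengths, deterministic under the seed
random_rooted_tree <- function(n, seed) {
  with_seed_local(seed, {
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- paste0("t", seq_len(n))
    tr
  })
}

with_seed_local <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exhaustive fixed-margin 2x2 Fisher p-values
enumerate_fisher <- function(a, b, c, d, sided = "two_tailed") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    stats::dhyper(k, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, r1, r2, c1)
  if (sided == "one_greater") {
    sum(probs[ks >= a])
  } else {
    sum(probs[probs <= p_obs + 1e-7 * p_obs])
  }
}

# direct ECDF sweep for the two-sample KS statistic
ks_statistic_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# patristic distance between two leaves by summing path edges (independent of
# ape::dist.nodes)
leaf_distance_oracle <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  adj <- list()
  add <- function(u, v, w) {
    key <- as.character(u)
    adj[[key]] <<- rbind(adj[[key]], c(v, w))
  }
  for (k in seq_len(nrow(tree$edge))) {
    add(tree$edge[k, 1], tree$edge[k, 2], tree$edge.length[k])
    add(tree$edge[k, 2], tree$edge[k, 1], tree$edge.length[k])
  }
  # BFS with distances
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  dist <- rep(NA_real_, n_nodes); dist[ia] <- 0
  queue <- ia
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]
      if (is.na(dist[u])) { dist[u] <- dist[v] + nb[r, 2]; queue <- c(queue, u) }
    }
  }
  dist[ib]
}

# small simulated dataset shared by several files (computed once per run)
shared_small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_species = 40, n_families = 60)
      cache <<- suppressMessages(simulate_dataset(cfg))
    }
    cache
  }
})
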