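# a quartet tree used by several fixtures: tips 1..4 = a, b, c, d;
# root = 5, (a,b) ancestor = 6, (c,d) ancestor = 7
quartet <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")

test_that("latest-event filtering keeps events nearest the leaves", {
  # single event: retained, no reversals
  ev1 <- tibble::tibble(cluster_id = "X", parent = 5L, child = 6L, type = "gain")
  res1 <- latest_events(ev1, quartet)
  expect_equal(nrow(res1$latest), 1L)
  expect_equal(nrow(res1$reversals), 0L)

  # a gain above a loss on the same path: only the loss is kept, 1 reversal
  ev2 <- tibble::tibble(cluster_id = "X", parent = c(5L, 6L),
                        child = c(6L, 1L), type = c("gain", "loss"))
  res2 <- latest_events(ev2, quartet)
  expect_equal(res2$latest$type, "loss")
  expect_equal(nrow(res2$reversals), 1L)
  expect_equal(res2$reversals$anc_type, "gain")

  # events on disjoint subtrees are both retained
  ev3 <- tibble::tibble(cluster_id = "X", parent = c(6L, 7L),
                        child = c(1L, 3L), type = c("gain", "loss"))
  res3 <- latest_events(ev3, quartet)
  expect_equal(nrow(res3$latest), 2L)
  expect_equal(nrow(res3$reversals), 0L)
})

test_that("double reversals are counted on alternating chains", {
  cat_tree <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  # tips a=1..d=4; root 5; (a,b,c)=6; (a,b)=7
  ev <- tibble::tibble(cluster_id = "X",
                       parent = c(5L, 6L, 7L),
                       child = c(6L, 7L, 1L),
                       type = c("loss", "gain", "loss"))
  res <- latest_events(ev, cat_tree)
  expect_equal(res$latest$child, 1L)
  expect_equal(res$n_double_reversals, 1L)
})

test_that("latest events form an antichain in the ancestor order", {
  for (seed in 1:5) {
    tr <- random_rooted_tree(8, seed + 40L)
    branches <- tibble::tibble(parent = tr$edge[, 1], child = tr$edge[, 2])
    ev <- with_seed_local(seed, {
      idx <- sample(nrow(branches), 5)
      branches[idx, ] %>%
        dplyr::mutate(cluster_id = "X",
                      type = sample(c("gain", "loss"), 5, replace = TRUE))
    })
    res <- latest_events(ev, tr)
    anc <- sigpevo:::node_ancestry_matrix(tr)
    le <- res$latest
    if (nrow(le) >= 2) {
      for (i in seq_len(nrow(le))) for (j in seq_len(nrow(le))) {
        if (i == j) next
        expect_false(le$child[i] == le$parent[j] ||
                       sigpevo:::is_strict_ancestor(anc$parent, le$child[i],
                                                    le$parent[j]))
      }
    }
  }
})

# alignment fixture for length ratios: s (with SP, cleavage 24) against
# various non-SP partners
lr_fixture <- function() {
  sp <- paste0(strrep("K", 24), strrep("B", 10))     # 24 SP cols + body
  t_gapped <- paste0(strrep("-", 24), strrep("B", 10))
  t_full <- paste0(strrep("Q", 24), strrep("B", 10))
  t_half <- paste0(strrep("-", 12), strrep("Q", 12), strrep("B", 10))
  c(s = sp, t0 = t_gapped, t1 = t_full, t05 = t_half)
}

test_that("length ratio separates elimination, retention and shortening", {
  msa <- lr_fixture()
  tree <- ape::read.tree(text = "((s:1,t0:1):1,(t1:1,t05:1):1);")
  states <- c(s = 1L, t0 = 0L, t1 = 0L, t05 = 0L)
  cp <- c(s = 24L, t0 = NA, t1 = NA, t05 = NA)
  ev <- tibble::tibble(parent = 5L, child = 6L)  # parent subtree = all tips
  res <- length_ratio(ev, tree, msa, states, cp)
  lr_by <- setNames(res$pairs$lr, res$pairs$nosp_id)
  expect_equal(unname(lr_by[["t0"]]), 0)      # full elimination
  expect_equal(unname(lr_by[["t1"]]), 1)      # same length
  expect_equal(unname(lr_by[["t05"]]), 0.5)   # shortened
  expect_equal(res$lr, mean(c(0, 1, 0.5)))
})

test_that("length ratio is skipped without a usable signal peptide descendant", {
  msa <- lr_fixture()
  tree <- ape::read.tree(text = "((s:1,t0:1):1,(t1:1,t05:1):1);")
  states <- c(s = 1L, t0 = 0L, t1 = 0L, t05 = 0L)
  no_cp <- c(s = NA_integer_, t0 = NA_integer_, t1 = NA_integer_,
             t05 = NA_integer_)
  ev <- tibble::tibble(parent = 5L, child = 6L)
  expect_null(length_ratio(ev, tree, msa, states, no_cp))
})

test_that("mechanism categories follow the configured thresholds", {
  expect_identical(mechanism_category(c(0, 0.05, 0.1, 0.3, 0.9, 1, 1.1, 1.5)),
                   c("indel", "indel", "indel", "intermediate", "substitution",
                     "substitution", "substitution", "intermediate"))
  expect_true(is.na(mechanism_category(NA_real_)))
})

test_that("N-terminal identity profile isolates the cleavage-site columns", {
  # identical N-termini
  msa_same <- c(s = paste0(strrep("K", 21), "AQA", strrep("B", 5)),
                t = paste0(strrep("K", 21), "AQA", strrep("B", 5)))
  tree <- ape::read.tree(text = "(s:1,t:1);")
  states <- c(s = 1L, t = 0L)
  cp <- c(s = 24L, t = NA)
  ev <- tibble::tibble(parent = 3L, child = 1L)
  prof <- nterm_identity_profile(ev, tree, msa_same, states, cp)
  expect_equal(prof$nterm_identity, 1)
  expect_equal(prof$cleavage_site_identity, 1)
  expect_equal(prof$remainder_identity, 1)

  # differing only at the three cleavage-site columns (positions 22..24)
  msa_site <- c(s = paste0(strrep("K", 21), "AQA", strrep("B", 5)),
                t = paste0(strrep("K", 21), "QEG", strrep("B", 5)))
  prof2 <- nterm_identity_profile(ev, tree, msa_site, states, cp)
  expect_equal(prof2$cleavage_site_identity, 0)
  expect_equal(prof2$remainder_identity, 1)

  # Spearman over a monotone set of (site, remainder) identities is 1
  site_id <- c(0.2, 0.5, 0.9)
  rem_id <- c(0.3, 0.6, 0.95)
  expect_equal(spearman(site_id, rem_id)$rho, 1)
})

test_that("mechanism summary handles empty event sets and tabulates counts", {
  empty <- tibble::tibble(cluster_id = character(), parent = integer(),
                          child = integer(), type = character())
  res <- mechanism_summary(empty, list(), list(),
                           states = tibble::tibble(protein_id = character(),
                                                   state = integer()),
                           cleavage = tibble::tibble(protein_id = character(),
                                                     cleavage_pos = integer()))
  expect_equal(nrow(res$mechanisms), 0L)
  expect_equal(nrow(res$summary), 0L)
})

test_that("planted mechanisms are recovered from clean simulations", {
  cfg <- sim_config(seed = 13, n_species = 30, n_families = 80,
                    start_error_rate = 0, mechanism_mix = 0.5,
                    sp_loss_rate = 0.05, sp_gain_rate = 0.0125,
                    tat_fraction = 0)
  ds <- suppressMessages(simulate_dataset(cfg))
  rep <- suppressMessages(run_all(ds))
  planted <- purrr::list_rbind(purrr::map(ds$truth$families, "events"))
  j <- dplyr::inner_join(rep$mechanism$mechanisms, planted,
                         by = c("cluster_id", "parent", "child", "type"))
  expect_gt(nrow(j), 10)
  agree <- mean(j$mechanism == j$category)
  expect_gt(agree, 0.85)
  # indel events sit near 0, substitution events near 1
  expect_true(all(j$lr[j$mechanism == "indel"] < 0.5))
  expect_true(all(j$lr[j$mechanism == "substitution"] > 0.5))
})
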