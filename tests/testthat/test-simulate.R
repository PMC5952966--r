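test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_species = 2), "n_species")
  expect_error(sim_config(lifestyle_fractions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(family_size_range = c(2, 10)), "family_size_range")
  expect_error(sim_config(sp_loss_rate = -0.1), "probabilities|rates")
  expect_error(sim_config(mechanism_mix = 1.5), "probabilities")
})

test_that("taxonomy simulation: degenerate all-free-living case and determinism", {
  cfg <- sim_config(seed = 3, n_species = 3,
                    lifestyle_fractions = c(free_living = 1, endosymbiont = 0,
                                            commensal = 0))
  tax <- simulate_taxonomy(cfg)
  expect_equal(nrow(tax$species), 3L)
  expect_true(all(tax$species$lifestyle == "free_living"))
  expect_true(all(tax$species$lifestyle_code == 0L))
  expect_true(ape::is.rooted(tax$tree))
  tax2 <- simulate_taxonomy(cfg)
  expect_identical(tax$species, tax2$species)
  expect_identical(ape::write.tree(tax$tree), ape::write.tree(tax2$tree))
})

test_that("taxonomy ranks are consistent with tree clades", {
  cfg <- sim_config(seed = 8, n_species = 40)
  tax <- simulate_taxonomy(cfg)
  expect_true(all(tax$tree$edge.length > 0))
  expect_true(ape::is.binary(tax$tree))
  for (g in unique(tax$species$genus)) {
    sp <- tax$species$species_id[tax$species$genus == g]
    if (length(sp) > 1) {
      expect_true(ape::is.monophyletic(tax$tree, sp))
    }
  }
  for (f in unique(tax$species$family)) {
    sp <- tax$species$species_id[tax$species$family == f]
    if (length(sp) > 1) {
      expect_true(ape::is.monophyletic(tax$tree, sp))
    }
  }
})

test_that("lifestyle counts follow the configured fractions", {
  cfg <- sim_config(seed = 12, n_species = 153)
  tax <- simulate_taxonomy(cfg)
  counts <- table(factor(tax$species$lifestyle,
                         levels = c("free_living", "endosymbiont", "commensal")))
  expected <- 153 * cfg$lifestyle_fractions
  for (ls in names(expected)) {
    bound <- 2.58 * sqrt(153 * cfg$lifestyle_fractions[[ls]] *
                           (1 - cfg$lifestyle_fractions[[ls]]))
    expect_lte(abs(counts[[ls]] - expected[[ls]]), bound + 1)
  }
  # endosymbiont genomes are much smaller on average
  by_ls <- tapply(tax$species$genome_size, tax$species$lifestyle, mean)
  expect_lt(by_ls[["endosymbiont"]], by_ls[["free_living"]] / 2)
})

test_that("no-event limit: signal peptide everywhere, no planted events", {
  cfg <- sim_config(seed = 4, n_species = 8, n_families = 6,
                    ancestor_sp_prob = 1, sp_gain_rate = 0, sp_loss_rate = 0,
                    tat_fraction = 0, start_error_rate = 0)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$proteins$true_state == 1L))
  planted <- purrr::list_rbind(purrr::map(ds$truth$families, "events"))
  expect_equal(nrow(planted), 0L)
})

test_that("planted loss counts match the closed-form branch expectation", {
  r <- 0.3
  cfg <- sim_config(seed = 20, n_species = 12, n_families = 200,
                    family_size_range = c(10, 10), ancestor_sp_prob = 1,
                    sp_gain_rate = 0, sp_loss_rate = r, tat_fraction = 0,
                    start_error_rate = 0, substitution_rate = 0)
  ds <- simulate_dataset(cfg)
  # closed form: with no gains, E[losses below a signal-peptide-bearing node]
  # satisfies E(v) = sum over children c of [r + (1 - r) * E(c)]
  expected_losses <- function(tree) {
    ntip <- ape::Ntip(tree)
    e <- rep(0, ntip + tree$Nnode)
    post <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(post))) {
      p <- post[k, 1]; ch <- post[k, 2]
      e[p] <- e[p] + r + (1 - r) * e[ch]
    }
    e[ntip + 1L]
  }
  oracle <- vapply(ds$trees, expected_losses, numeric(1))
  per_family <- vapply(names(ds$trees), function(cid) {
    sum(ds$truth$families[[cid]]$events$type == "loss")
  }, numeric(1))
  se <- stats::sd(per_family) / sqrt(length(per_family))
  expect_lte(abs(mean(per_family) - mean(oracle)), 3 * se)
})

test_that("indel losses leave gaps across the signal peptide columns", {
  ds <- shared_small_dataset()
  checked <- 0L
  for (cid in names(ds$truth$families)) {
    fam <- ds$truth$families[[cid]]
    ev <- fam$events
    indel_losses <- ev[ev$type == "loss" & ev$mechanism == "indel", ]
    if (nrow(indel_losses) == 0L) next
    tree <- ds$trees[[cid]]
    ntip <- ape::Ntip(tree)
    prot <- ds$proteins[ds$proteins$cluster_id == cid, ]
    sp_tips <- prot$protein_id[prot$true_state == 1L & prot$true_start_shift == 0]
    if (length(sp_tips) == 0L) next
    m <- sigpevo:::seq_char_matrix(fam$true_msa)
    tips_by_node <- sigpevo:::node_descendant_tips(tree)
    for (k in seq_len(nrow(indel_losses))) {
      below <- tips_by_node[[indel_losses$child[k]]]
      below <- below[below <= ntip]
      for (tip in tree$tip.label[below] ) {
        if (!(tip %in% rownames(m)) || prot$true_state[prot$protein_id == tip] != 0L) next
        s <- sp_tips[1]
        cp <- prot$true_cleavage[prot$protein_id == s]
        sp_cols <- which(m[s, ] != "-")[seq_len(cp)]
        # the signal-peptide-free descendant aligns with gaps over most of the
        # donor's signal peptide columns (its own N-terminal segment is gone)
        expect_lte(sum(m[tip, sp_cols] != "-") / cp, 0.35)
        checked <- checked + 1L
      }
    }
    if (checked > 10L) break
  }
  expect_gt(checked, 0L)
})

test_that("translating the recorded coding region reproduces the protein", {
  ds <- shared_small_dataset()
  idx <- with_seed_local(2, sample(nrow(ds$proteins), 60))
  for (i in idx) {
    cds <- substr(ds$proteins$genomic[i], ds$proteins$cds_start[i],
                  ds$proteins$cds_end[i])
    expect_identical(translate_cds(cds), ds$proteins$sequence[i])
  }
})

test_that("the generator is deterministic and writes byte-identical files", {
  cfg <- sim_config(seed = 9, n_species = 10, n_families = 8)
  d1 <- suppressMessages(simulate_dataset(cfg))
  d2 <- suppressMessages(simulate_dataset(cfg))
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$msas, d2$msas)
  expect_identical(d1$predictions, d2$predictions)

  t1 <- tempfile(); t2 <- tempfile()
  write_sp_dataset(d1, t1)
  write_sp_dataset(d2, t2)
  f1 <- list.files(t1, recursive = TRUE)
  expect_identical(f1, list.files(t2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))),
                     label = f)
  }
})

test_that("a dataset directory reads back consistently", {
  cfg <- sim_config(seed = 9, n_species = 10, n_families = 8)
  ds <- suppressMessages(simulate_dataset(cfg))
  dir <- tempfile()
  write_sp_dataset(ds, dir)
  back <- read_sp_dataset(dir)
  expect_setequal(back$proteins$protein_id, ds$proteins$protein_id)
  expect_identical(sort(names(back$msas)), sort(names(ds$msas)))
  expect_equal(nrow(back$predictions), nrow(ds$predictions))
  j <- match(ds$proteins$protein_id, back$proteins$protein_id)
  expect_identical(back$proteins$sequence[j], ds$proteins$sequence)
  expect_identical(back$proteins$cds_start[j], ds$proteins$cds_start)
  # missing files are reported by name
  expect_error(read_sp_dataset(tempfile()), "missing input file")
})

test_that("planted start errors hide the signal peptide from the predictors", {
  ds <- shared_small_dataset()  # zero predictor noise
  preds <- add_consensus(ds$predictions)
  j <- dplyr::inner_join(ds$proteins, preds, by = "protein_id")
  corrupted <- j[j$true_start_shift > 0, ]
  expect_gt(nrow(corrupted), 0L)
  expect_true(all(corrupted$true_state == 1L))
  expect_true(all(corrupted$consensus == "NEGATIVE"))
  # shifts are concentrated around the signal peptide length
  expect_true(all(corrupted$true_start_shift >= 15))
  expect_true(all(corrupted$true_start_shift <= 40 + ds$config$start_shift_range[2]))
})

test_that("zero-noise predictor calls equal the ground-truth states", {
  ds <- shared_small_dataset()
  preds <- add_consensus(ds$predictions)
  j <- dplyr::inner_join(ds$proteins, preds, by = "protein_id")
  clean <- j[!j$tat & j$true_start_shift == 0, ]
  expect_true(all((clean$consensus == "POSITIVE") == (clean$true_state == 1L)))
  # Tat families are flagged by the Tat detector on every member
  tatm <- j[j$tat, ]
  if (nrow(tatm) > 0) expect_true(all(tatm$consensus == "TAT"))
})

test_that("predictor emulation honours calls, noise and score consistency", {
  p <- emulate_predictors(CANONICAL_SP_SEQ, seed = 1)
  expect_gt(p$signalp_score, 0.5)
  expect_true(p$signalp_call); expect_true(p$phobius_call)
  expect_false(p$tatp_call)
  expect_false(is.na(p$cleavage_pos))

  pt <- emulate_predictors(TAT_SP_SEQ, seed = 1)
  expect_true(pt$tatp_call)

  pn <- emulate_predictors(NO_SP_SEQ, seed = 1)
  expect_false(pn$signalp_call)
  expect_lt(pn$signalp_score, 0.5)
  expect_true(is.na(pn$cleavage_pos))

  # forced phobius flip produces a discordant triple
  pf <- emulate_predictors(CANONICAL_SP_SEQ,
                           c(signalp = 0, phobius = 1, tatp = 0), seed = 1)
  expect_true(pf$signalp_call); expect_false(pf$phobius_call)
  # score always sits on the same side of 0.5 as the call
  for (s in 1:20) {
    pr <- emulate_predictors(CANONICAL_SP_SEQ,
                             c(signalp = 0.5, phobius = 0.2, tatp = 0), seed = s)
    expect_identical(pr$signalp_score > 0.5, pr$signalp_call)
  }
  expect_error(emulate_predictors(""), "non-empty")
})

test_that("planted events lie on existing branches of the emitted tree", {
  ds <- shared_small_dataset()
  for (cid in names(ds$truth$families)) {
    ev <- ds$truth$families[[cid]]$events
    if (nrow(ev) == 0) next
    tree <- ds$trees[[cid]]
    edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
    expect_true(all(paste(ev$parent, ev$child) %in% edge_key))
    # leaf states are the readout of the planted history
    ntip <- ape::Ntip(tree)
    st <- ds$truth$families[[cid]]$node_states
    prot <- ds$proteins[ds$proteins$cluster_id == cid, ]
    expect_identical(st[match(prot$protein_id, tree$tip.label)],
                     prot$true_state)
  }
})
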