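# fixture helpers: build a coding record with fully controlled context

codon_of <- c(M = "ATG", A = "GCT", K = "AAA", L = "CTT", P = "CCT",
              S = "TCT", V = "GTT", F = "TTT", I = "ATT", Q = "CAA",
              E = "GAA", G = "GGT", T = "ACT", N = "AAT")

encode_protein <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(c(codon_of[chars], "TAA"), collapse = "")
}

# genomic record: upstream context (given as codons), CDS, downstream filler
make_record <- function(aa, upstream_codons = rep("CCT", 30),
                        downstream = strrep("C", 90)) {
  up <- paste(upstream_codons, collapse = "")
  cds <- encode_protein(aa)
  tibble::tibble(
    genomic = paste0(up, cds, downstream),
    cds_start = nchar(up) + 1L,
    cds_end = nchar(up) + nchar(cds)
  )
}

test_that("correction window derives limits from first-residue offsets", {
  # all rows start at column 1
  msa0 <- c(t = "MAAAA", s1 = "MKKLL", s2 = "MKKLA")
  expect_equal(correction_window(msa0, "t", c("s1", "s2")),
               c(upstream = 30, downstream = 30))

  # one SP member starts 12 non-gap columns before the target
  msa1 <- c(s1 = paste0(strrep("K", 12), "MAAAA"),
            t = paste0(strrep("-", 12), "MAAAA"))
  expect_equal(correction_window(msa1, "t", "s1"),
               c(upstream = 42, downstream = 30))

  # SP members start 5 before and 8 after the target
  msa2 <- c(s1 = paste0(strrep("K", 5), "MTTTTTTTTTAAAA"),
            t = paste0(strrep("-", 5), "MTTTTTTTTTAAAA"),
            s2 = paste0(strrep("-", 5), "--------MAAAAA"))
  expect_equal(correction_window(msa2, "t", c("s1", "s2")),
               c(upstream = 35, downstream = 38))

  expect_error(correction_window(msa0, "absent", "s1"), "not in the alignment")
  expect_error(correction_window(msa0, "t", character(0)), "nonempty")
})

test_that("alternative start enumeration finds planted in-frame starts", {
  aa <- paste(rep("A", 40), collapse = "")
  # no start codons anywhere in the window: only the shift-0 candidate
  rec0 <- make_record(aa, upstream_codons = rep("CCT", 30))
  cands0 <- enumerate_alt_starts(rec0, c(upstream = 30, downstream = 10))
  expect_equal(cands0$shift, 0L)

  # a GTG planted 24 codons upstream, clean path to the annotated start
  ups <- rep("CCT", 30); ups[30 - 23] <- "GTG"   # 24 codons before the CDS
  rec1 <- make_record(aa, upstream_codons = ups)
  cands1 <- enumerate_alt_starts(rec1, c(upstream = 30, downstream = 10))
  expect_true(-24L %in% cands1$shift)
  c24 <- cands1[cands1$shift == -24L, ]
  expect_equal(c24$codon, "GTG")
  expect_equal(nchar(c24$sequence), nchar(aa) + 24L)
  # the original protein is reproduced downstream of the extension
  expect_equal(substr(c24$sequence, 26, nchar(c24$sequence)),
               substr(aa, 2, nchar(aa)))

  # an in-frame stop between the upstream start and the gene excludes it
  ups2 <- ups; ups2[30 - 11] <- "TAA"
  rec2 <- make_record(aa, upstream_codons = ups2)
  cands2 <- enumerate_alt_starts(rec2, c(upstream = 30, downstream = 10))
  expect_false(-24L %in% cands2$shift)

  # downstream starts are reported with positive shifts
  aa_down <- paste0(strrep("A", 20), "M", strrep("A", 19))
  rec3 <- make_record(aa_down, upstream_codons = rep("CCT", 30))
  cands3 <- enumerate_alt_starts(rec3, c(upstream = 0, downstream = 30))
  expect_true(20L %in% cands3$shift)
  expect_equal(cands3$sequence[cands3$shift == 20L],
               paste0("M", strrep("A", 19)))
})

test_that("the shift-0 candidate reproduces the input record exactly", {
  ds <- shared_small_dataset()
  idx <- with_seed_local(5, sample(nrow(ds$proteins), 20))
  for (i in idx) {
    rec <- ds$proteins[i, ]
    cands <- enumerate_alt_starts(rec, c(upstream = 30, downstream = 30))
    zero <- cands[cands$shift == 0L, ]
    expect_equal(nrow(zero), 1L)
    expect_identical(zero$sequence, rec$sequence)
  }
})

test_that("correction decisions follow the priority rules", {
  base <- tibble::tibble(
    shift = c(0L, -24L), codon = c("ATG", "GTG"),
    sequence = c("MAAA", "MKKLLAAA"),
    signalp_score = c(0.1, 0.8),
    signalp_call = c(FALSE, TRUE),
    phobius_call = c(FALSE, TRUE),
    tatp_call = c(FALSE, FALSE)
  )
  dec <- decide_correction(base)
  expect_identical(dec$outcome, "accepted_positive")
  expect_identical(dec$candidate$shift, -24L)

  # a Tat-positive candidate rejects the whole cluster
  tat <- base; tat$tatp_call[2] <- TRUE
  expect_identical(decide_correction(tat)$outcome, "cluster_rejected_tat")

  # reliable negative at shift 0 plus a discordant alternative: keep negative
  disc <- base
  disc$signalp_call[2] <- TRUE; disc$phobius_call[2] <- FALSE
  expect_identical(decide_correction(disc)$outcome,
                   "accepted_negative_unchanged")

  # only discordant candidates at every start: delete the protein
  all_disc <- base
  all_disc$signalp_call <- c(TRUE, TRUE)
  all_disc$phobius_call <- c(FALSE, FALSE)
  expect_identical(decide_correction(all_disc)$outcome,
                   "protein_deleted_discordant")
})

test_that("among positive candidates the best SignalP score wins, ties by shift", {
  cands <- tibble::tibble(
    shift = c(-24L, -12L, 12L), codon = c("GTG", "ATG", "TTG"),
    sequence = c("a", "b", "c"),
    signalp_score = c(0.7, 0.9, 0.9),
    signalp_call = TRUE, phobius_call = TRUE, tatp_call = FALSE
  )
  dec <- decide_correction(cands)
  expect_identical(dec$outcome, "accepted_positive")
  expect_identical(dec$candidate$shift, -12L)  # 0.9 tie broken by |shift|
})

test_that("round 2 is a no-op when no start errors were planted", {
  cfg <- sim_config(seed = 31, n_species = 20, n_families = 40,
                    start_error_rate = 0)
  ds <- suppressMessages(simulate_dataset(cfg))
  rep <- suppressMessages(run_all(ds))
  expect_true(all(rep$decisions$outcome == "accepted_negative_unchanged"))
  expect_identical(rep$round1$event_counts, rep$round2$event_counts)
  expect_identical(rep$round1$clusters, rep$round2$clusters)
})

test_that("clusters dropping below three members are excluded from round 2", {
  ds <- shared_small_dataset()
  preds <- add_consensus(ds$predictions)
  classes <- classify_clusters(ds$membership, preds)
  mixed <- classes[classes$class_label == "mixed", ]
  mixed <- mixed[order(mixed$n_members), ]
  expect_gt(nrow(mixed), 0L)
  cid <- mixed$cluster_id[1]
  # delete enough members to push the cluster below the size-3 filter
  victim <- head(mixed$retained[[1]], mixed$n_members[1] - 2L)
  decisions <- tibble::tibble(
    cluster_id = cid, protein_id = victim,
    outcome = "protein_deleted_discordant",
    shift = NA_integer_, codon = NA_character_, sequence = NA_character_,
    signalp_score = NA_real_, signalp_call = NA, phobius_call = NA,
    tatp_call = NA, cleavage_pos = NA_integer_
  )
  r2 <- run_round2(ds, decisions)
  cls <- r2$classes
  expect_identical(cls$class_label[cls$cluster_id == cid], "rejected")
  expect_identical(cls$rejection_reason[cls$cluster_id == cid], "too_small")
  expect_false(cid %in% r2$round$events$cluster_id)
})

test_that("correction never touches consensus-positive proteins", {
  ds <- shared_small_dataset()
  preds <- add_consensus(ds$predictions)
  classes <- classify_clusters(ds$membership, preds)
  decisions <- suppressMessages(correct_gene_starts(ds, classes, preds))
  positives <- preds$protein_id[preds$consensus == "POSITIVE"]
  expect_false(any(decisions$protein_id %in% positives))
})
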