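test_that("discrimination score reproduces hand-computed values", {
  expect_equal(discrimination_score(5, 5, 3, 3), 0)
  expect_equal(discrimination_score(10, 0, 0, 10), 2)
  expect_equal(discrimination_score(3, 1, 1, 3), 1)
  expect_error(discrimination_score(0, 0, 1, 1), "nonempty")
})

test_that("discrimination score is antisymmetric, bounded and zero on equal proportions", {
  grid <- expand.grid(a_sp = 0:4, a_nosp = 0:4, b_sp = 0:4, b_nosp = 0:4)
  grid <- grid[grid$a_sp + grid$a_nosp >= 1 & grid$b_sp + grid$b_nosp >= 1, ]
  d_ab <- discrimination_score(grid$a_sp, grid$a_nosp, grid$b_sp, grid$b_nosp)
  d_ba <- discrimination_score(grid$b_sp, grid$b_nosp, grid$a_sp, grid$a_nosp)
  expect_equal(d_ab, -d_ba)
  expect_true(all(d_ab >= -2 & d_ab <= 2))
  same <- with(grid, a_sp * (b_sp + b_nosp) == b_sp * (a_sp + a_nosp))
  expect_true(all(abs(d_ab[same]) < 1e-12))
})

test_that("Fisher p-values match exhaustive fixed-margin enumeration", {
  set.seed(1)
  for (rep in 1:40) {
    tot <- sample(4:30, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    expect_equal(fisher_exact_2x2(tab, "two_tailed"),
                 enumerate_fisher(a, b, c, d, "two_tailed"), tolerance = 1e-8)
    expect_equal(fisher_exact_2x2(tab, "one_greater"),
                 enumerate_fisher(a, b, c, d, "one_greater"), tolerance = 1e-10)
  }
})

test_that("Fisher behaves at the boundaries", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, 2), "two_tailed"), 1)
  # one-sided p decreases as the top-left count grows at fixed margins
  ps <- vapply(0:5, function(k) {
    fisher_exact_2x2(matrix(c(k, 5 - k, 5 - k, k), 2, 2), "one_greater")
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("per-cluster discrimination analysis builds counts and skips empty groups", {
  members <- tibble::tibble(
    cluster_id = rep(c("A", "B"), each = 4),
    protein_id = paste0("p", 1:8),
    state = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L),
    lifestyle = c("free_living", "free_living", "endosymbiont", "endosymbiont",
                  "free_living", "free_living", "free_living", "free_living")
  )
  res <- discrimination_analysis(members, "free_living", "endosymbiont")
  expect_equal(nrow(res), 1L)  # cluster B has no endosymbiont: skipped
  expect_equal(res$cluster_id, "A")
  expect_equal(res$d, discrimination_score(2, 0, 0, 2))
})

test_that("GO propagation closes annotation sets over is_a edges", {
  ontology <- list(edges = tibble::tibble(
    child = c("leaf", "mid", "d1", "d2", "dleaf", "dleaf"),
    parent = c("mid", "root", "root", "root", "d1", "d2")
  ))
  ann <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                        term_id = c("root", "leaf", "dleaf"))
  closed <- go_propagate(ann, ontology)
  expect_setequal(closed$term_id[closed$protein_id == "p1"], "root")
  expect_setequal(closed$term_id[closed$protein_id == "p2"],
                  c("leaf", "mid", "root"))
  # diamond: root counted once
  p3 <- closed$term_id[closed$protein_id == "p3"]
  expect_setequal(p3, c("dleaf", "d1", "d2", "root"))
  expect_equal(sum(p3 == "root"), 1L)
})

test_that("GO propagation rejects cyclic ontologies", {
  cyc <- list(edges = tibble::tibble(child = c("a", "b"), parent = c("b", "a")))
  expect_error(go_propagate(tibble::tibble(protein_id = "p", term_id = "a"), cyc),
               "cycle")
})

test_that("enrichment p-values equal the hypergeometric tail", {
  groups <- tibble::tibble(
    protein_id = paste0("p", 1:105),
    group = c(rep("g1", 5), rep("g2", 100))
  )
  ann <- tibble::tibble(
    protein_id = c(paste0("p", 1:5), paste0("p", 6:10)),
    term_id = "T"
  )
  res <- go_enrichment(groups, ann)
  r1 <- res[res$group == "g1" & res$term_id == "T", ]
  # 5 of 5 in group vs 10 of 105 background
  oracle <- sum(stats::dhyper(5:5, 10, 95, 5))
  expect_equal(r1$p_one_sided, oracle, tolerance = 1e-12)
  expect_equal(r1$k_in_group, 5L)
  expect_equal(r1$K_background, 10L)
})

test_that("a term present in every protein is unenriched everywhere", {
  groups <- tibble::tibble(protein_id = paste0("p", 1:20),
                           group = rep(c("g1", "g2"), each = 10))
  ann <- tibble::tibble(protein_id = paste0("p", 1:20), term_id = "T")
  res <- go_enrichment(groups, ann)
  expect_true(all(res$p_one_sided == 1))
})

test_that("KS statistic matches a direct ECDF sweep", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:10, 1:10)$p, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(20); y <- rnorm(25, 0.4)
    expect_equal(ks_two_sample(x, y)$D, ks_statistic_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- 1:10
  expect_equal(spearman(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # tie-heavy fixture against a manual average-rank computation
  xt <- c(1, 2, 2, 2, 5, 5, 7)
  yt <- c(3, 3, 1, 6, 6, 2, 2)
  avg_rank <- function(v) {
    vapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2, numeric(1))
  }
  oracle <- stats::cor(avg_rank(xt), avg_rank(yt))
  expect_equal(spearman(xt, yt)$rho, oracle, tolerance = 1e-12)
  # p agrees with the t-approximation of cor.test
  ct <- stats::cor.test(xt, yt, method = "spearman", exact = FALSE)
  expect_equal(spearman(xt, yt)$p, ct$p.value, tolerance = 1e-8)
})

test_that("energy permutation test separates distinct multivariate samples", {
  set.seed(5)
  X <- matrix(rnorm(100), 50, 2)
  Y <- matrix(rnorm(100, mean = 3), 50, 2)
  res <- cvm_two_sample_multivariate(X, Y, n_permutations = 999, seed = 9)
  expect_lte(res$p, 0.01)
  expect_gte(res$p, 1 / 1000)
})

test_that("energy permutation test is calibrated under the null", {
  # a random split of one sample: the statistic is small and p not extreme
  set.seed(6)
  Z <- matrix(rnorm(120), 60, 2)
  res <- cvm_two_sample_multivariate(Z[1:30, ], Z[31:60, ],
                                     n_permutations = 199, seed = 10)
  expect_gte(res$p, 1 / 200)
  # type-I error at nominal 0.05 within binomial 99% bounds
  n_sims <- 400L
  rejections <- 0L
  set.seed(11)
  for (s in seq_len(n_sims)) {
    W <- matrix(rnorm(40), 20, 2)
    p <- cvm_two_sample_multivariate(W[1:10, ], W[11:20, ],
                                     n_permutations = 99, seed = s)$p
    if (p <= 0.05) rejections <- rejections + 1L
  }
  bound <- 2.58 * sqrt(n_sims * 0.05 * 0.95)
  expect_gte(rejections, floor(n_sims * 0.05 - bound))
  expect_lte(rejections, ceiling(n_sims * 0.05 + bound))
})

test_that("OBO round trip preserves terms and is_a edges", {
  ont <- simulate_go_dag <- list(
    terms = tibble::tibble(term_id = c("GO:1", "GO:2", "GO:3"),
                           name = c("root", "mid", "leaf")),
    edges = tibble::tibble(child = c("GO:2", "GO:3"), parent = c("GO:1", "GO:2"))
  )
  path <- tempfile(fileext = ".obo")
  write_obo(ont, path)
  back <- read_obo(path)
  expect_equal(back$terms$term_id, ont$terms$term_id)
  expect_equal(dplyr::arrange(back$edges, child),
               dplyr::arrange(ont$edges, child))
})
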