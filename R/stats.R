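# Lifestyle and functional association statistics: the discrimination score,
# Fisher tests, GO propagation and enrichment, and distribution comparisons.

#' Discrimination score between two lifestyles in a cluster
#'
#' `d = (a_sp - a_nosp) / (a_sp + a_nosp) - (b_sp - b_nosp) / (b_sp + b_nosp)`
#' where the four counts are the numbers of proteins of lifestyle `a` and `b`
#' with and without a signal peptide in one cluster. The score ranges from -2
#' to 2: values near -2 mean lifestyle `a` members tend to lack signal
#' peptides relative to lifestyle `b`, values near 2 the opposite, and values
#' near 0 are indecisive. All arguments are vectorised.
#'
#' @param a_sp,a_nosp,b_sp,b_nosp Nonnegative counts; each lifestyle group
#'   must be nonempty (`a_sp + a_nosp >= 1`, `b_sp + b_nosp >= 1`).
#' @return Numeric vector of scores in `[-2, 2]`.
#' @examples
#' discrimination_score(10, 0, 0, 10)  # 2, the attained maximum
#' discrimination_score(3, 1, 1, 3)    # 1
#' @export
discrimination_score <- function(a_sp, a_nosp, b_sp, b_nosp) {
  na <- a_sp + a_nosp
  nb <- b_sp + b_nosp
  if (any(na < 1) || any(nb < 1)) {
    abort("both lifestyle groups must be nonempty")
  }
  (a_sp - a_nosp) / na - (b_sp - b_nosp) / nb
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. `one_greater` gives the
#' upper tail probability for the top-left cell; `two_tailed` sums the
#' probabilities of all tables as or less probable than the observed one.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param sided `"one_greater"` or `"two_tailed"`.
#' @return P-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(table, sided = c("two_tailed", "one_greater")) {
  sided <- match.arg(sided)
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)), all(table >= 0))
  alternative <- if (sided == "one_greater") "greater" else "two.sided"
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' Per-cluster discrimination analysis
#'
#' Builds, for every cluster containing members of both lifestyles, the 2x2
#' table of lifestyle by secretion state, the discrimination score and a
#' two-tailed Fisher p-value. Clusters in which either lifestyle group is
#' empty are skipped.
#'
#' @param members Tibble with `cluster_id`, `protein_id`, `state` (0/1),
#'   `lifestyle`.
#' @param lifestyle_a,lifestyle_b The two lifestyles compared (`a` minus `b`
#'   in the score).
#' @return Tibble: `cluster_id`, `a_sp`, `a_nosp`, `b_sp`, `b_nosp`, `d`,
#'   `fisher_p`.
#' @export
discrimination_analysis <- function(members, lifestyle_a, lifestyle_b) {
  tab <- members %>%
    filter(.data$lifestyle %in% c(lifestyle_a, lifestyle_b)) %>%
    group_by(.data$cluster_id) %>%
    summarise(
      a_sp = sum(.data$lifestyle == lifestyle_a & .data$state == 1L),
      a_nosp = sum(.data$lifestyle == lifestyle_a & .data$state == 0L),
      b_sp = sum(.data$lifestyle == lifestyle_b & .data$state == 1L),
      b_nosp = sum(.data$lifestyle == lifestyle_b & .data$state == 0L),
      .groups = "drop"
    ) %>%
    filter(.data$a_sp + .data$a_nosp >= 1, .data$b_sp + .data$b_nosp >= 1)
  if (nrow(tab) == 0L) return(tab %>% mutate(d = numeric(0), fisher_p = numeric(0)))
  tab %>%
    mutate(
      d = discrimination_score(.data$a_sp, .data$a_nosp, .data$b_sp, .data$b_nosp),
      fisher_p = map_dbl(row_number(), function(i) {
        fisher_exact_2x2(matrix(c(tab$a_sp[i], tab$a_nosp[i],
                                  tab$b_sp[i], tab$b_nosp[i]),
                                2, 2, byrow = TRUE))
      })
    )
}

# ---- gene ontology ---------------------------------------------------------

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas (id, name, namespace, is_a) from an OBO file.
#' Only `is_a` relations are read.
#'
#' @param path Path to an OBO file.
#' @return List with `terms` (tibble: `term_id`, `name`) and `edges` (tibble:
#'   `child`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- tibble(term_id = cur$id,
                                             name = cur$name %||% NA_character_)
      for (p in cur$parents) {
        edges[[length(edges) + 1L]] <<- tibble(child = cur$id, parent = p)
      }
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || is.null(cur)) next
    if (grepl("^id: ", ln)) cur$id <- sub("^id: ", "", ln)
    if (grepl("^name: ", ln)) cur$name <- sub("^name: ", "", ln)
    if (grepl("^is_a: ", ln)) {
      cur$parents <- c(cur$parents, sub(" !.*$", "", sub("^is_a: ", "", ln)))
    }
  }
  flush()
  list(terms = list_rbind(terms), edges = list_rbind(edges))
}

#' Write an ontology in minimal OBO format
#'
#' @param ontology List with `terms` and `edges` as in [read_obo()].
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$term_id[i]
    parents <- ontology$edges$parent[ontology$edges$child == id]
    is_a <- if (length(parents) > 0) paste0("is_a: ", parents) else character(0)
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", ontology$terms$name[i]), is_a, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Propagate annotations to ancestral ontology terms
#'
#' Replaces each protein's term set by its ancestral closure over `is_a`
#' edges (each term plus all its ancestors up to the root, counted once).
#'
#' @param annotations Tibble with `protein_id`, `term_id`.
#' @param ontology List with `edges` (tibble `child`, `parent`); must be
#'   acyclic.
#' @return Tibble with the closed annotation sets (distinct
#'   `protein_id`/`term_id` pairs).
#' @export
go_propagate <- function(annotations, ontology) {
  edges <- ontology$edges
  all_terms <- unique(c(edges$child, edges$parent, annotations$term_id))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = all_terms)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    bad <- igraph::ends(g, cyc[1])
    abort(sprintf("ontology contains a cycle involving %s and %s",
                  bad[1], bad[2]))
  }
  ancestors <- setNames(map(all_terms, function(t) {
    names(igraph::subcomponent(g, t, mode = "out"))
  }), all_terms)
  annotations %>%
    distinct(.data$protein_id, .data$term_id) %>%
    mutate(term_id = unname(ancestors[.data$term_id])) %>%
    tidyr::unnest("term_id") %>%
    distinct(.data$protein_id, .data$term_id)
}

#' GO term enrichment per protein group
#'
#' One-sided Fisher's exact test for each term in each group, with the
#' pooled occurrence frequency over all groups as background: for a term
#' annotated on `K` of the `N` background proteins and `k` of the `n` group
#' proteins, the p-value is the upper hypergeometric tail of `k`.
#'
#' @param groups Tibble with `protein_id`, `group`.
#' @param closed_annotations Closed annotation sets from [go_propagate()].
#' @return Tibble: `group`, `term_id`, `k_in_group`, `n_group`,
#'   `K_background`, `N_background`, `p_one_sided`, sorted by p within
#'   group.
#' @export
go_enrichment <- function(groups, closed_annotations) {
  groups <- groups %>% distinct(.data$protein_id, .data$group)
  background <- groups %>% distinct(.data$protein_id)
  N <- nrow(background)
  ann <- closed_annotations %>%
    semi_join(background, by = "protein_id")
  term_bg <- ann %>% count(.data$term_id, name = "K_background")

  per_group <- groups %>% count(.data$group, name = "n_group")
  counts <- groups %>%
    inner_join(ann, by = "protein_id",
               relationship = "many-to-many") %>%
    count(.data$group, .data$term_id, name = "k_in_group")

  tidyr::expand_grid(group = per_group$group, term_id = term_bg$term_id) %>%
    left_join(per_group, by = "group") %>%
    left_join(term_bg, by = "term_id") %>%
    left_join(counts, by = c("group", "term_id")) %>%
    mutate(
      k_in_group = tidyr::replace_na(.data$k_in_group, 0L),
      N_background = N,
      p_one_sided = stats::phyper(.data$k_in_group - 1L, .data$K_background,
                                  N - .data$K_background, .data$n_group,
                                  lower.tail = FALSE)
    ) %>%
    select("group", "term_id", "k_in_group", "n_group", "K_background",
           "N_background", "p_one_sided") %>%
    arrange(.data$group, .data$p_one_sided)
}

# ---- distribution comparisons ---------------------------------------------

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' distribution functions; the p-value uses the asymptotic two-sample
#' formula.
#'
#' @param x,y Numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Spearman rank correlation with t-approximation
#'
#' Rank correlation using average ranks for ties; the p-value uses the
#' t-distribution approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_))  # constant input: undefined
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# energy statistic from a pooled distance matrix and an index split
energy_statistic_idx <- function(D, ix, iy) {
  n <- length(ix); m <- length(iy)
  dxy <- mean(D[ix, iy, drop = FALSE])
  dxx <- sum(D[ix, ix]) / (n * n)
  dyy <- sum(D[iy, iy]) / (m * m)
  (n * m / (n + m)) * (2 * dxy - dxx - dyy)
}

# Euclidean energy-distance statistic between two multivariate samples
energy_statistic <- function(X, Y) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(rbind(X, Y)))
  energy_statistic_idx(D, seq_len(n), n + seq_len(nrow(Y)))
}

#' Permutation two-sample test for multivariate distributions
#'
#' Energy-distance statistic between two multivariate samples with a
#' permutation p-value: group labels are reshuffled `n_permutations` times
#' under a fixed seed and the p-value is
#' `(1 + #{permuted >= observed}) / (n_permutations + 1)`, so it is never
#' smaller than `1 / (n_permutations + 1)`.
#'
#' @param X,Y Numeric matrices (rows = observations, same number of
#'   columns).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `statistic` and `p`.
#' @export
cvm_two_sample_multivariate <- function(X, Y, n_permutations = 999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y), nrow(X) >= 2L, nrow(Y) >= 2L)
  n <- nrow(X); m <- nrow(Y)
  D <- as.matrix(stats::dist(rbind(X, Y)))
  obs <- energy_statistic_idx(D, seq_len(n), n + seq_len(m))
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n + m)
      stat_b <- energy_statistic_idx(D, idx[seq_len(n)], idx[n + seq_len(m)])
      if (stat_b >= obs) exceed <- exceed + 1L
    }
    list(statistic = obs, p = (1 + exceed) / (n_permutations + 1))
  })
}
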