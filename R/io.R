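# Reading and writing the on-disk dataset layout: FASTA sequences, TSV
# tables, aligned FASTA alignments, Newick trees, an OBO ontology and a
# ground-truth JSON.

write_fasta <- function(seqs, path, aa = TRUE) {
  x <- if (aa) Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fasta <- function(path, aa = TRUE) {
  x <- if (aa) Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a simulated dataset to a directory
#'
#' Emits the full on-disk layout: `proteins.faa`, `cds.fna` (with CDS
#' coordinates in the headers), `clusters.tsv`, `predictions.tsv`,
#' `taxonomy.tsv`, `lifestyles.tsv`, `msa/<cluster>.afa`,
#' `trees/<cluster>.nwk`, `go.obo`, `annotations.tsv` and `truth.json`.
#'
#' @param dataset An `sp_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sp_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "msa"), showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)

  prot <- dataset$proteins
  write_fasta(setNames(prot$sequence, prot$protein_id),
              file.path(dir, "proteins.faa"), aa = TRUE)
  cds_names <- sprintf("%s cds_start=%d cds_end=%d", prot$protein_id,
                       prot$cds_start, prot$cds_end)
  write_fasta(setNames(prot$genomic, cds_names),
              file.path(dir, "cds.fna"), aa = FALSE)

  readr::write_tsv(dataset$membership, file.path(dir, "clusters.tsv"))
  readr::write_tsv(dataset$predictions, file.path(dir, "predictions.tsv"))
  readr::write_tsv(dataset$species %>%
                     select("species_id", "order", "family", "genus"),
                   file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(dataset$species %>%
                     select("species_id", "lifestyle", "lifestyle_code",
                            "genome_size"),
                   file.path(dir, "lifestyles.tsv"))

  for (cid in names(dataset$msas)) {
    write_fasta(dataset$msas[[cid]],
                file.path(dir, "msa", paste0(cid, ".afa")), aa = TRUE)
    ape::write.tree(dataset$trees[[cid]],
                    file.path(dir, "trees", paste0(cid, ".nwk")))
  }

  if (!is.null(dataset$go)) {
    write_obo(dataset$go, file.path(dir, "go.obo"))
    readr::write_tsv(dataset$annotations, file.path(dir, "annotations.tsv"))
  }

  truth <- list(
    config_seed = dataset$config$seed,
    families = map(dataset$truth$families, function(f) {
      list(node_states = f$node_states, events = f$events,
           true_msa = as.list(f$true_msa), tat = f$tat, root_sp = f$root_sp)
    }),
    proteins = dataset$proteins %>%
      select("protein_id", "true_state", "true_cleavage", "true_start_shift",
             "tat")
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_sp_dataset()]
#'
#' @param dir Dataset directory.
#' @return An `sp_dataset` (without the simulation `config`; the stored seed
#'   is kept in `config$seed` for downstream seeding).
#' @export
read_sp_dataset <- function(dir) {
  req <- c("proteins.faa", "cds.fna", "clusters.tsv", "predictions.tsv",
           "taxonomy.tsv", "lifestyles.tsv")
  for (f in req) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("missing input file '%s' in %s", f, dir))
    }
  }
  aa <- read_fasta(file.path(dir, "proteins.faa"), aa = TRUE)
  cds <- read_fasta(file.path(dir, "cds.fna"), aa = FALSE)
  cds_meta <- stringr::str_match(names(cds),
                                 "^(\\S+) cds_start=(\\d+) cds_end=(\\d+)")
  membership <- readr::read_tsv(file.path(dir, "clusters.tsv"),
                                show_col_types = FALSE)
  predictions <- readr::read_tsv(file.path(dir, "predictions.tsv"),
                                 show_col_types = FALSE)
  taxonomy <- readr::read_tsv(file.path(dir, "taxonomy.tsv"),
                              show_col_types = FALSE)
  lifestyles <- readr::read_tsv(file.path(dir, "lifestyles.tsv"),
                                show_col_types = FALSE)
  species <- taxonomy %>% left_join(lifestyles, by = "species_id")

  genomic <- setNames(unname(cds), cds_meta[, 2])
  proteins <- tibble(
    protein_id = names(aa),
    sequence = unname(aa),
    genomic = unname(genomic[names(aa)]),
    cds_start = as.integer(cds_meta[match(names(aa), cds_meta[, 2]), 3]),
    cds_end = as.integer(cds_meta[match(names(aa), cds_meta[, 2]), 4])
  ) %>%
    left_join(membership, by = "protein_id")
  # species of a protein is encoded as <cluster>|<species> by the generator;
  # fall back to that convention when no explicit mapping file exists
  proteins$species_id <- sub("^[^|]*\\|", "", proteins$protein_id)

  msas <- list()
  trees <- list()
  for (f in list.files(file.path(dir, "msa"), pattern = "\\.afa$")) {
    cid <- sub("\\.afa$", "", f)
    msas[[cid]] <- read_fasta(file.path(dir, "msa", f), aa = TRUE)
  }
  for (f in list.files(file.path(dir, "trees"), pattern = "\\.nwk$")) {
    cid <- sub("\\.nwk$", "", f)
    trees[[cid]] <- ape::read.tree(file.path(dir, "trees", f))
  }

  go <- NULL; annotations <- NULL
  if (file.exists(file.path(dir, "go.obo"))) {
    go <- read_obo(file.path(dir, "go.obo"))
    annotations <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                                   show_col_types = FALSE)
  }

  truth <- NULL
  seed <- 1L
  if (file.exists(file.path(dir, "truth.json"))) {
    tr <- jsonlite::read_json(file.path(dir, "truth.json"))
    seed <- tr$config_seed %||% 1L
    truth <- list(families = map(tr$families, function(f) {
      list(
        node_states = unlist(f$node_states),
        events = list_rbind(map(f$events, as_tibble)),
        true_msa = unlist(f$true_msa),
        tat = isTRUE(f$tat), root_sp = isTRUE(f$root_sp)
      )
    }))
  }

  structure(list(
    config = sim_config(seed = seed, n_species = max(3L, nrow(species)),
                        n_families = max(1L, length(msas))),
    species = species,
    proteins = proteins,
    membership = membership,
    predictions = predictions,
    msas = msas,
    trees = trees,
    go = go,
    annotations = annotations,
    truth = truth
  ), class = "sp_dataset")
}
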