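# Shared constants and small helpers.

# Kyte-Doolittle hydropathy scale, used to score candidate h-regions.
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AMINO_ACIDS <- names(KD_SCALE)

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
check_protein_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AMINO_ACIDS)
  if (length(bad) > 0L) {
    abort(sprintf(
      "`%s` contains non-standard residues at position(s) %s: %s",
      arg, paste(head(bad, 5L), collapse = ", "),
      paste(unique(chars[head(bad, 5L)]), collapse = ", ")
    ))
  }
  invisible(chars)
}

# Deterministic stream of sub-seeds so that independently seeded stages do not
# share or disturb the global RNG sequence.
seed_stream <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Split aligned/unaligned sequences into a character matrix (rows = sequences).
seq_char_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1L)
  m <- do.call(rbind, strsplit(unname(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Translate an in-frame coding sequence (no internal stops expected); the
# initiator codon is always rendered as M, trailing stop codons are dropped.
translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L, n >= 3L)
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) abort("coding sequence contains an invalid codon")
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) abort("coding sequence contains an internal stop codon")
  aa[1L] <- "M"
  paste(aa, collapse = "")
}

codon_table_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

fmt_pct <- function(x, digits = 1) round(100 * x, digits)
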