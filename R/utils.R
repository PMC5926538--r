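#' @useDynLib syntelnc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' @param seq character scalar over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Strand vocabulary: "+", "-", "*" ("*" = unknown, GRanges convention).
.check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-", "*")
  if (any(bad)) {
    stop("invalid strand value(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  strand
}

# Derive a child RNG seed from a base seed and a string label, stable across
# sessions and platforms, always < 2^31.
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 599999L) * 3571L + (h %% 599993L)
}

# Evaluate `expr` with a local RNG state seeded from `seed` (restores the
# caller's .Random.seed afterwards).
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
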