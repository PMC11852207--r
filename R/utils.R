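#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over a character vector of DNA sequences
#' (alphabet A, C, G, T, N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAGN"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All k-mers of a sequence
#'
#' Forward-strand k-mers at every start position (0-based starts returned as
#' an attribute-free integer vector alongside via names is avoided; callers
#' use position = index - 1).
#'
#' @param sequence single DNA string.
#' @param k word length.
#' @return character vector of length `nchar(sequence) - k + 1` (empty when
#'   the sequence is shorter than k).
#' @export
seq_kmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  L <- nchar(sequence)
  if (L < k) return(character(0))
  substring(sequence, 1:(L - k + 1L), k:L)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
# All seeded operations in the package go through this so that library
# calls never perturb user-level randomness.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; used by the design and simulation generators.
#'
#' @param length sequence length in bp.
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched.
#' @return a single DNA string.
#' @export
random_dna <- function(length, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

# Validate a DNA alphabet (strict ACGT unless allow_n).
check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: %s",
                 what, if (allow_n) ",N" else "",
                 paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Derive a child seed from a master seed and a stage offset, kept below
# 2^31 so it is always a valid R integer.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}
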