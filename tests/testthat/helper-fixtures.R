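# Shared fixtures, built once per test run. The "small" design keeps the
# exhaustive decoder and reference enumeration cheap (3 modules, 16
# configurations, ~800 bp amplicon); the full-size default design is used
# where the assay geometry itself matters.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

small_design <- function() get_fixture("small_design", function() {
  default_design(module_lengths = c(80L, 100L, 120L), anchor_length = 200L,
                 seed = 42L)
})

small_refs <- function() get_fixture("small_refs", function() {
  render_reference_set(small_design())
})

small_index <- function() get_fixture("small_index", function() {
  build_marker_index(small_design())
})

full_design <- function() get_fixture("full_design", default_design)

full_refs <- function() get_fixture("full_refs", function() {
  render_reference_set(full_design())
})

full_index <- function() get_fixture("full_index", function() {
  build_marker_index(full_design())
})

# Naive O(L^2) all-pairs repeat oracle, deliberately independent of the
# k-mer-table implementation in find_repeats(): compares every window
# pair directly.
oracle_repeats <- function(sequence, k = 13L) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  km <- substring(sequence, 1:(L - k + 1L), k:L)
  ok <- !grepl("N", km, fixed = TRUE)
  km <- km[ok]
  if (!length(km)) return(character(0))
  rc <- revcomp(km)
  direct <- outer(km, km, "==")
  diag(direct) <- FALSE
  inverted <- outer(km, rc, "==")
  hit <- apply(direct, 1, any) | apply(inverted, 1, any)
  sort(unique(pmin(km[hit], rc[hit])))
}
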