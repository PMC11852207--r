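test_that("library simulation is seed-reproducible and rate-faithful", {
  a <- simulate_library(5, 50, event_rate = 2, seed = 99L)
  b <- simulate_library(5, 50, event_rate = 2, seed = 99L)
  expect_identical(a, b)
  expect_false(identical(a, simulate_library(5, 50, event_rate = 2,
                                             seed = 100L)))
  # event_rate 0: every member stays at reference
  quiet <- simulate_library(5, 40, event_rate = 0, seed = 1L)
  expect_identical(unique(names(quiet)), format_config(1:5))
  # fixed single event: every member at BFS depth 1
  depths <- reachable_set(5)
  one <- simulate_library(5, 60, event_rate = 0, fixed_events = 1L,
                          seed = 3L)
  expect_identical(unique(unname(depths[names(one)])), 1L)
})

test_that("simulated members are always valid configurations", {
  lib <- simulate_library(5, 200, event_rate = 4, seed = 17L)
  for (cf in lib) expect_silent(validate_config(cf))
  # weights must be sane
  expect_error(simulate_library(5, 10, 1, weights = rep(0, 9)),
               "non-negative")
})

test_that("noise-free reads reproduce the template up to strand", {
  refs <- small_refs()[1:6]
  sim <- simulate_reads(refs, error_model(0, 0, 0), depth = 2, seed = 5L)
  expect_identical(nrow(sim$reads), 12L)
  for (i in seq_len(nrow(sim$reads))) {
    tmpl <- refs[[sim$truth$source[i]]]
    got <- sim$reads$sequence[i]
    if (sim$truth$strand[i] == "-") got <- revcomp(got)
    expect_identical(got, tmpl)
  }
  # both orientations occur
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
})

test_that("read simulation is byte-reproducible from the seed", {
  refs <- small_refs()[1:3]
  s1 <- simulate_reads(refs, error_model(), depth = 2, seed = 7L)
  s2 <- simulate_reads(refs, error_model(), depth = 2, seed = 7L)
  expect_identical(s1, s2)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$sequence, s1$reads$sequence)
  expect_identical(back$id, s1$reads$id)
  unlink(fq)
})

test_that("mean edit distance matches the error budget", {
  tmpl <- full_refs()[[format_config(1:5)]]
  n_reads <- 200L
  sim <- simulate_reads(setNames(rep(tmpl, 1), "t"), error_model(),
                        depth = n_reads, seed = 11L)
  seqs <- ifelse(sim$truth$strand == "-", revcomp(sim$reads$sequence),
                 sim$reads$sequence)
  d <- vapply(seqs, function(s) shufflonr:::myers_distance(tmpl, s),
              integer(1), USE.NAMES = FALSE)
  expected <- nchar(tmpl) * (0.02 + 0.02 + 0.02)  # 260.7 on 4345 bp
  se <- stats::sd(d) / sqrt(n_reads)
  # the op count L*(sub+ins+del) bounds the edit distance from above;
  # optimal alignments re-explain a small fraction (~2%) of ops more
  # cheaply, so allow a 5% shortfall but no excess beyond Monte-Carlo
  expect_lt(mean(d), expected + 4 * se)
  expect_gt(mean(d), 0.95 * expected - 4 * se)
})

test_that("error model rejects out-of-range rates", {
  expect_error(error_model(sub_rate = 0.5), "0.2")
  expect_error(error_model(ins_rate = -0.01), "0.2")
})

test_that("estimated shuffling rate is monotone in the event rate", {
  lambdas <- c(0, 0.5, 1, 2, 4)
  rates <- vapply(seq_along(lambdas), function(i) {
    lib <- simulate_library(5, 400, event_rate = lambdas[i],
                            seed = 300L + i)
    shuffling_rate(library_summary(names(lib)))
  }, numeric(1))
  expect_identical(rates[1], 0)
  # non-decreasing up to Monte-Carlo slack
  expect_true(all(diff(rates) > -0.05))
})

test_that("planted repeats are written exactly where requested", {
  kmer <- "ACGTTGCAAGGTC"
  bg <- plant_repeats(2000, kmer, positions = c(100, 700),
                      strands = c("+", "+"), seed = 21L)
  expect_identical(nchar(bg), 2000L)
  expect_identical(substr(bg, 101, 113), kmer)
  expect_identical(substr(bg, 701, 713), kmer)
  # exactly the planted occurrences, none elsewhere on either strand
  expect_identical(shufflonr:::gregexpr_all(bg, kmer), c(101L, 701L))
  expect_length(shufflonr:::gregexpr_all(bg, revcomp(kmer)), 0)
  inv <- plant_repeats(1500, kmer, positions = c(50, 900),
                       strands = c("+", "-"), seed = 22L)
  expect_identical(substr(inv, 901, 913), revcomp(kmer))
  expect_error(plant_repeats(100, kmer, positions = c(0, 5),
                             strands = c("+", "+")), "overlap")
  expect_error(plant_repeats(100, kmer, positions = 95), "out of bounds")
})

test_that("truth-tracking: error-free reads decode to their generator", {
  lib <- simulate_library(3, 30, event_rate = 2, seed = 77L)
  refs <- small_refs()
  sim <- simulate_reads(refs[names(lib)], error_model(0, 0, 0),
                        depth = 1, seed = 78L)
  idx <- small_index()
  for (i in seq_len(nrow(sim$reads))) {
    r <- classify_read(sim$reads$sequence[i], idx)
    expect_identical(r$status, "classified")
    expect_identical(r$config_string, sim$truth$source[i])
  }
})
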