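uniform384 <- function() {
  library_summary(setNames(rep(1, 384), names(enumerate_configurations(5))))
}

test_that("shuffling rate is the non-reference fraction of classified reads", {
  ref <- format_config(1:5)
  expect_identical(shuffling_rate(library_summary(setNames(50, ref))), 0)
  expect_identical(shuffling_rate(library_summary(setNames(70, "-1+2+3+4+5"))), 1)
  s <- library_summary(setNames(c(30, 70), c(ref, "+1-2+3+4+5")))
  expect_equal(shuffling_rate(s), 0.70)
  # unclassified reads never enter the denominator
  s2 <- library_summary(setNames(c(30, 70), c(ref, "+1-2+3+4+5")),
                        n_unclassified = 900)
  expect_equal(shuffling_rate(s2), 0.70)
  expect_error(library_summary(character(0)), "empty")
  expect_error(library_summary(setNames(10, "+2+1+3+4+5")), "parity")
})

test_that("occupancy puts a pure reference library on the diagonal", {
  M <- occupancy(library_summary(setNames(10, format_config(1:5))))
  for (p in 1:5) expect_identical(M[paste0("pos", p), paste0("+", p)], 1)
  expect_identical(sum(M), 5)
})

test_that("occupancy of the uniform library matches enumeration averages", {
  M <- occupancy(uniform384())
  expect_equal(unname(rowSums(M)), rep(1, 5))
  # odd positions: 3 odd modules x 2 strands, each 1/6
  for (p in c(1, 3, 5)) for (m in c(1, 3, 5)) for (s in c("+", "-")) {
    expect_equal(M[paste0("pos", p), paste0(s, m)], 1 / 6)
  }
  # even positions: 2 even modules x 2 strands, each 1/4
  for (p in c(2, 4)) for (m in c(2, 4)) for (s in c("+", "-")) {
    expect_equal(M[paste0("pos", p), paste0(s, m)], 1 / 4)
  }
  # parity-forbidden cells are structural zeros
  expect_identical(M["pos1", "+2"], 0)
  expect_identical(M["pos2", "-5"], 0)
})

test_that("diversity sampling matches the closed-form expectation", {
  # single-configuration library: always exactly one unique
  one <- library_summary(setNames(5, format_config(1:5)))
  d1 <- diversity(one, sample_size = 100, n_draws = 20, seed = 1)
  expect_identical(unique(d1$unique_counts), 1)
  # uniform library at a desk-scale sample size
  u <- uniform384()
  n <- 500
  d <- diversity(u, sample_size = n, n_draws = 200, seed = 2)
  closed <- 384 * (1 - (1 - 1 / 384)^n)
  se <- stats::sd(d$unique_counts) / sqrt(200)
  expect_lt(abs(d$mean_unique - closed), 4 * se)
  # rarefaction curve is monotone and ends at the full sample size
  expect_true(all(diff(d$rarefaction$mean_unique) >= 0))
  expect_identical(max(d$rarefaction$size), n)
})

test_that("inversion-count distribution is the BFS-depth histogram", {
  ref <- format_config(1:5)
  only_ref <- inversion_count_distribution(library_summary(setNames(9, ref)))
  expect_identical(only_ref, c("0" = 1))
  one_event <- library_summary(setNames(c(4, 6),
                                        c("-1+2+3+4+5", "-3-2-1+4+5")))
  expect_identical(inversion_count_distribution(one_event), c("1" = 1))
  # invariant: mass at depth 0 == 1 - shuffling rate, exactly
  lib <- simulate_library(5, 300, event_rate = 2, seed = 31L)
  s <- library_summary(names(lib))
  dist <- inversion_count_distribution(s)
  mass0 <- if ("0" %in% names(dist)) dist[["0"]] else 0
  expect_equal(mass0, 1 - shuffling_rate(s), tolerance = 1e-12)
})

test_that("inversion frequency uses only reference-order reads", {
  lens <- c(143, 237, 332, 426, 521)
  ref <- format_config(1:5)
  pure <- inversion_frequency(list(A = library_summary(setNames(50, ref))),
                              lens)
  expect_identical(pure$frequency, rep(0, 5))
  mix <- library_summary(setNames(c(90, 10, 25),
                                  c(ref, "-1+2+3+4+5", "+3+2+1+4+5")))
  tab <- inversion_frequency(list(A = mix), lens)
  # the shuffled-order configuration (25 reads) must not contribute
  expect_identical(unique(tab$n_reference_order), 100)
  expect_equal(tab$frequency[tab$module == 1], 0.10)
  expect_equal(tab$frequency[tab$module == 2], 0)
  # no reference-order reads: flagged undefined, not dropped
  odd <- library_summary(setNames(5, "+3+2+1+4+5"))
  tab2 <- inversion_frequency(list(B = odd), lens)
  expect_true(all(tab2$undefined))
  expect_true(all(is.na(tab2$frequency)))
})

test_that("regression recovers an exact linear length effect", {
  lens <- c(143, 237, 332, 426, 521)
  tab <- data.frame(si = "A", module = 1:5, length = lens,
                    n_reference_order = 100, n_inverted = 0,
                    frequency = 0.5 - 5e-4 * lens, undefined = FALSE)
  fit <- suppressWarnings(regress_inversion(tab))  # perfect-fit warning
  expect_equal(unname(coef(fit$fit)["length"]), -5e-4, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit$fit))), 1e-12)
})

test_that("regression needs variation and flags rank deficiency", {
  tab <- data.frame(si = "A", module = 1:3, length = c(100, 100, 100),
                    frequency = c(0.1, 0.2, 0.3), undefined = FALSE)
  expect_error(regress_inversion(tab), "distinct module lengths")
})

test_that("permuted frequencies give calibrated type-I error", {
  set.seed(88)
  lens <- rep(c(143, 237, 332, 426, 521), 3)
  si <- rep(c("A", "B", "C"), each = 5)
  base <- runif(15, 0.2, 0.4)
  pvals <- replicate(300, {
    tab <- data.frame(si = si, module = rep(1:5, 3), length = lens,
                      frequency = sample(base), undefined = FALSE)
    fit <- regress_inversion(tab)
    fit$coefficients["length", "Pr(>|t|)"]
  })
  # roughly uniform: rejection rate near the nominal 5%
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("pooling replicates adds counts explicitly", {
  ref <- format_config(1:5)
  a <- library_summary(setNames(c(10, 5), c(ref, "-1+2+3+4+5")),
                       n_unclassified = 2)
  b <- library_summary(setNames(c(20, 5), c(ref, "+1-2+3+4+5")),
                       n_unclassified = 3)
  p <- pool_summaries(list(a, b))
  expect_identical(p$n_classified, 40)
  expect_identical(p$n_unclassified, 5)
  expect_identical(unname(p$counts[ref]), 30)
  # per-replicate averaging is just the mapped statistic
  expect_equal(mean(c(shuffling_rate(a), shuffling_rate(b))),
               mean(c(5 / 15, 5 / 25)))
})

test_that("summary JSON round trip preserves counts", {
  ref <- format_config(1:5)
  s <- library_summary(setNames(c(3, 7), c(ref, "+1-2+3+4+5")),
                       n_unclassified = 4)
  f <- tempfile(fileext = ".json")
  write_summary_json(s, f)
  s2 <- read_summary_json(f)
  expect_equal(s2$counts[names(s$counts)], s$counts)
  expect_identical(s2$n_unclassified, 4)
  unlink(f)
})
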