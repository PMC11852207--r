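#' Library summary: read counts per configuration
#'
#' The common input to all statistics: how many classified reads support
#' each configuration, plus the number of unclassified reads.
#'
#' @param x either a character vector of configuration strings (one per
#'   classified read / library member), or a named numeric vector of
#'   counts.
#' @param n_unclassified reads that failed classification.
#' @param n_modules module count; inferred from the first key if omitted.
#' @return object of class `library_summary` with fields `counts`,
#'   `n_classified`, `n_unclassified`, `n_modules`.
#' @export
library_summary <- function(x, n_unclassified = 0L, n_modules = NULL) {
  counts <- if (is.character(x)) {
    tab <- table(x)
    setNames(as.numeric(tab), names(tab))
  } else {
    stopifnot(!is.null(names(x)), all(x >= 0))
    x[x > 0]
  }
  if (length(counts) == 0L) stop("empty library summary", call. = FALSE)
  if (is.null(n_modules)) n_modules <- length(parse_config(names(counts)[1]))
  for (key in names(counts)) validate_config(parse_config(key), n_modules)
  structure(list(counts = counts,
                 n_classified = sum(counts),
                 n_unclassified = as.numeric(n_unclassified),
                 n_modules = as.integer(n_modules)),
            class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("library_summary: %d configurations, %g classified, %g unclassified reads\n",
              length(x$counts), x$n_classified, x$n_unclassified))
  invisible(x)
}

#' Pool several library summaries
#'
#' Adds counts across replicates. Pooling is always explicit: per-replicate
#' statistics are obtained by mapping the statistic over the list instead.
#'
#' @param summaries list of `library_summary` objects of equal n_modules.
#' @return a pooled `library_summary`.
#' @export
pool_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  n <- unique(vapply(summaries, function(s) s$n_modules, integer(1)))
  stopifnot(length(n) == 1)
  keys <- unique(unlist(lapply(summaries, function(s) names(s$counts))))
  counts <- setNames(numeric(length(keys)), keys)
  for (s in summaries) counts[names(s$counts)] <- counts[names(s$counts)] +
      s$counts
  library_summary(counts,
                  n_unclassified = sum(vapply(summaries,
                                              function(s) s$n_unclassified,
                                              numeric(1))),
                  n_modules = n)
}

reference_key <- function(n) format_config(seq_len(n))

#' Shuffling rate
#'
#' Fraction of classified library members not in the reference (starting)
#' configuration. Unclassified reads are excluded from the denominator.
#'
#' @param summary a [library_summary()].
#' @return a fraction in \[0, 1\].
#' @export
shuffling_rate <- function(summary) {
  stopifnot(inherits(summary, "library_summary"), summary$n_classified > 0)
  ref <- reference_key(summary$n_modules)
  n_ref <- if (ref %in% names(summary$counts)) summary$counts[[ref]] else 0
  1 - n_ref / summary$n_classified
}

#' Module occupancy matrix
#'
#' Per-position distribution over signed modules: entry (p, "+m"/"-m") is
#' the proportion of classified reads placing module m at position p on
#' that strand. Rows (positions) sum to 1; parity-forbidden entries are
#' structurally zero.
#'
#' @param summary a [library_summary()].
#' @return matrix, rows `pos1..posn`, columns `+1,-1,...,+n,-n`.
#' @export
occupancy <- function(summary) {
  stopifnot(inherits(summary, "library_summary"), summary$n_classified > 0)
  n <- summary$n_modules
  cols <- as.vector(rbind(paste0("+", 1:n), paste0("-", 1:n)))
  M <- matrix(0, n, 2L * n, dimnames = list(paste0("pos", 1:n), cols))
  for (key in names(summary$counts)) {
    cf <- parse_config(key)
    w <- summary$counts[[key]]
    for (p in 1:n) {
      lab <- paste0(if (cf[p] > 0) "+" else "-", abs(cf[p]))
      M[p, lab] <- M[p, lab] + w
    }
  }
  M / summary$n_classified
}

#' Library diversity under subsampling
#'
#' Repeatedly draws `sample_size` members with replacement, with
#' probability proportional to counts, and reports the number of unique
#' configurations seen per draw plus a rarefaction curve (mean uniques as
#' a function of subsample size).
#'
#' @param summary a [library_summary()].
#' @param sample_size members per draw (default 4000, the assay's
#'   diversity analysis size).
#' @param n_draws Monte-Carlo repetitions.
#' @param rarefaction_sizes subsample sizes for the curve; default a
#'   log-spaced grid up to `sample_size`.
#' @param seed integer seed.
#' @return list: `unique_counts` (length `n_draws`), `mean_unique`,
#'   `rarefaction` (data.frame size / mean_unique).
#' @export
diversity <- function(summary, sample_size = 4000L, n_draws = 100L,
                      rarefaction_sizes = NULL, seed = 1L) {
  stopifnot(inherits(summary, "library_summary"), sample_size >= 1)
  keys <- names(summary$counts)
  prob <- summary$counts / sum(summary$counts)
  if (is.null(rarefaction_sizes)) {
    rarefaction_sizes <- unique(round(exp(seq(log(1), log(sample_size),
                                              length.out = 12L))))
  }
  local_seed(seed, {
    draws <- replicate(n_draws,
                       sample.int(length(keys), sample_size, replace = TRUE,
                                  prob = prob),
                       simplify = FALSE)
    uniq <- vapply(draws, function(d) length(unique(d)), numeric(1))
    curve <- vapply(rarefaction_sizes, function(sz) {
      mean(vapply(draws, function(d) length(unique(d[seq_len(sz)])),
                  numeric(1)))
    }, numeric(1))
    list(unique_counts = uniq, mean_unique = mean(uniq),
         rarefaction = data.frame(size = rarefaction_sizes,
                                  mean_unique = curve))
  })
}

#' Distribution of minimal inversion-event counts
#'
#' Assigns each configuration its BFS depth (minimal number of inversion
#' events from the reference, via [reachable_set()]) and histograms read
#' counts by depth. Mass at depth 0 equals 1 minus the shuffling rate.
#'
#' @param summary a [library_summary()].
#' @param depths optional precomputed depth vector from [reachable_set()].
#' @return named numeric vector: proportion of classified reads per depth.
#' @export
inversion_count_distribution <- function(summary, depths = NULL) {
  stopifnot(inherits(summary, "library_summary"))
  if (is.null(depths)) depths <- reachable_set(summary$n_modules)
  d <- depths[names(summary$counts)]
  if (anyNA(d)) stop("summary contains configurations outside the reachable set",
                     call. = FALSE)
  agg <- tapply(summary$counts, d, sum) / summary$n_classified
  out <- setNames(as.numeric(agg), names(agg))
  out[order(as.integer(names(out)))]
}

#' Per-module inversion frequency table
#'
#' Restricted to reads whose unsigned module ORDER is the reference order
#' (1, 2, ..., n): for each module, the frequency of the inverted ('-')
#' orientation among those reads. One row per (SI, module).
#'
#' @param summaries named list of [library_summary()] objects, one per
#'   invertase (SI); names are the SI labels.
#' @param module_lengths module lengths in bp (reference order), e.g.
#'   `nchar(design$modules)`.
#' @return data.frame: si, module, length, n_reference_order, n_inverted,
#'   frequency (NA, flagged by `undefined`, when no reference-order reads
#'   exist).
#' @export
inversion_frequency <- function(summaries, module_lengths) {
  stopifnot(length(summaries) >= 1, !is.null(names(summaries)))
  n <- length(module_lengths)
  rows <- list()
  for (si in names(summaries)) {
    s <- summaries[[si]]
    stopifnot(s$n_modules == n)
    n_ref_order <- 0
    n_inv <- numeric(n)
    for (key in names(s$counts)) {
      cf <- parse_config(key)
      if (!identical(abs(cf), 1:n)) next  # only reference module order
      w <- s$counts[[key]]
      n_ref_order <- n_ref_order + w
      n_inv <- n_inv + w * (cf < 0)
    }
    freq <- if (n_ref_order > 0) n_inv / n_ref_order else rep(NA_real_, n)
    rows[[si]] <- data.frame(si = si, module = 1:n,
                             length = as.numeric(module_lengths),
                             n_reference_order = n_ref_order,
                             n_inverted = n_inv, frequency = freq,
                             undefined = n_ref_order == 0,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress module inversion frequency on module length and SI
#'
#' Ordinary least squares of frequency on module length (continuous) and
#' SI (categorical, treatment-coded against the first level, or the level
#' named by `reference_level`). With a single SI the categorical term is
#' dropped. Errors on rank-deficient designs, naming the collinear term.
#'
#' @param table output of [inversion_frequency()].
#' @param reference_level SI level to treat as baseline.
#' @return list: `fit` (the lm object), `coefficients` (coefficient
#'   table), `f_statistic`, `f_p_value`.
#' @export
regress_inversion <- function(table, reference_level = NULL) {
  tab <- table[!is.na(table$frequency), , drop = FALSE]
  if (length(unique(tab$length)) < 2L) {
    stop("need at least 2 distinct module lengths", call. = FALSE)
  }
  multi_si <- length(unique(tab$si)) >= 2L
  if (multi_si) {
    lev <- unique(tab$si)
    if (!is.null(reference_level)) {
      lev <- c(reference_level, setdiff(lev, reference_level))
    }
    tab$si <- factor(tab$si, levels = lev)
    fit <- lm(frequency ~ length + si, data = tab)
  } else {
    fit <- lm(frequency ~ length, data = tab)
  }
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(fit = fit,
       coefficients = as.data.frame(sm$coefficients),
       f_statistic = unname(fstat[1]),
       f_p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                             lower.tail = FALSE)))
}

#' Write / read a library summary as JSON
#'
#' @param summary a [library_summary()].
#' @param path JSON path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(list(counts = as.list(summary$counts),
                            n_classified = summary$n_classified,
                            n_unclassified = summary$n_unclassified,
                            n_modules = summary$n_modules),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  library_summary(unlist(x$counts), n_unclassified = x$n_unclassified,
                  n_modules = x$n_modules)
}
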