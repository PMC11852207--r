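#' Parity-constrained signed permutations of shufflon modules
#'
#' A configuration of an n-module shufflon is a signed permutation of the
#' module ids 1..n: the entry at position p gives which module sits there
#' and on which strand. Because the flanking recombination sites alternate
#' in orientation, inversion events move modules only between positions of
#' the same parity, so valid configurations place odd ids at odd positions
#' and even ids at even positions.
#'
#' Configurations are represented as integer vectors of signed ids, e.g.
#' `c(-3, -2, -1, 4, 5)`, with the reference configuration `1:n`. The
#' canonical string form concatenates signed ids, e.g. `"+1-4+3-2+5"`.
#'
#' @name configuration
NULL

DEFAULT_ENUM_CAP <- 7L

#' Format / parse configuration strings
#'
#' @param config integer vector of signed module ids.
#' @return `format_config()`: a single string such as `"+1-4+3-2+5"`;
#'   `parse_config()`: the integer vector.
#' @export
#' @examples
#' format_config(c(-3, -2, -1, 4, 5))
#' parse_config("+1-4+3-2+5")
format_config <- function(config) {
  stopifnot(is.numeric(config), length(config) >= 1)
  paste0(ifelse(config > 0, "+", "-"), abs(as.integer(config)), collapse = "")
}

#' @rdname format_config
#' @param string configuration string (signed ids, no separators).
#' @export
parse_config <- function(string) {
  stopifnot(is.character(string), length(string) == 1L)
  m <- gregexpr("[+-][0-9]+", string)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(string)) {
    stop("malformed configuration string: ", string, call. = FALSE)
  }
  as.integer(regmatches(string, gregexpr("[+-][0-9]+", string))[[1]])
}

#' Validate a configuration
#'
#' Checks the signed-permutation invariants: the unsigned ids are exactly
#' `1..n` and every module sits at a position of its own parity.
#'
#' @param config integer vector of signed module ids.
#' @param n expected module count (defaults to `length(config)`).
#' @return invisibly `config`; errors with a diagnostic on violation.
#' @export
validate_config <- function(config, n = length(config)) {
  config <- as.integer(config)
  if (length(config) != n) {
    stop(sprintf("configuration has %d entries, expected %d",
                 length(config), n), call. = FALSE)
  }
  ids <- abs(config)
  if (!identical(sort(ids), seq_len(n))) {
    stop("configuration ids are not a permutation of 1..", n, ": ",
         format_config(config), call. = FALSE)
  }
  pos <- seq_len(n)
  bad <- which(pos %% 2L != ids %% 2L)
  if (length(bad)) {
    stop(sprintf("parity violation at position %d (module %d): %s",
                 bad[1], ids[bad[1]], format_config(config)), call. = FALSE)
  }
  invisible(config)
}

is_valid_config <- function(config, n = length(config)) {
  !inherits(try(validate_config(config, n), silent = TRUE), "try-error")
}

#' Count parity-constrained configurations
#'
#' Closed form \eqn{\lceil n/2\rceil!\,\lfloor n/2\rfloor!\,2^n}: odd
#' modules permute among odd positions, even modules among even positions,
#' and every module is independently invertible.
#'
#' @param n module count (>= 1).
#' @return the count as a double (exact for all practically relevant n).
#' @export
#' @examples
#' count_configurations(5)   # 384
#' count_configurations(11)  # 176947200
count_configurations <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  factorial(ceiling(n / 2)) * factorial(floor(n / 2)) * 2^n
}

#' Enumerate all parity-constrained configurations
#'
#' Generates every valid signed permutation in deterministic lexicographic
#' order on the signed tuple. Enumeration is capped (default 7 modules,
#' 5040 x 2^7 states); beyond the cap use [count_configurations()].
#'
#' @param n module count.
#' @param cap maximum n for enumeration.
#' @return list of integer configurations, named by their canonical string.
#' @export
#' @examples
#' length(enumerate_configurations(5))  # 384
enumerate_configurations <- function(n, cap = DEFAULT_ENUM_CAP) {
  if (!is.numeric(n) || n < 1 || n != floor(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (n > cap) {
    stop(sprintf(paste0("n = %d exceeds the enumeration cap (%d); use ",
                        "count_configurations() for analytic counting"),
                 n, cap), call. = FALSE)
  }
  n <- as.integer(n)
  odd_ids <- seq(1L, n, by = 2L)
  even_ids <- if (n >= 2L) seq(2L, n, by = 2L) else integer(0)

  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  odd_perms <- perms(odd_ids)
  even_perms <- perms(even_ids)
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))

  configs <- list()
  for (po in odd_perms) {
    for (pe in even_perms) {
      base <- integer(n)
      base[odd_ids] <- po        # odd positions get odd ids
      if (length(even_ids)) base[even_ids] <- pe
      for (r in seq_len(nrow(signs))) {
        configs[[length(configs) + 1L]] <- base * signs[r, ]
      }
    }
  }
  keys <- vapply(configs, format_config, character(1))
  ord <- order(vapply(configs, function(cf) paste(sprintf("%+03d", cf),
                                                  collapse = ""), character(1)))
  configs <- configs[ord]
  names(configs) <- keys[ord]
  configs
}

#' Inversion events between recombination sites
#'
#' Junctions are indexed 0..n left to right; module p sits between
#' junctions p-1 and p. Sites alternate in orientation, so only junction
#' pairs an odd distance apart carry oppositely oriented sites and can
#' recombine by inversion.
#'
#' @param n module count.
#' @return data.frame with columns `i`, `j` (0-based junction indices,
#'   j > i, j - i odd), one row per valid inversion event.
#' @export
#' @examples
#' nrow(inversion_events(5))  # 9
inversion_events <- function(n) {
  stopifnot(n >= 1)
  pairs <- expand.grid(i = 0:n, j = 0:n)
  pairs <- pairs[pairs$j > pairs$i & (pairs$j - pairs$i) %% 2L == 1L, ,
                 drop = FALSE]
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  pairs
}

#' Apply one inversion event to a configuration
#'
#' The block of modules strictly between junctions `i` and `j` is reversed
#' in order and every orientation bit in it is flipped. Odd-span events are
#' the only valid ones (same-orientation sites cannot recombine by
#' inversion); odd-length block reversal preserves position parity, so the
#' result is always a valid configuration. The operation is an involution.
#'
#' @param config integer configuration.
#' @param i,j 0-based junction indices with `j > i` and `j - i` odd.
#' @return the recombined configuration.
#' @export
#' @examples
#' apply_inversion(1:5, 0, 3)  # c(-3, -2, -1, 4, 5)
apply_inversion <- function(config, i, j) {
  n <- length(config)
  if (i < 0 || j > n || j <= i) {
    stop(sprintf("junction indices must satisfy 0 <= i < j <= %d", n),
         call. = FALSE)
  }
  if ((j - i) %% 2L == 0L) {
    stop(sprintf(paste0("event (%d,%d) has even span: the two sites have ",
                        "the same orientation and cannot recombine by ",
                        "inversion"), i, j), call. = FALSE)
  }
  block <- (i + 1L):j
  config[block] <- -rev(config[block])
  config
}

#' Reachable configurations under the inversion-event model
#'
#' Breadth-first closure of the reference configuration `1:n` under all
#' valid inversion events, with the minimal event count (BFS depth) per
#' configuration. For every n the closure equals the full parity-
#' constrained set, which validates the closed-form count against the
#' mechanistic event model.
#'
#' @param n module count (capped as in [enumerate_configurations()]).
#' @param cap enumeration cap.
#' @return named integer vector: BFS depth per configuration string,
#'   with attribute `configs` holding the configuration list.
#' @export
#' @examples
#' depths <- reachable_set(3)
#' depths[format_config(1:3)]  # reference at depth 0
reachable_set <- function(n, cap = DEFAULT_ENUM_CAP) {
  if (n > cap) {
    stop(sprintf("n = %d exceeds the cap (%d)", n, cap), call. = FALSE)
  }
  events <- inversion_events(n)
  ref <- seq_len(as.integer(n))
  depth <- new.env(parent = emptyenv())
  configs <- new.env(parent = emptyenv())
  key0 <- format_config(ref)
  assign(key0, 0L, envir = depth)
  assign(key0, ref, envir = configs)
  frontier <- list(ref)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (cf in frontier) {
      for (r in seq_len(nrow(events))) {
        cf2 <- apply_inversion(cf, events$i[r], events$j[r])
        key <- format_config(cf2)
        if (!exists(key, envir = depth, inherits = FALSE)) {
          assign(key, d, envir = depth)
          assign(key, cf2, envir = configs)
          nxt[[length(nxt) + 1L]] <- cf2
        }
      }
    }
    frontier <- nxt
  }
  keys <- ls(depth)
  out <- vapply(keys, function(k) get(k, envir = depth), integer(1))
  out <- sort(out)
  ord <- names(out)
  structure(out, configs = setNames(lapply(ord, function(k)
    get(k, envir = configs)), ord))
}
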