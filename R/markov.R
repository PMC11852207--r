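#' Transition matrix of the inversion-event random walk
#'
#' One step of the chain applies a single inversion event drawn by weight.
#' States are the enumerated configurations (canonical order); entry
#' (s, t) is the probability that one event maps s to t. With uniform
#' weights each event is an involution, so the matrix is symmetric and
#' doubly stochastic and the stationary distribution is uniform over all
#' configurations.
#'
#' @param n module count.
#' @param weights optional event weights (see [simulate_library()]).
#' @param cap enumeration cap.
#' @return square matrix with dimnames the configuration strings.
#' @export
transition_matrix <- function(n, weights = NULL, cap = DEFAULT_ENUM_CAP) {
  configs <- enumerate_configurations(n, cap = cap)
  keys <- names(configs)
  events <- inversion_events(n)
  ne <- nrow(events)
  if (is.null(weights)) weights <- rep(1, ne)
  stopifnot(length(weights) == ne, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  P <- matrix(0, length(configs), length(configs),
              dimnames = list(keys, keys))
  for (s in seq_along(configs)) {
    for (e in seq_len(ne)) {
      t_key <- format_config(apply_inversion(configs[[s]], events$i[e],
                                             events$j[e]))
      P[s, t_key] <- P[s, t_key] + w[e]
    }
  }
  P
}

#' Expected shuffling rate under the Poisson event model
#'
#' A library member receives k ~ Poisson(lambda) events; the probability
#' of ending at the reference is \eqn{\sum_k P(k)\,(P^k)_{ref,ref}}. The
#' expected shuffling rate is one minus that return probability, computed
#' by iterating the reference row of the chain (truncating the Poisson sum
#' at negligible tail mass).
#'
#' @param lambda mean events per member.
#' @param P transition matrix from [transition_matrix()].
#' @param tol tail mass at which to truncate the Poisson sum.
#' @return expected shuffling rate in \[0, 1\].
#' @export
expected_shuffling_rate <- function(lambda, P, tol = 1e-12) {
  stopifnot(lambda >= 0)
  ref <- format_config(seq_len(nchar_config(colnames(P)[1])))
  v <- setNames(numeric(ncol(P)), colnames(P))
  v[ref] <- 1
  p_ref <- dpois(0, lambda) * v[ref]
  k <- 0L
  kmax <- max(20, ceiling(lambda + 12 * sqrt(lambda + 1)))
  while (k < kmax) {
    k <- k + 1L
    v <- as.numeric(v %*% P)
    names(v) <- colnames(P)
    p_ref <- p_ref + dpois(k, lambda) * v[ref]
    if (ppois(k, lambda, lower.tail = FALSE) < tol) break
  }
  unname(1 - p_ref)
}

# module count encoded in a configuration string
nchar_config <- function(key) length(parse_config(key))

#' Stationary distribution by power iteration
#'
#' @param P transition matrix.
#' @param max_iter,tol iteration controls.
#' @return named probability vector.
#' @export
stationary_distribution <- function(P, max_iter = 10000L, tol = 1e-12) {
  v <- rep(1 / ncol(P), ncol(P))
  for (i in seq_len(max_iter)) {
    v2 <- as.numeric(v %*% P)
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      break
    }
    v <- v2
  }
  setNames(v, colnames(P))
}
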