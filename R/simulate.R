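#' Sequencing error model
#'
#' Independent per-base substitution, insertion and deletion
#' probabilities. Defaults (2% each) are of the magnitude of R9.4-era
#' nanopore reads.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in
#'   \[0, 0.2\].
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.02, del_rate = 0.02) {
  r <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.2)) {
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

#' Simulate a shuffled plasmid library
#'
#' Each library member starts at the reference configuration, draws
#' `k ~ Poisson(event_rate)` inversion events (or exactly `fixed_events`
#' when given) and applies them sequentially, sampling events by weight.
#' This emulates the outcome of incubating the reporter with an active
#' shufflon invertase: memoryless recombination between oppositely
#' oriented sites.
#'
#' @param n_modules module count of the design.
#' @param n_members number of library members to draw.
#' @param event_rate mean inversion events per member (Poisson).
#' @param weights optional non-negative weight per row of
#'   [inversion_events()] (default uniform). The preset
#'   `event_weights(n, "positional_bias")` down-weights events touching
#'   the terminal junctions, mimicking the observation that terminal
#'   modules shuffle less often than central ones.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param fixed_events if non-NULL, apply exactly this many events per
#'   member instead of a Poisson draw.
#' @return list of integer configurations, named by configuration string.
#' @export
simulate_library <- function(n_modules, n_members, event_rate,
                             weights = NULL, seed = 1L,
                             fixed_events = NULL) {
  stopifnot(n_members >= 1, event_rate >= 0)
  events <- inversion_events(n_modules)
  ne <- nrow(events)
  if (is.null(weights)) weights <- rep(1, ne)
  if (length(weights) != ne || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be ", ne, " non-negative values, not all zero",
         call. = FALSE)
  }
  ref <- seq_len(as.integer(n_modules))
  local_seed(seed, {
    ks <- if (is.null(fixed_events)) rpois(n_members, event_rate)
          else rep.int(as.integer(fixed_events), n_members)
    members <- vector("list", n_members)
    for (m in seq_len(n_members)) {
      cf <- ref
      if (ks[m] > 0) {
        ev <- sample.int(ne, ks[m], replace = TRUE, prob = weights)
        for (e in ev) cf <- apply_inversion(cf, events$i[e], events$j[e])
      }
      members[[m]] <- cf
    }
    names(members) <- vapply(members, format_config, character(1))
    members
  })
}

#' @rdname simulate_library
#' @param n module count.
#' @param preset `"uniform"` or `"positional_bias"`.
#' @param terminal_weight weight for events involving junction 0 or n
#'   under the positional-bias preset.
#' @export
event_weights <- function(n, preset = c("uniform", "positional_bias"),
                          terminal_weight = 0.4) {
  preset <- match.arg(preset)
  events <- inversion_events(n)
  w <- rep(1, nrow(events))
  if (preset == "positional_bias") {
    w[events$i == 0L | events$j == n] <- terminal_weight
  }
  w
}

# Apply the error model to one sequence; per-base i.i.d. operations.
mutate_sequence <- function(sequence, model) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(b)
  bases <- c("A", "C", "G", "T")
  piece <- b
  subs <- runif(n) < model$sub_rate
  if (any(subs)) {
    # substitute with a uniformly chosen *different* base
    cur <- match(b[subs], bases)
    shift <- sample.int(3L, sum(subs), replace = TRUE)
    piece[subs] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  dels <- runif(n) < model$del_rate
  piece[dels] <- ""
  ins <- runif(n) < model$ins_rate
  if (any(ins)) {
    piece[ins] <- paste0(piece[ins],
                         sample(bases, sum(ins), replace = TRUE))
  }
  paste(piece, collapse = "")
}

#' Simulate noisy long reads
#'
#' Applies the error model independently per base to each template, then
#' reverse complements each read with probability 0.5 (random sequencing
#' orientation). Read ids encode the template name so downstream accuracy
#' can be scored against truth.
#'
#' @param sequences named character vector of template sequences (names
#'   are typically configuration strings).
#' @param model an [error_model()].
#' @param depth reads per template.
#' @param seed integer seed.
#' @return list with `reads` (data.frame: id, sequence) and `truth`
#'   (data.frame: id, source, strand).
#' @export
simulate_reads <- function(sequences, model = error_model(), depth = 1L,
                           seed = 1L) {
  stopifnot(inherits(model, "error_model"), depth >= 1)
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("template", seq_along(sequences))
  local_seed(seed, {
    total <- length(sequences) * depth
    ids <- character(total)
    seqs <- character(total)
    src <- character(total)
    strand <- character(total)
    r <- 0L
    for (t in seq_along(sequences)) {
      for (d in seq_len(depth)) {
        r <- r + 1L
        s <- mutate_sequence(sequences[[t]], model)
        flip <- runif(1) < 0.5
        if (flip) s <- revcomp(s)
        ids[r] <- sprintf("read%05d", r)
        seqs[r] <- s
        src[r] <- nm[t]
        strand[r] <- if (flip) "-" else "+"
      }
    }
    list(reads = data.frame(id = ids, sequence = seqs,
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, source = src, strand = strand,
                            stringsAsFactors = FALSE))
  })
}

#' Write / read simulated reads as FASTQ
#'
#' Placeholder qualities (Phred 40) are attached; the classifiers ignore
#' quality.
#'
#' @param reads data.frame with `id` and `sequence` columns.
#' @param path FASTQ file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  q <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                     function(L) strrep("I", L), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @return `read_fastq()`: a data.frame with `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub(" .*", "", names(x)), sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Plant k-mer repeats in a random background
#'
#' Fixture generator for the repeat miner: draws a random background
#' sequence screened to contain no occurrence of the chosen k-mer or its
#' reverse complement, then writes the k-mer (or its reverse complement,
#' per strand flag) at the stated 0-based positions.
#'
#' @param background_length background length in bp.
#' @param kmer the k-mer to plant.
#' @param positions integer vector of 0-based start positions.
#' @param strands character vector of "+"/"-" per position.
#' @param seed integer seed.
#' @return a single DNA string with exactly the planted occurrences.
#' @export
plant_repeats <- function(background_length, kmer, positions,
                          strands = rep("+", length(positions)),
                          seed = 1L) {
  k <- nchar(kmer)
  check_dna(kmer, "planted k-mer")
  stopifnot(length(positions) == length(strands),
            all(strands %in% c("+", "-")))
  positions <- as.integer(positions)
  if (any(positions < 0L) || any(positions + k > background_length)) {
    stop("planted occurrence out of bounds", call. = FALSE)
  }
  if (length(positions) > 1L) {
    o <- order(positions)
    p <- positions[o]
    if (any(p[-1] < p[-length(p)] + k)) {
      stop("planted occurrences overlap", call. = FALSE)
    }
  }
  rc <- revcomp(kmer)
  local_seed(seed, {
    for (attempt in 1:500) {
      bg <- random_dna(background_length)
      for (idx in seq_along(positions)) {
        ins <- if (strands[idx] == "+") kmer else rc
        substr(bg, positions[idx] + 1L, positions[idx] + k) <- ins
      }
      occ_f <- length(gregexpr_all(bg, kmer))
      occ_r <- length(gregexpr_all(bg, rc))
      want_f <- sum(strands == "+") + (kmer == rc) * sum(strands == "-")
      want_r <- sum(strands == "-") + (kmer == rc) * sum(strands == "+")
      if (occ_f == want_f && occ_r == want_r) return(bg)
    }
    stop("could not generate a clean background; placement impossible?",
         call. = FALSE)
  })
}

# All (possibly overlapping) match start positions, 1-based; empty integer
# when absent.
gregexpr_all <- function(x, pattern) {
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(x, from, nchar(x)), fixed = TRUE)
    if (p == -1L) break
    hits <- c(hits, from + p - 1L)
    from <- from + p
  }
  hits
}
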