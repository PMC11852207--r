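#' Find direct and inverted k-mer repeats
#'
#' Exhaustive sliding-window k-mer screen of one flanking-DNA record with
#' reverse-complement canonicalisation (a k-mer and its reverse complement
#' are the same repeat seen from opposite strands; for odd k the two are
#' never equal). A repeat is reported iff it occurs at least twice on one
#' strand (a direct repeat) or at least once on each strand (an inverted
#' repeat) — the screen used to flag candidate recombination-site loci
#' near putative invertase genes. The default k of 13 is the length of
#' the longest conserved stretch of the canonical 31-nt sfx site.
#' Overlapping occurrences are counted; windows containing N are skipped.
#'
#' @param sequence one DNA string (alphabet ACGTN).
#' @param k word length (default 13).
#' @return data.frame, one row per reported repeat: `canonical_kmer`
#'   (lexicographic min of k-mer and reverse complement), `n_occ`,
#'   `n_direct` (occurrence count on the more frequent strand),
#'   `n_inverted_pairs` (opposite-strand pair count), plus list-columns
#'   `positions` (0-based) and `strands` ("+" where the forward-strand
#'   word equals the canonical k-mer).
#' @export
find_repeats <- function(sequence, k = 13L) {
  check_dna(sequence, "flank sequence", allow_n = TRUE)
  empty <- data.frame(canonical_kmer = character(0), n_occ = integer(0),
                      n_direct = integer(0), n_inverted_pairs = numeric(0))
  empty$positions <- list()
  empty$strands <- list()
  if (nchar(sequence) < k) {
    warning("sequence shorter than k; no repeats reported")
    return(empty)
  }
  km <- seq_kmers(sequence, k)
  pos0 <- seq_along(km) - 1L
  ok <- !grepl("N", km, fixed = TRUE)
  km <- km[ok]
  pos0 <- pos0[ok]
  if (!length(km)) return(empty)
  rc <- revcomp(km)
  canon <- pmin(km, rc)
  strand <- ifelse(km == canon, "+", "-")
  grp <- split(seq_along(km), canon)
  rows <- lapply(names(grp), function(key) {
    idx <- grp[[key]]
    np <- sum(strand[idx] == "+")
    nm <- length(idx) - np
    n_direct <- max(np, nm)
    n_inv <- np * nm
    if (n_direct < 2L && n_inv < 1L) return(NULL)
    o <- order(pos0[idx])
    out <- data.frame(canonical_kmer = key, n_occ = length(idx),
                      n_direct = n_direct, n_inverted_pairs = n_inv,
                      stringsAsFactors = FALSE)
    out$positions <- list(pos0[idx][o])
    out$strands <- list(strand[idx][o])
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$canonical_kmer), , drop = FALSE]
}

#' Categorise a locus by its repeat content
#'
#' @param hits data.frame from [find_repeats()] for one locus.
#' @return `"direct_and_inverted"` if any repeat has an inverted pair,
#'   `"direct_only"` if any has >= 2 same-strand occurrences but none
#'   inverted, else `"no_repeat"`.
#' @export
classify_locus <- function(hits) {
  if (nrow(hits) == 0L) return("no_repeat")
  if (any(hits$n_inverted_pairs >= 1)) return("direct_and_inverted")
  if (any(hits$n_direct >= 2L)) return("direct_only")
  "no_repeat"
}

#' Flag repeats matching known site k-mers
#'
#' Repeats identical to the conserved portion of an already-known site
#' carry no novelty; they are flagged (never deleted) so downstream
#' reports can exclude them. Matching is canonicalised, so the reverse
#' complement of a known k-mer is also non-novel.
#'
#' @param hits data.frame from [find_repeats()].
#' @param known_kmers character vector of known k-mers.
#' @return `hits` with a logical `novel` column.
#' @export
novelty_filter <- function(hits, known_kmers) {
  knownc <- unique(pmin(known_kmers, revcomp(known_kmers)))
  hits$novel <- !(hits$canonical_kmer %in% knownc)
  hits
}

#' Reconstruct candidate 31-nt sites around repeat occurrences
#'
#' For each occurrence of a repeat, extracts the 31-nt window that places
#' the conserved k-mer at a fixed offset within the site (default: flush
#' with the right end of the window, since core + right arm of the
#' canonical site span 19 nt and contain the conserved stretch). Windows
#' from '-'-strand occurrences are reverse complemented so all right arms
#' read in the same register; windows truncated by the sequence ends are
#' dropped. Each candidate is split 12/7/12 into left arm, core and right
#' arm, and scored for palindromy (identity between the left arm and the
#' reverse complement of the right arm) — near-palindromic sites lack the
#' arm asymmetry that restricts the invertase to inversions.
#'
#' @param sequence the flank DNA the hit came from.
#' @param hit one row of [find_repeats()] output.
#' @param offset 0-based position of the k-mer within the 31-nt window,
#'   in \[0, 31 - k\].
#' @return data.frame: window, left_arm, core, right_arm, position
#'   (0-based window start on the forward strand), strand,
#'   palindromy_score.
#' @export
reconstruct_sites <- function(sequence, hit, offset = 18L) {
  k <- nchar(hit$canonical_kmer)
  site_len <- 31L
  if (offset < 0L || offset > site_len - k) {
    stop("offset must lie in [0, ", site_len - k, "]", call. = FALSE)
  }
  L <- nchar(sequence)
  pos <- hit$positions[[1]]
  strands <- hit$strands[[1]]
  rows <- list()
  for (idx in seq_along(pos)) {
    p <- pos[idx]
    if (strands[idx] == "+") {
      a <- p - offset            # 0-based window start
    } else {
      a <- p + k + offset - site_len
    }
    if (a < 0L || a + site_len > L) next  # truncated at sequence end
    w <- substr(sequence, a + 1L, a + site_len)
    if (strands[idx] == "-") w <- revcomp(w)
    left <- substr(w, 1, 12)
    core <- substr(w, 13, 19)
    right <- substr(w, 20, 31)
    pal <- mean(strsplit(left, "")[[1]] ==
                  strsplit(revcomp(right), "")[[1]])
    rows[[length(rows) + 1L]] <-
      data.frame(window = w, left_arm = left, core = core,
                 right_arm = right, position = as.integer(a),
                 strand = strands[idx],
                 palindromy_score = pal, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("all candidate windows truncated at sequence ends")
    return(data.frame(window = character(0), left_arm = character(0),
                      core = character(0), right_arm = character(0),
                      position = integer(0), strand = character(0),
                      palindromy_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pick one representative candidate site
#'
#' Among reconstructed sites sharing a conserved core/right arm,
#' palindromic candidates (score >= threshold) are excluded first; the
#' site with the modal left arm is returned, ties (and singletons among
#' ties) resolved by a seeded random choice so the pick is reproducible.
#'
#' @param sites data.frame from [reconstruct_sites()].
#' @param palindromy_threshold exclusion threshold (default 0.75).
#' @param seed integer seed for tie-breaking.
#' @return a single-row data.frame.
#' @export
pick_representative_site <- function(sites, palindromy_threshold = 0.75,
                                     seed = 1L) {
  stopifnot(nrow(sites) >= 1)
  keep <- sites[sites$palindromy_score < palindromy_threshold, ,
                drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("all candidate sites are palindromic (score >= ",
         palindromy_threshold, "); no asymmetric representative exists",
         call. = FALSE)
  }
  tab <- table(keep$left_arm)
  best <- names(tab)[tab == max(tab)]
  arm <- if (length(best) == 1L) best else
    local_seed(seed, sample(best, 1L))
  cand <- keep[keep$left_arm == arm, , drop = FALSE]
  row <- if (nrow(cand) == 1L) cand else
    local_seed(seed, cand[sample.int(nrow(cand), 1L), , drop = FALSE])
  rownames(row) <- NULL
  row
}

#' Write candidate sites as annotated FASTA
#'
#' One record per candidate 31-nt site; headers carry the arm split and
#' palindromy score, e.g.
#' `site_1 pos=82 strand=+ left=... core=... right=... palindromy=0.08`.
#'
#' @param sites data.frame from [reconstruct_sites()].
#' @param path output FASTA path.
#' @export
write_candidate_sites <- function(sites, path) {
  ids <- sprintf("site_%d pos=%d strand=%s left=%s core=%s right=%s palindromy=%.3f",
                 seq_len(nrow(sites)), sites$position, sites$strand,
                 sites$left_arm, sites$core, sites$right_arm,
                 sites$palindromy_score)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sites$window, ids)), path)
  invisible(path)
}

#' Mine a multi-FASTA of flanking regions
#'
#' Runs [find_repeats()] + [classify_locus()] + [novelty_filter()] over
#' every record and returns per-locus tables plus a category summary.
#'
#' @param fasta path to a multi-FASTA of flanking DNA (one record per
#'   locus).
#' @param k word length.
#' @param known_kmers optional known-site k-mers for the novelty flag.
#' @return list: `loci` (data.frame locus / category / n_hits /
#'   n_novel), `hits` (named list of per-locus hit tables), `summary`
#'   (category counts).
#' @export
mine_flanks <- function(fasta, k = 13L, known_kmers = character(0)) {
  seqs <- as.character(Biostrings::readDNAStringSet(fasta))
  hits <- lapply(seqs, function(s) {
    h <- find_repeats(s, k = k)
    if (length(known_kmers)) h <- novelty_filter(h, known_kmers)
    else h$novel <- rep(TRUE, nrow(h))
    h
  })
  cats <- vapply(hits, classify_locus, character(1))
  loci <- data.frame(locus = names(seqs), category = unname(cats),
                     n_hits = vapply(hits, nrow, integer(1)),
                     n_novel = vapply(hits, function(h) sum(h$novel),
                                      integer(1)),
                     stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  list(loci = loci, hits = hits,
       summary = table(factor(cats, levels = c("no_repeat", "direct_only",
                                               "direct_and_inverted"))))
}
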