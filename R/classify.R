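#' Size-filter reads
#'
#' Reads whose length deviates from the expected amplicon size by more
#' than `tolerance * expected` are set aside before classification,
#' mirroring the size selection of the sequencing pipeline.
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param expected_length expected amplicon length in bp (for a design,
#'   `nchar(build_sequence(design, 1:n))`).
#' @param tolerance fraction in (0, 1); default 0.15.
#' @return list with `pass` and `size_filtered` data.frames.
#' @export
size_filter <- function(reads, expected_length, tolerance = 0.15) {
  stopifnot(tolerance > 0, tolerance < 1)
  L <- nchar(reads$sequence)
  ok <- abs(L - expected_length) <= tolerance * expected_length
  list(pass = reads[ok, , drop = FALSE],
       size_filtered = reads[!ok, , drop = FALSE])
}

#' Build the k-mer marker index for a design
#'
#' For every module and both anchors, collects the k-mers that occur
#' exactly once across all design sequences counting both strands. These
#' "markers" identify a module (and its strand) wherever it has moved;
#' anchor markers fix the global read orientation. The default design is
#' screened at generation time so that ample markers exist.
#'
#' @param design a [shufflon_design()].
#' @param k marker length (default 15: long enough to be unique, short
#'   enough to survive ~6% read error at useful density).
#' @param min_markers minimum unique markers required per module.
#' @return an object of class `marker_index`: lookup table from k-mer to
#'   (element, strand, offset).
#' @export
build_marker_index <- function(design, k = 15L, min_markers = 10L) {
  stopifnot(inherits(design, "shufflon_design"))
  seqs <- c(design$modules,
            anchor_L = design$anchor_left, anchor_R = design$anchor_right)
  per <- lapply(seqs, seq_kmers, k = k)
  all_fwd <- unlist(per, use.names = FALSE)
  counts <- table(c(all_fwd, revcomp(all_fwd)))
  unique_kmers <- names(counts)[counts == 1L]

  elem <- rep(names(seqs), lengths(per))
  offset <- unlist(lapply(per, function(x) seq_along(x) - 1L),
                   use.names = FALSE)
  keep <- all_fwd %in% unique_kmers
  tab <- data.frame(kmer = all_fwd[keep], element = elem[keep],
                    offset = offset[keep], stringsAsFactors = FALSE)

  n_per <- table(factor(tab$element, levels = names(seqs)))
  mods <- paste0("M", seq_len(n_modules(design)))
  short <- mods[n_per[mods] < min_markers]
  if (length(short)) {
    stop("modules with fewer than ", min_markers, " unique ", k,
         "-mers: ", paste(short, collapse = ", "),
         "; use a larger k or redesign the modules", call. = FALSE)
  }
  # dictionary over both strands: a reverse-complement hit means the
  # element appears inverted in the read
  dict <- data.frame(
    kmer = c(tab$kmer, revcomp(tab$kmer)),
    element = rep(tab$element, 2L),
    strand = rep(c("+", "-"), each = nrow(tab)),
    offset = rep(tab$offset, 2L),
    stringsAsFactors = FALSE)
  structure(list(k = as.integer(k), dict = dict,
                 n_modules = n_modules(design),
                 counts = as.integer(n_per[mods])),
            class = "marker_index")
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf("marker_index: k=%d, %d modules, markers per module: %s\n",
              x$k, x$n_modules, paste(x$counts, collapse = ",")))
  invisible(x)
}

# match read k-mers against the marker dictionary; returns hits with read
# positions (1-based start of the k-mer in the read)
marker_hits <- function(sequence, index) {
  km <- seq_kmers(sequence, index$k)
  idx <- match(km, index$dict$kmer)
  hit <- !is.na(idx)
  data.frame(pos = which(hit),
             element = index$dict$element[idx[hit]],
             strand = index$dict$strand[idx[hit]],
             stringsAsFactors = FALSE)
}

#' Classify a read by marker k-mers
#'
#' The production decoder. Steps: (1) locate anchor markers to call the
#' global strand and canonicalise the read to the forward orientation;
#' (2) locate each module by its marker hits — median hit position gives
#' the module's position, majority marker strand its orientation; (3)
#' sort modules by position to obtain the configuration. The call is
#' accepted only if all n modules are found, the parity invariant holds,
#' and the marker-consistency score (fraction of module marker hits
#' agreeing with the final call) reaches `min_score`; otherwise the read
#' is returned unclassified. Failures are statuses, never errors.
#'
#' @param read data.frame row, list, or single string; needs `id` and
#'   `sequence` (a bare string gets id "read").
#' @param index a [build_marker_index()] result.
#' @param min_score minimum marker-consistency score (default 0.6).
#' @return list: `read_id`, `status` ("classified"/"unclassified"),
#'   `configuration` (integer vector or NULL), `config_string`, `score`,
#'   `global_strand`.
#' @export
classify_read <- function(read, index, min_score = 0.6) {
  if (is.character(read)) read <- list(id = "read", sequence = read)
  seqc <- read$sequence
  res <- list(read_id = read$id, status = "unclassified",
              configuration = NULL, config_string = NA_character_,
              score = 0, global_strand = NA_character_)
  n <- index$n_modules
  hits <- marker_hits(seqc, index)
  anchors <- hits[hits$element %in% c("anchor_L", "anchor_R"), ]
  if (nrow(anchors) == 0L) return(res)
  # majority anchor strand calls the global read orientation
  fwd_votes <- sum(anchors$strand == "+")
  if (fwd_votes == nrow(anchors) - fwd_votes) return(res)
  global_strand <- if (fwd_votes > nrow(anchors) - fwd_votes) "+" else "-"
  res$global_strand <- global_strand
  if (global_strand == "-") {
    hits <- marker_hits(revcomp(seqc), index)
  }
  mh <- hits[!(hits$element %in% c("anchor_L", "anchor_R")), ]
  if (nrow(mh) == 0L) return(res)
  found <- unique(mh$element)
  if (length(found) != n) return(res)

  centre <- vapply(split(mh$pos, mh$element), median, numeric(1))
  plus <- vapply(split(mh$strand == "+", mh$element), sum, numeric(1))
  tot <- vapply(split(mh$strand, mh$element), length, numeric(1))
  elems <- names(centre)
  ord <- order(centre)
  ids <- as.integer(sub("^M", "", elems[ord]))
  orient_plus <- plus[ord] > tot[ord] / 2
  ties <- plus[ord] * 2 == tot[ord]
  if (any(ties)) return(res)
  config <- ifelse(orient_plus, ids, -ids)
  # score: fraction of module marker hits consistent with the call
  consistent <- sum(ifelse(orient_plus, plus[ord], tot[ord] - plus[ord]))
  score <- consistent / sum(tot)
  res$score <- unname(score)
  if (!is_valid_config(config, n) || score < min_score) return(res)
  res$status <- "classified"
  res$configuration <- as.integer(config)
  res$config_string <- format_config(config)
  res
}

#' Classify a read against the full reference set (exhaustive oracle)
#'
#' The faithful, slow re-implementation of map-against-all-references:
#' the global Levenshtein distance from the read (and its reverse
#' complement) to every reference sequence is computed with a bit-parallel
#' algorithm; the unique minimiser wins if its identity
#' `1 - d / max(|read|, |ref|)` reaches `identity_floor`. Any tie at the
#' minimum distance is returned unclassified — arbitrary assignment would
#' bias diversity upward. Intended as the test oracle and for small
#' batches; [classify_read()] is the production path.
#'
#' @param read as in [classify_read()].
#' @param reference_set named character vector (names = configuration
#'   strings), e.g. from [render_reference_set()].
#' @param identity_floor minimum identity of the best hit (default 0.80,
#'   a scale-free translation of the pipeline's aligner-score cutoff).
#' @return list as in [classify_read()].
#' @export
classify_read_exhaustive <- function(read, reference_set,
                                     identity_floor = 0.80) {
  if (is.character(read)) read <- list(id = "read", sequence = read)
  seqc <- read$sequence
  # early-abandoned comparisons (NA) have distance strictly above the
  # final minimum, so treating them as +Inf preserves tie semantics
  d_f <- myers_distance_best(seqc, reference_set, .Machine$integer.max)
  best_f <- suppressWarnings(min(d_f, na.rm = TRUE))
  d_r <- myers_distance_best(revcomp(seqc), reference_set,
                             if (is.finite(best_f)) best_f
                             else .Machine$integer.max)
  d_f[is.na(d_f)] <- Inf
  d_r[is.na(d_r)] <- Inf
  d <- pmin(d_f, d_r)
  best <- min(d)
  winners <- which(d == best)
  res <- list(read_id = read$id, status = "unclassified",
              configuration = NULL, config_string = NA_character_,
              score = 0, global_strand = NA_character_)
  maxlen <- pmax(nchar(seqc), nchar(reference_set))
  identity <- 1 - best / maxlen[winners[1]]
  res$score <- unname(identity)
  if (length(winners) != 1L || identity < identity_floor) return(res)
  key <- names(reference_set)[winners]
  res$status <- "classified"
  res$configuration <- parse_config(key)
  res$config_string <- key
  res$global_strand <- if (d_f[winners] <= d_r[winners]) "+" else "-"
  res
}

#' Classify a batch of reads
#'
#' Applies [size_filter()] then [classify_read()] to every read and
#' returns a tidy per-read table.
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param index a [build_marker_index()] result.
#' @param expected_length expected amplicon length; NULL skips the size
#'   filter.
#' @param tolerance size-filter tolerance.
#' @param min_score see [classify_read()].
#' @return data.frame: read_id, status, configuration, score, strand.
#' @export
classify_reads <- function(reads, index, expected_length = NULL,
                           tolerance = 0.15, min_score = 0.6) {
  filtered <- NULL
  if (!is.null(expected_length)) {
    sf <- size_filter(reads, expected_length, tolerance)
    reads <- sf$pass
    filtered <- sf$size_filtered
  }
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    r <- classify_read(list(id = reads$id[i], sequence = reads$sequence[i]),
                       index, min_score = min_score)
    data.frame(read_id = r$read_id, status = r$status,
               configuration = ifelse(is.na(r$config_string), "",
                                      r$config_string),
               score = r$score,
               strand = ifelse(is.na(r$global_strand), "",
                               r$global_strand),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(filtered) && nrow(filtered)) {
    out <- rbind(out, data.frame(read_id = filtered$id,
                                 status = "size_filtered",
                                 configuration = "", score = 0,
                                 strand = "", stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), status = character(0),
                      configuration = character(0), score = numeric(0),
                      strand = character(0))
  }
  out
}
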