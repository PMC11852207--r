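#' Construct an sfx recombination site
#'
#' An sfx site is the 31-nt crossover site recognised by a shufflon
#' invertase: a 12-bp variable left arm, a 7-bp core (spacer) and a 12-bp
#' conserved right arm.
#'
#' @param left_arm 12-nt DNA string.
#' @param core 7-nt DNA string.
#' @param right_arm 12-nt DNA string.
#' @return an object of class `sfx_site`.
#' @export
sfx_site <- function(left_arm, core, right_arm) {
  check_dna(c(left_arm, core, right_arm), "sfx site")
  if (nchar(left_arm) != 12L || nchar(core) != 7L || nchar(right_arm) != 12L) {
    stop("sfx site arms/core must be 12/7/12 nt", call. = FALSE)
  }
  structure(list(left_arm = left_arm, core = core, right_arm = right_arm),
            class = "sfx_site")
}

#' @rdname sfx_site
#' @param site an `sfx_site`.
#' @return `site_sequence()`: the 31-nt site string.
#' @export
site_sequence <- function(site) {
  stopifnot(inherits(site, "sfx_site"))
  paste0(site$left_arm, site$core, site$right_arm)
}

#' Construct a shufflon reporter design
#'
#' The physical reporter: n invertible dummy modules separated and flanked
#' by n+1 copies of one sfx site in alternating orientation (+,-,+,-,...
#' starting with +), the whole cassette embedded between two constant
#' anchor sequences used for read orientation and size selection.
#'
#' @param modules character vector of module DNA sequences, in reference
#'   order (module 1 first). Must be pairwise distinct, strict ACGT.
#' @param site an [sfx_site()].
#' @param anchor_left,anchor_right non-empty anchor DNA strings.
#' @return an object of class `shufflon_design`.
#' @export
shufflon_design <- function(modules, site, anchor_left, anchor_right) {
  stopifnot(inherits(site, "sfx_site"))
  modules <- as.character(modules)
  n <- length(modules)
  if (n < 1L) stop("need at least one module", call. = FALSE)
  check_dna(modules, "module")
  check_dna(c(anchor_left, anchor_right), "anchor")
  if (nchar(anchor_left) == 0L || nchar(anchor_right) == 0L) {
    stop("anchors must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(modules)) {
    stop("module sequences must be pairwise distinct", call. = FALSE)
  }
  ss <- site_sequence(site)
  hit <- grepl(ss, modules, fixed = TRUE) | grepl(revcomp(ss), modules,
                                                  fixed = TRUE)
  if (any(hit)) {
    stop("module ", which(hit)[1], " contains the sfx site sequence",
         call. = FALSE)
  }
  names(modules) <- paste0("M", seq_len(n))
  structure(list(modules = modules, site = site,
                 anchor_left = anchor_left, anchor_right = anchor_right),
            class = "shufflon_design")
}

#' @export
print.shufflon_design <- function(x, ...) {
  cat(sprintf("shufflon_design: %d modules (%s bp), 31-nt site, anchors %d/%d bp\n",
              length(x$modules),
              paste(nchar(x$modules), collapse = ","),
              nchar(x$anchor_left), nchar(x$anchor_right)))
  invisible(x)
}

n_modules <- function(design) length(design$modules)

#' Default five-module reporter design
#'
#' Generates a reproducible synthetic reporter matching the assayed
#' construct geometry: five modules of increasing length (143 to 521 bp),
#' one 31-nt sfx site at six alternating junctions, and ~1.25 kb anchors
#' per side so the full amplicon is ~4.3 kb (the assay size-selects
#' "approximately 4.5 kb" material). Sequences are drawn pseudo-randomly
#' from a fixed seed and screened so that no 15-mer is shared between any
#' two of the modules/anchors on either strand — the property the marker
#' decoder relies on — and so that no module contains the site.
#'
#' @param module_lengths module lengths in bp, reference order.
#' @param anchor_length anchor length per side in bp.
#' @param seed integer seed controlling all generated sequences.
#' @param marker_k word length used by the uniqueness screen.
#' @return a [shufflon_design()].
#' @export
#' @examples
#' d <- default_design()
#' nchar(build_sequence(d, 1:5))  # 4345
default_design <- function(module_lengths = c(143L, 237L, 332L, 426L, 521L),
                           anchor_length = 1250L,
                           seed = 20260911L,
                           marker_k = 15L) {
  local_seed(seed, {
    site <- sfx_site(random_dna(12), random_dna(7), random_dna(12))
    ss <- site_sequence(site)
    lens <- c(module_lengths, anchor_length, anchor_length)
    seqs <- vapply(lens, random_dna, character(1))
    # rejection screen: regenerate any sequence that shares a k-mer (either
    # strand) with another, or contains the site
    for (iter in 1:200) {
      km <- lapply(seqs, function(s) unique(c(seq_kmers(s, marker_k),
                                              revcomp(seq_kmers(s, marker_k)))))
      tab <- table(unlist(km))
      shared <- names(tab)[tab > 1L]
      bad <- vapply(seq_along(seqs), function(i) {
        any(km[[i]] %in% shared) ||
          grepl(ss, seqs[i], fixed = TRUE) ||
          grepl(revcomp(ss), seqs[i], fixed = TRUE)
      }, logical(1))
      if (!any(bad)) break
      seqs[bad] <- vapply(lens[bad], random_dna, character(1))
    }
    if (any(bad)) stop("could not generate collision-free default design")
    k <- length(module_lengths)
    shufflon_design(seqs[seq_len(k)], site,
                    anchor_left = seqs[k + 1L], anchor_right = seqs[k + 2L])
  })
}

# Site copy at junction j (0-based): orientation alternates starting '+'.
junction_site <- function(design, j) {
  ss <- site_sequence(design$site)
  if (j %% 2L == 0L) ss else revcomp(ss)
}

#' Render a configuration as a DNA sequence
#'
#' Builds `anchor_left + (site, module) x n + site + anchor_right` for a
#' given configuration. The module at position p is the sequence of the
#' module id placed there, reverse complemented when its orientation is
#' '-'. Site copies sit at fixed junction positions in fixed alternating
#' orientation for every configuration: recombination between identical
#' sites regenerates the sites, so only module content and orientation
#' vary between references. Output length is therefore constant over all
#' configurations of a design.
#'
#' @param design a [shufflon_design()].
#' @param config integer configuration (or configuration string).
#' @return a single DNA string.
#' @export
build_sequence <- function(design, config) {
  stopifnot(inherits(design, "shufflon_design"))
  if (is.character(config)) config <- parse_config(config)
  n <- n_modules(design)
  config <- validate_config(config, n)
  parts <- character(2L * n + 3L)
  parts[1] <- design$anchor_left
  for (p in seq_len(n)) {
    m <- design$modules[[abs(config[p])]]
    if (config[p] < 0) m <- revcomp(m)
    parts[2L * p] <- junction_site(design, p - 1L)
    parts[2L * p + 1L] <- m
  }
  parts[2L * n + 2L] <- junction_site(design, n)
  parts[2L * n + 3L] <- design$anchor_right
  paste(parts, collapse = "")
}

#' Render the full reference set
#'
#' One sequence per enumerated configuration, named by the canonical
#' configuration string. For the default five-module design this is the
#' 384-member reference set that reads are classified against.
#'
#' @param design a [shufflon_design()].
#' @param cap enumeration cap (see [enumerate_configurations()]).
#' @return named character vector of reference sequences.
#' @export
render_reference_set <- function(design, cap = DEFAULT_ENUM_CAP) {
  configs <- enumerate_configurations(n_modules(design), cap = cap)
  vapply(configs, function(cf) build_sequence(design, cf), character(1))
}

#' Read / write a design as FASTA plus a key-value config
#'
#' The FASTA holds records `M1..Mn`, `anchor_L`, `anchor_R`; the JSON
#' config holds the site arms. `write_design()` writes both files;
#' `read_design()` reconstructs the design.
#'
#' @param design a [shufflon_design()].
#' @param fasta,config file paths.
#' @return `read_design()`: a [shufflon_design()].
#' @export
write_design <- function(design, fasta, config) {
  n <- n_modules(design)
  seqs <- c(design$modules,
            anchor_L = design$anchor_left, anchor_R = design$anchor_right)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  jsonlite::write_json(list(site = design$site[c("left_arm", "core",
                                                 "right_arm")],
                            n_modules = n),
                       config, auto_unbox = TRUE, pretty = TRUE)
  invisible(design)
}

#' @rdname write_design
#' @export
read_design <- function(fasta, config) {
  seqs <- as.character(Biostrings::readDNAStringSet(fasta))
  cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
  n <- as.integer(cfg$n_modules)
  need <- c(paste0("M", seq_len(n)), "anchor_L", "anchor_R")
  if (!all(need %in% names(seqs))) {
    stop("design FASTA is missing records: ",
         paste(setdiff(need, names(seqs)), collapse = ", "), call. = FALSE)
  }
  shufflon_design(unname(seqs[paste0("M", seq_len(n))]),
                  sfx_site(cfg$site$left_arm, cfg$site$core,
                           cfg$site$right_arm),
                  anchor_left = unname(seqs[["anchor_L"]]),
                  anchor_right = unname(seqs[["anchor_R"]]))
}

#' Write a reference set as multi-FASTA
#'
#' Record ids are the configuration strings (e.g. `"+1-4+3-2+5"`).
#'
#' @param refs named character vector from [render_reference_set()].
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(refs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  invisible(path)
}
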