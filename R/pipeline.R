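#' Build a run configuration
#'
#' Collects every tunable of an end-to-end run (design, simulation,
#' classification, statistics) around a single master seed. All child
#' seeds are derived from the master by fixed offsets, so each stage is
#' independently reproducible. The config is serialised verbatim into the
#' output directory and embedded in the final report.
#'
#' @param module_lengths,anchor_length,design_seed design parameters
#'   (see [default_design()]).
#' @param n_members,event_rate,weight_preset library simulation.
#' @param depth,sub_rate,ins_rate,del_rate read simulation.
#' @param marker_k,min_score,size_tolerance classifier.
#' @param diversity_sample_size,diversity_draws statistics.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(module_lengths = c(143L, 237L, 332L, 426L, 521L),
                       anchor_length = 1250L,
                       design_seed = 20260911L,
                       n_members = 500L,
                       event_rate = 3,
                       weight_preset = "uniform",
                       depth = 1L,
                       sub_rate = 0.02, ins_rate = 0.02, del_rate = 0.02,
                       marker_k = 15L, min_score = 0.6,
                       size_tolerance = 0.15,
                       diversity_sample_size = 4000L,
                       diversity_draws = 50L,
                       seed = 1L) {
  cfg <- list(module_lengths = as.integer(module_lengths),
              anchor_length = as.integer(anchor_length),
              design_seed = as.integer(design_seed),
              n_members = as.integer(n_members),
              event_rate = as.numeric(event_rate),
              weight_preset = weight_preset,
              depth = as.integer(depth),
              sub_rate = as.numeric(sub_rate),
              ins_rate = as.numeric(ins_rate),
              del_rate = as.numeric(del_rate),
              marker_k = as.integer(marker_k),
              min_score = as.numeric(min_score),
              size_tolerance = as.numeric(size_tolerance),
              diversity_sample_size = as.integer(diversity_sample_size),
              diversity_draws = as.integer(diversity_draws),
              seed = as.integer(seed))
  stopifnot(cfg$n_members >= 1, cfg$event_rate >= 0, cfg$depth >= 1,
            cfg$size_tolerance > 0, cfg$size_tolerance < 1)
  error_model(cfg$sub_rate, cfg$ins_rate, cfg$del_rate)  # validates rates
  match.arg(cfg$weight_preset, c("uniform", "positional_bias"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full in-silico assay
#'
#' design -> simulate library -> simulate reads -> classify -> statistics,
#' writing intermediate artifacts (FASTA / FASTQ / TSV / JSON) and a final
#' JSON report to `outdir`. Identical configs and seeds produce identical
#' outputs. Stage failures abort with the stage named; artifacts written
#' before the failure are preserved.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(outdir, "config.json"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  design <- stage("design", {
    d <- default_design(module_lengths = config$module_lengths,
                        anchor_length = config$anchor_length,
                        seed = config$design_seed,
                        marker_k = config$marker_k)
    write_design(d, file.path(outdir, "design.fasta"),
                 file.path(outdir, "design.json"))
    d
  })
  n <- n_modules(design)
  refs <- stage("references", {
    r <- render_reference_set(design)
    write_reference_fasta(r, file.path(outdir, "references.fasta"))
    r
  })
  members <- stage("simulate_library", {
    simulate_library(n, config$n_members, config$event_rate,
                     weights = event_weights(n, config$weight_preset),
                     seed = child_seed(config$seed, 1L))
  })
  sim <- stage("simulate_reads", {
    templates <- setNames(refs[names(members)], names(members))
    s <- simulate_reads(templates,
                        error_model(config$sub_rate, config$ins_rate,
                                    config$del_rate),
                        depth = config$depth,
                        seed = child_seed(config$seed, 2L))
    write_fastq(s$reads, file.path(outdir, "reads.fastq"))
    utils::write.table(s$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })
  calls <- stage("classify", {
    index <- build_marker_index(design, k = config$marker_k)
    cl <- classify_reads(sim$reads, index,
                         expected_length = nchar(refs[[1]]),
                         tolerance = config$size_tolerance,
                         min_score = config$min_score)
    utils::write.table(cl, file.path(outdir, "classifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl
  })
  report <- stage("stats", {
    classified <- calls[calls$status == "classified", ]
    summary <- library_summary(classified$configuration,
                               n_unclassified = sum(calls$status !=
                                                      "classified"),
                               n_modules = n)
    write_summary_json(summary, file.path(outdir, "library_summary.json"))
    depths <- reachable_set(n)
    div <- diversity(summary,
                     sample_size = config$diversity_sample_size,
                     n_draws = config$diversity_draws,
                     seed = child_seed(config$seed, 3L))
    inv <- inversion_frequency(list(run = summary),
                               nchar(design$modules))
    utils::write.table(inv, file.path(outdir, "inversion_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(package_version = as.character(utils::packageVersion("shufflonr")),
         config = unclass(config),
         n_reads = nrow(calls),
         n_classified = summary$n_classified,
         n_unclassified = summary$n_unclassified,
         shuffling_rate = shuffling_rate(summary),
         occupancy = occupancy(summary),
         inversion_count_distribution =
           as.list(inversion_count_distribution(summary, depths)),
         diversity_mean_unique = div$mean_unique,
         rarefaction = div$rarefaction,
         inversion_frequency = inv)
  })
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by `inst/scripts/shufflon`. Subcommands:
#' `count`, `enumerate`, `simulate`, `classify`, `stats`, `mine`, `run`.
#' Machine output goes to stdout / files; logs to stderr.
#'
#' @param args character vector of command-line arguments (first element
#'   the subcommand).
#' @return exit status, invisibly.
#' @export
shufflon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: shufflon <count|enumerate|simulate|classify|stats|mine|run> [options]",
    "  count      --n <modules>",
    "  enumerate  --n <modules>",
    "  run        --config <json> --out <dir> | --out <dir> [--seed S]",
    "  classify   --design-fasta F --design-config J --fastq F --out TSV",
    "  stats      --summary JSON --out JSON",
    "  mine       --fasta F --out TSV [--k 13]",
    sep = "\n")
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the CLI requires the 'optparse' package", call. = FALSE)
  }
  sub <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--n", type = "integer", default = 5L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--design-fasta", type = "character",
                          default = NULL, dest = "design_fasta"),
    optparse::make_option("--design-config", type = "character",
                          default = NULL, dest = "design_config"),
    optparse::make_option("--fastq", type = "character", default = NULL),
    optparse::make_option("--summary", type = "character", default = NULL),
    optparse::make_option("--fasta", type = "character", default = NULL),
    optparse::make_option("--k", type = "integer", default = 13L))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                              args = rest)
  switch(sub,
    count = {
      cat(format(count_configurations(opt$n), scientific = FALSE), "\n")
    },
    enumerate = {
      cat(names(enumerate_configurations(opt$n)), sep = "\n")
      message(sprintf("analytic count: %s",
                      format(count_configurations(opt$n),
                             scientific = FALSE)))
    },
    simulate = ,
    run = {
      if (is.null(opt$out)) stop("run: --out is required", call. = FALSE)
      cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
             else run_config(seed = opt$seed)
      message("running pipeline into ", opt$out)
      run_pipeline(cfg, opt$out)
    },
    classify = {
      if (is.null(opt$design_fasta) || is.null(opt$design_config) ||
          is.null(opt$fastq) || is.null(opt$out)) {
        stop("classify: --design-fasta, --design-config, --fastq, --out required",
             call. = FALSE)
      }
      d <- read_design(opt$design_fasta, opt$design_config)
      index <- build_marker_index(d)
      reads <- read_fastq(opt$fastq)
      cl <- classify_reads(reads, index,
                           expected_length = nchar(build_sequence(
                             d, seq_len(n_modules(d)))))
      utils::write.table(cl, opt$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message(sum(cl$status == "classified"), "/", nrow(cl),
              " reads classified")
    },
    stats = {
      if (is.null(opt$summary) || is.null(opt$out)) {
        stop("stats: --summary and --out required", call. = FALSE)
      }
      s <- read_summary_json(opt$summary)
      jsonlite::write_json(
        list(shuffling_rate = shuffling_rate(s),
             occupancy = occupancy(s),
             inversion_count_distribution =
               as.list(inversion_count_distribution(s))),
        opt$out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    },
    mine = {
      if (is.null(opt$fasta) || is.null(opt$out)) {
        stop("mine: --fasta and --out required", call. = FALSE)
      }
      res <- mine_flanks(opt$fasta, k = opt$k)
      utils::write.table(res$loci, opt$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(as.list(res$summary),
                           paste0(opt$out, ".summary.json"),
                           auto_unbox = TRUE)
      message(paste(names(res$summary), as.integer(res$summary),
                    sep = "=", collapse = " "))
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
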