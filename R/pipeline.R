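#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config schema. Defaults are the
#' published parameter set wherever one is stated (einverted scores, hairpin
#' thresholds, 18-27 nt read window, wobble scoring with cutoff 18); the
#' rest are this package's declared defaults. `inputs` left NULL switch the
#' run to the seeded synthetic scenario.
#'
#' @param seed integer seed for the synthetic scenario.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    schema_version = 1L,
    seed = as.integer(seed),
    inputs = list(b_fasta = NULL, a_fasta = NULL, reads = NULL,
                  alignment = NULL, depth = NULL),
    synthetic = list(),
    ir = list(match = 4L, mismatch = -4L, gap = -8L, min_score = 50L,
              max_span = 350L),
    hairpin = list(max_terminal_loop = 40L, min_paired_stem = 20L,
                   max_mismatches = 4L, max_asym_bulges = 2L),
    srna = list(min_len = 18L, max_len = 27L, adapter = NULL,
                max_mismatches = 0L, min_expression = 5,
                size_min = 21L, size_max = 24L),
    targets = list(match = 1, mismatch = -1, gap = -2, wobble = -0.5,
                   cutoff = 18, comparator = ">="),
    coverage = list(min_depth = 1L, breadth_threshold = 0.9),
    outdir = NULL
  )
}

check_config_keys <- function(cfg, defaults, path = "") {
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]]) && k != "synthetic")
      check_config_keys(cfg[[k]], defaults[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are errors, not warnings: silent parameter drift is the main
#' reproducibility hazard in a multi-stage screen.
#'
#' @param path YAML file.
#' @return configuration list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  check_config_keys(cfg, defaults)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]) &&
                       k != "synthetic")
        merge_lists(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_lists(defaults, cfg)
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full dominance-modifier discovery pipeline
#'
#' Stage order: inverted repeats on the B-like locus, sRNA expression screen,
#' hairpin structural filter, retained precursors, expressed-sRNA window
#' extraction, target scan on the A-like locus, plus optional diversity and
#' coverage stages. With no input paths configured, the seeded synthetic
#' scenario supplies all inputs.
#'
#' @param config configuration list (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return list of class `slocus_report`: stage `counts` (n_ir, n_expressed,
#'   n_passing, n_retained, n_targets), result tables, diversity and
#'   coverage results where computed, and a text `log`.
#' @export
run_all <- function(config = default_pipeline_config()) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  synthetic <- is.null(config$inputs$b_fasta)
  scen <- NULL
  if (synthetic) {
    scen <- simulate_scenario(do.call(synthetic_config,
                                      c(list(seed = config$seed),
                                        config$synthetic)))
    b_seq <- scen$haplotypes["B_hap"]
    a_seq <- scen$haplotypes["A_hap"]
    reads <- scen$reads
    aln <- scen$population
    depths <- scen$depths
    say("inputs: synthetic scenario (seed %d)", config$seed)
  } else {
    b_seq <- read_fasta(config$inputs$b_fasta)[1]
    a_seq <- read_fasta(config$inputs$a_fasta)[1]
    reads <- if (!is.null(config$inputs$reads))
      read_srna_reads(config$inputs$reads) else NULL
    aln <- if (!is.null(config$inputs$alignment))
      read_fasta(config$inputs$alignment) else NULL
    depths <- if (!is.null(config$inputs$depth))
      read_depth_table(config$inputs$depth) else NULL
    say("inputs: %s / %s", config$inputs$b_fasta, config$inputs$a_fasta)
  }

  irp <- do.call(ir_params, config$ir)
  irs <- find_inverted_repeats(b_seq, irp)
  say("find-ir: %d inverted repeats (min_score=%d, max_span=%d)",
      nrow(irs), irp$min_score, irp$max_span)

  crit <- do.call(hairpin_criteria, config$hairpin)
  sr <- config$srna
  if (is.null(reads)) stop("stage srna: no reads provided", call. = FALSE)
  fr <- filter_reads(reads, adapter = sr$adapter, min_len = sr$min_len,
                     max_len = sr$max_len)
  refs <- c(b_seq, a_seq)
  mapped <- map_reads(fr, refs, max_mismatches = sr$max_mismatches)
  say("map-reads: %d distinct reads, %d placements", nrow(fr), nrow(mapped))
  expr <- hairpin_expression(irs, mapped,
                             size_range = c(sr$size_min, sr$size_max))
  screened <- screen_candidates(irs, crit, expr,
                                min_expression = sr$min_expression)
  counts <- c(n_ir = nrow(screened),
              n_expressed = sum(screened$expressed),
              n_passing = sum(screened$passes),
              n_retained = sum(screened$retained))
  say("screen-hairpins: %d expressed, %d passing, %d retained",
      counts["n_expressed"], counts["n_passing"], counts["n_retained"])

  scheme <- wobble_scheme(match = config$targets$match,
                          mismatch = config$targets$mismatch,
                          gap = config$targets$gap,
                          wobble = config$targets$wobble,
                          cutoff = config$targets$cutoff,
                          comparator = config$targets$comparator)
  retained <- screened[screened$retained, , drop = FALSE]
  target_hits <- list()
  for (k in seq_len(nrow(retained))) {
    srna_k <- top_expressed_read(mapped, retained[k, ],
                                 size_range = c(sr$size_min, sr$size_max))
    if (is.na(srna_k)) next
    hits <- scan_targets(srna_k, a_seq, scheme,
                         srna_id = sprintf("precursor%d_sRNA", k))
    if (nrow(hits)) target_hits[[length(target_hits) + 1L]] <- hits
  }
  targets <- if (length(target_hits)) do.call(rbind, target_hits) else
    data.frame(srna_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               score = numeric(0), n_gaps = integer(0),
               pairing = character(0))
  counts <- c(counts, n_targets = nrow(targets))
  say("predict-targets: %d hits %s %g", nrow(targets), scheme$comparator,
      scheme$cutoff)

  div <- NULL
  if (!is.null(aln) && length(aln) >= 2L) {
    div <- diversity(aln)
    say("diversity: n=%d S=%d pi=%.6f thetaW=%.6f", div$n, div$S, div$pi,
        div$theta_w)
  }
  cov <- NULL
  if (!is.null(depths)) {
    cov <- coverage_calls(depths, config$coverage$min_depth,
                          config$coverage$breadth_threshold)
    say("coverage-call: %d/%d present", sum(cov$present), nrow(cov))
  }

  report <- structure(list(counts = counts, inverted_repeats = irs,
                           screened = screened, targets = targets,
                           diversity = div, coverage = cov,
                           truth = if (synthetic) scen$truth else NULL,
                           config = config, log = log_lines),
                      class = "slocus_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    lens <- stats::setNames(nchar(refs), names(refs))
    write_ir_gff3(irs, file.path(config$outdir, "inverted_repeats.gff3"), lens)
    write_precursor_gff3(screened,
                         file.path(config$outdir, "precursors.gff3"), lens)
    write_target_gff3(targets, file.path(config$outdir, "targets.gff3"), lens)
    utils::write.table(screened[, setdiff(names(screened),
                                          c("aln_left", "aln_right"))],
                       file.path(config$outdir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(targets, file.path(config$outdir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(config$outdir, "pipeline.log"))
  }
  report
}

#' @export
print.slocus_report <- function(x, ...) {
  cat("S-locus dominance-modifier screen\n")
  cat(sprintf("  inverted repeats : %d\n", x$counts["n_ir"]))
  cat(sprintf("  expressed        : %d\n", x$counts["n_expressed"]))
  cat(sprintf("  hairpin-passing  : %d\n", x$counts["n_passing"]))
  cat(sprintf("  retained         : %d\n", x$counts["n_retained"]))
  cat(sprintf("  target hits      : %d\n", x$counts["n_targets"]))
  if (!is.null(x$diversity))
    cat(sprintf("  diversity        : pi=%.4g thetaW=%.4g (S=%d, n=%d)\n",
                x$diversity$pi, x$diversity$theta_w, x$diversity$S,
                x$diversity$n))
  if (!is.null(x$coverage))
    cat(sprintf("  coverage         : %d/%d haplotypes present\n",
                sum(x$coverage$present), nrow(x$coverage)))
  invisible(x)
}
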