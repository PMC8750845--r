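#' Default run configuration
#'
#' All tunables of the pipeline in one list, round-trippable through YAML
#' ([read_run_config()] / [write_run_config()]). Every run echoes its fully
#' resolved configuration into the output, so results are reproducible from
#' the output directory alone.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # pair alignment / site catalog
    match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L,
    count_gap_runs = TRUE,
    # QC
    min_len = 3000L, max_len = 5000L, min_score_frac = 0.4,
    # read alignment: band half-width covers indel drift and modest trimming
    # with a wide margin at ~6x less work than the full dynamic program
    band_width = 300L,
    # caller
    reference_gene = "A", min_site_coverage = 5L,
    min_separation = 0.30, min_amplitude = 0.30, min_plateau_sites = 3L,
    percentile_convention = "linear-interpolation (type 7)",
    recommended_depth = 200L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full crossover-calling pipeline on one sample
#'
#' Chains the whole analysis: length filter, on-target selection, per-read
#' genotyping at the catalog sites, mismatch-rate profile, background and
#' foreground levels, sigmoid fit and fusion call. The on-target decision
#' reuses the genotyping alignments (best score fraction against either
#' paralog), so each read is aligned once per paralog.
#'
#' @param reads a [read_set()].
#' @param pair the [gene_pair()].
#' @param model optional [gene_model] for region labels.
#' @param catalog optional precomputed [extract_informative_sites()] catalog
#'   (built from `pair` when NULL).
#' @param config a [run_config()].
#' @return list of class `run_result`: `qc` (counts per stage), `calls`,
#'   `profile`, `background`, `foreground`, `fit`, `call`, `catalog`,
#'   `config`.
#' @export
run_sample <- function(reads, pair, model = NULL, catalog = NULL,
                       config = run_config()) {
  params <- align_params(config$match, config$mismatch, config$gap_open,
                         config$gap_extend)
  if (is.null(catalog)) {
    aln <- align_gene_pair(pair, params)
    catalog <- extract_informative_sites(aln, config$count_gap_runs)
  }
  n_input <- length(reads)
  reads <- length_filter(reads, config$min_len, config$max_len)
  n_length_pass <- length(reads)
  if (n_length_pass == 0L) stop("no informative coverage: no reads in the length window")
  calls <- genotype_reads(reads, pair, catalog, params, config$band_width)
  on_target <- calls$score_frac >= config$min_score_frac
  n_on_target <- sum(on_target)
  if (n_on_target == 0L) stop("no informative coverage: no on-target reads")
  if (n_on_target < config$recommended_depth)
    warning(sprintf("only %d on-target reads; calls are stable from about %d",
                    n_on_target, config$recommended_depth))
  calls <- calls[on_target]
  res <- .call_from_calls(calls, catalog, model,
                          reference_gene = config$reference_gene,
                          min_site_coverage = config$min_site_coverage,
                          min_separation = config$min_separation,
                          min_amplitude = config$min_amplitude,
                          min_plateau_sites = config$min_plateau_sites)
  structure(list(qc = list(n_input = n_input, n_length_pass = n_length_pass,
                           n_on_target = n_on_target,
                           corrected = reads$corrected),
                 calls = calls, profile = res$profile,
                 background = res$background, foreground = res$foreground,
                 fit = res$fit, call = res$call, catalog = catalog,
                 config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d reads -> %d length-pass -> %d on-target\n",
              x$qc$n_input, x$qc$n_length_pass, x$qc$n_on_target))
  print(x$call)
  invisible(x)
}
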