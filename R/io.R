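#' Export a mismatch profile as TSV
#'
#' One row per site: `site` (catalog row), `position`, `kind`, `n`, `m`,
#' `rate`, `used`.
#'
#' @param profile a [build_mismatch_profile()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a fusion call (plus run metadata) as JSON
#'
#' The JSON carries the call (status, interval, label, background,
#' foreground, fit parameters) and an echo of the resolved configuration, so
#' a result is interpretable without the session that made it. No timestamps
#' are written: identical inputs give byte-identical output.
#'
#' @param result a [run_sample()] result (or a list with the same fields).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_call_json <- function(result, path) {
  call <- result$call
  fit <- call$fit
  out <- list(
    status = call$status,
    crossover_interval = if (is.null(call$crossover_interval)) NULL
      else as.list(call$crossover_interval),
    region_label = call$region_label,
    background = call$background,
    foreground = if (is.na(call$foreground)) NULL else call$foreground,
    reference_gene = call$reference_gene,
    fit = list(converged = fit$converged, degenerate = fit$degenerate,
               asym_left = fit$asym_left, asym_right = fit$asym_right,
               slope = fit$slope, inflection = fit$inflection,
               residual_sd = fit$residual_sd, n_sites = fit$n_sites),
    qc = result$qc,
    config = if (!is.null(result$config)) unclass(result$config) else NULL,
    version = as.character(utils::packageVersion("chimeratrace")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
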