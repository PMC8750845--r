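#' Read long-read sequences from FASTQ or FASTA
#'
#' Format is detected from the first character of the file (`@` FASTQ, `>`
#' FASTA); gzipped input is handled transparently.
#'
#' @param path FASTQ or FASTA file.
#' @param corrected provenance flag: were these reads error-corrected
#'   upstream? Carried into QC reports.
#' @return an object of class `read_set`: list with `id`, `seq` (character
#'   vectors), `qual` (character or NULL), `corrected`.
#' @export
read_reads <- function(path, corrected = FALSE) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  con <- gzfile(path, "rb")
  first <- rawToChar(readBin(con, "raw", 1L))
  close(con)
  if (identical(first, "@")) {
    # mcols dropped when coercing the quality track; nothing of value is lost
    qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    read_set(sub("\\s.*$", "", names(qs)), as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             corrected = corrected)
  } else if (identical(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    read_set(sub("\\s.*$", "", names(ss)), as.character(ss),
             corrected = corrected)
  } else stop("'", path, "' is neither FASTA nor FASTQ")
}

#' Hook for externally corrected reads
#'
#' Accepts reads that were error-corrected outside the package (e.g. by a
#' long-read consensus tool); they flow through the identical pipeline with a
#' `corrected = TRUE` provenance flag in all reports.
#'
#' @inheritParams read_reads
#' @return a `read_set` with `corrected = TRUE`.
#' @export
external_corrected_input <- function(path) read_reads(path, corrected = TRUE)

#' @rdname read_reads
#' @param id,seq,qual parallel vectors of identifiers, sequences and
#'   (optionally) quality strings.
#' @export
read_set <- function(id, seq, qual = NULL, corrected = FALSE) {
  stopifnot(length(id) == length(seq),
            is.null(qual) || length(qual) == length(seq))
  structure(list(id = unname(as.character(id)), seq = unname(toupper(seq)),
                 qual = if (is.null(qual)) NULL else unname(qual),
                 corrected = isTRUE(corrected)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s%s\n", length(x$id),
              if (is.null(x$qual)) "" else " (with qualities)",
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' Subset a read set
#' @param x a `read_set`.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.read_set` <- function(x, i, ...) {
  read_set(x$id[i], x$seq[i],
           qual = if (is.null(x$qual)) NULL else x$qual[i],
           corrected = x$corrected)
}

#' Keep reads inside the amplicon length window
#'
#' Long-range PCR of the chimeric locus yields a single product of known
#' size; reads far outside that window are fragments or artefacts. Bounds
#' are inclusive; defaults suit a ~3.9 kb amplicon.
#'
#' @param reads a [read_set()].
#' @param min_len,max_len inclusive length bounds in bp.
#' @return the filtered `read_set`, order preserved.
#' @export
length_filter <- function(reads, min_len = 3000L, max_len = 5000L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len]
}

#' Keep reads that align to the paralog locus pair
#'
#' A read is on-target when its best local-alignment score against either
#' paralog, in either orientation, reaches `min_score_frac` of the maximum
#' attainable score (`match * read_length`). Off-target PCR products and
#' junk reads score far below any sensible threshold; the default 0.4 leaves
#' a wide margin on both sides.
#'
#' @param reads a [read_set()].
#' @param pair the [gene_pair()].
#' @param params [align_params()].
#' @param min_score_frac pass threshold as a fraction of the perfect score.
#' @param band_width band half-width passed to [local_align()]; 0 = exact.
#' @return list with `reads` (the passing subset) and `report`, a `qc_report`
#'   holding per-read dispositions (`best_gene`, `orientation`, `score_frac`).
#' @export
on_target_filter <- function(reads, pair, params = align_params(),
                             min_score_frac = 0.4, band_width = 0L) {
  stopifnot(min_score_frac > 0, min_score_frac <= 1)
  n <- length(reads)
  best_frac <- numeric(n); best_gene <- character(n); orient <- character(n)
  rc <- ct_revcomp(reads$seq)
  for (i in seq_len(n)) {
    cand <- list(
      c(gene = "A", strand = "+",
        score = local_align(reads$seq[i], pair$seq_a, params, band_width)$score),
      c(gene = "B", strand = "+",
        score = local_align(reads$seq[i], pair$seq_b, params, band_width)$score),
      c(gene = "A", strand = "-",
        score = local_align(rc[i], pair$seq_a, params, band_width)$score),
      c(gene = "B", strand = "-",
        score = local_align(rc[i], pair$seq_b, params, band_width)$score))
    sc <- vapply(cand, function(x) as.numeric(x[["score"]]), 0)
    k <- which.max(sc)  # first maximum: forward preferred on ties
    best_frac[i] <- sc[k] / (params$match * nchar(reads$seq[i]))
    best_gene[i] <- cand[[k]][["gene"]]
    orient[i] <- cand[[k]][["strand"]]
  }
  pass <- best_frac >= min_score_frac
  disposition <- data.frame(id = reads$id, length = nchar(reads$seq),
                            best_gene = best_gene, orientation = orient,
                            score_frac = best_frac, on_target = pass,
                            stringsAsFactors = FALSE)
  report <- structure(list(n_input = n, n_on_target = sum(pass),
                           corrected = reads$corrected,
                           disposition = disposition),
                      class = "qc_report")
  list(reads = reads[pass], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d reads in, %d on-target%s\n", x$n_input,
              x$n_on_target, if (x$corrected) " (corrected input)" else ""))
  invisible(x)
}

#' Write reads as FASTQ
#'
#' Reads lacking quality strings get a constant dummy quality (`I`, Q40).
#'
#' @param reads a [read_set()].
#' @param path output file (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  qual <- if (is.null(reads$qual))
    vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  else reads$qual
  qs <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qs, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}
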