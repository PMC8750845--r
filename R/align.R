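#' Alignment scoring parameters
#'
#' Scores for the affine-gap Smith-Waterman aligner used throughout the
#' package. A gap of length L costs `gap_open + L * gap_extend`. `N` bases
#' score as a mismatch against everything, including `N`.
#'
#' Defaults are conventional DNA local-alignment scores (match +2,
#' mismatch -3, gap open 5, gap extend 2).
#'
#' @param match positive match score.
#' @param mismatch mismatch penalty, given as a negative score.
#' @param gap_open gap-opening penalty (positive cost).
#' @param gap_extend per-base gap-extension penalty (positive cost).
#' @return an object of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

#' Local (Smith-Waterman) alignment of two sequences
#'
#' Optimal affine-gap local alignment with deterministic tie-breaking
#' (diagonal > up > left in the traceback; the first maximal cell in
#' row-major order starts the trace). Optionally banded around a diagonal
#' offset for speed; `band_width = 0` computes the full dynamic program.
#'
#' @param query,target DNA strings (characters, uppercase ACGTN).
#' @param params an [align_params()] object.
#' @param band_width half-width of the diagonal band, in bases; 0 disables
#'   banding (exact alignment).
#' @param band_offset center diagonal of the band, as `target_pos - query_pos`.
#' @return a list of class `ct_alignment` with elements `score`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (1-based, inclusive; 0 when no
#'   positive-scoring alignment exists), `qpos`/`tpos` (parallel vectors of
#'   aligned positions, 0 marking a gap), and `t_base`, a character vector of
#'   length `nchar(target)` giving the query base aligned to each target
#'   position (`"-"` for a deletion in the query, `NA` outside the aligned
#'   span).
#' @export
local_align <- function(query, target, params = align_params(),
                        band_width = 0L, band_offset = 0L) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(target), length(target) == 1L, nzchar(target))
  res <- .sw_align_cpp(query, target, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       as.integer(band_width), as.integer(band_offset))
  n <- nchar(target)
  t_base <- rep(NA_character_, n)
  if (res$score > 0L) {
    qb <- strsplit(query, "", fixed = TRUE)[[1]]
    keep <- res$tpos > 0L
    tp <- res$tpos[keep]
    qp <- res$qpos[keep]
    t_base[tp] <- ifelse(qp > 0L, qb[pmax(qp, 1L)], "-")
  }
  structure(c(res, list(t_base = t_base, params = params)),
            class = "ct_alignment")
}

#' @export
print.ct_alignment <- function(x, ...) {
  cat(sprintf("<ct_alignment> score %d; query %d-%d; target %d-%d; %d columns\n",
              x$score, x$q_start, x$q_end, x$t_start, x$t_end, length(x$qpos)))
  invisible(x)
}

# reverse-complement for plain character vectors, via Biostrings
ct_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
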