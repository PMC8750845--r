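# Per-read genotyping at catalog sites.
#
# Observation coding at discriminating sites:
#   1 = matches gene A, 2 = matches gene B, 0 = matches neither
#   (sequencing/PCR error, or a gap at a substitution-type site),
#   NA = site not covered by the read's alignment to the host paralog.
# Ambiguous sites are coded TRUE (read differs from the shared base),
# FALSE (read agrees), NA (uncovered, or a gap).

# Precompute per-catalog indexing shared by every read.
.catalog_index <- function(catalog) {
  s <- catalog$sites
  disc <- which(s$kind == "discriminating")
  amb <- which(s$kind == "ambiguous")
  d <- s[disc, , drop = FALSE]
  type <- ifelse(d$base_a == "-", "GB", ifelse(d$base_b == "-", "GA", "M"))
  list(disc_rows = disc, amb_rows = amb,
       d_type = type,
       d_pos_a = d$pos_a, d_pos_b = d$pos_b,
       d_base_a = d$base_a, d_base_b = d$base_b,
       d_len = d$run_length,
       a_pos = s$pos_a[amb], a_base = s$base_a[amb])
}

# Genotype one oriented read given its two alignments' target-base maps.
.site_calls_from_maps <- function(obs_a, obs_b, ci) {
  nd <- length(ci$d_type)
  disc <- rep(NA_integer_, nd)
  simple <- ci$d_type == "M"
  if (any(simple)) {
    o <- obs_a[ci$d_pos_a[simple]]
    disc[simple] <- ifelse(is.na(o), NA_integer_,
                    ifelse(o == ci$d_base_a[simple], 1L,
                    ifelse(o == ci$d_base_b[simple], 2L, 0L)))
  }
  for (k in which(!simple)) {
    if (ci$d_type[k] == "GA") {     # bases live in A; gene B is gapped here
      pos <- ci$d_pos_a[k] + seq_len(ci$d_len[k]) - 1L
      o <- obs_a[pos]
      exp_b <- strsplit(ci$d_base_a[k], "", fixed = TRUE)[[1]]
      disc[k] <- if (anyNA(o)) NA_integer_
                 else if (all(o == exp_b)) 1L
                 else if (all(o == "-")) 2L
                 else 0L
    } else {                        # bases live in B; gene A is gapped here
      pos <- ci$d_pos_b[k] + seq_len(ci$d_len[k]) - 1L
      o <- obs_b[pos]
      exp_b <- strsplit(ci$d_base_b[k], "", fixed = TRUE)[[1]]
      disc[k] <- if (anyNA(o)) NA_integer_
                 else if (all(o == exp_b)) 2L
                 else if (all(o == "-")) 1L
                 else 0L
    }
  }
  o <- obs_a[ci$a_pos]
  amb <- ifelse(is.na(o) | o == "-", NA, o != ci$a_base)
  list(disc = disc, amb = amb)
}

#' Genotype a single read at every catalog site
#'
#' Aligns the read to both paralogs, picks the orientation with the best
#' combined (A + B) score (forward preferred on an exact tie), and records
#' the read's base at every informative site: each site is read off the
#' alignment to its host paralog (sites with a base in gene A off the
#' A-alignment; gap-in-A sites off the B-alignment), so indel-type
#' discriminating sites are well defined.
#'
#' @param read a single DNA string.
#' @param pair the [gene_pair()].
#' @param catalog the [extract_informative_sites()] catalog.
#' @param params [align_params()].
#' @param band_width band half-width for [local_align()]; 0 = exact.
#' @param min_score_frac if non-NULL, error when the best score fraction
#'   falls below it (reads are expected to have passed QC already).
#' @return list of class `read_calls`: `orientation` (`"+"`/`"-"`),
#'   `score_a`, `score_b`, `score_frac`, `disc` (integer codes, see above),
#'   `amb` (logical codes).
#' @export
genotype_read <- function(read, pair, catalog, params = align_params(),
                          band_width = 0L, min_score_frac = NULL) {
  ci <- .catalog_index(catalog)
  fwd_a <- local_align(read, pair$seq_a, params, band_width)
  fwd_b <- local_align(read, pair$seq_b, params, band_width)
  rcr <- ct_revcomp(read)
  rev_a <- local_align(rcr, pair$seq_a, params, band_width)
  rev_b <- local_align(rcr, pair$seq_b, params, band_width)
  if (fwd_a$score + fwd_b$score >= rev_a$score + rev_b$score) {
    orient <- "+"; aln_a <- fwd_a; aln_b <- fwd_b
  } else {
    orient <- "-"; aln_a <- rev_a; aln_b <- rev_b
  }
  frac <- max(aln_a$score, aln_b$score) / (params$match * nchar(read))
  if (!is.null(min_score_frac) && frac < min_score_frac)
    stop("read aligns to neither paralog above the QC threshold")
  calls <- .site_calls_from_maps(aln_a$t_base, aln_b$t_base, ci)
  structure(list(orientation = orient, score_a = aln_a$score,
                 score_b = aln_b$score, score_frac = frac,
                 disc = calls$disc, amb = calls$amb),
            class = "read_calls")
}

#' Genotype a read set at every catalog site
#'
#' Batch version of [genotype_read()]. For speed the orientation of each read
#' is chosen by its gene-A alignment scores (`orientation_by = "gene_a"`,
#' three alignments per read); `"total"` reproduces the single-read contract
#' exactly (four alignments per read). With paralogs this similar the two
#' rules agree except on pathological reads.
#'
#' @inheritParams genotype_read
#' @param reads a [read_set()].
#' @param orientation_by `"gene_a"` (fast) or `"total"`.
#' @return object of class `site_calls`: `disc` (reads x discriminating-sites
#'   integer matrix), `amb` (reads x ambiguous-sites logical matrix),
#'   `orientation`, `score_frac`, `best_gene`, `id`, plus the catalog row
#'   indices of the site columns.
#' @export
genotype_reads <- function(reads, pair, catalog, params = align_params(),
                           band_width = 0L,
                           orientation_by = c("gene_a", "total")) {
  orientation_by <- match.arg(orientation_by)
  ci <- .catalog_index(catalog)
  n <- length(reads)
  nd <- length(ci$disc_rows); na <- length(ci$amb_rows)
  disc <- matrix(NA_integer_, n, nd)
  amb <- matrix(NA, n, na)
  orient <- character(n); frac <- numeric(n)
  score_a <- integer(n); score_b <- integer(n)
  rc <- ct_revcomp(reads$seq)
  for (i in seq_len(n)) {
    fwd_a <- local_align(reads$seq[i], pair$seq_a, params, band_width)
    rev_a <- local_align(rc[i], pair$seq_a, params, band_width)
    if (orientation_by == "gene_a") {
      plus <- fwd_a$score >= rev_a$score
      aln_a <- if (plus) fwd_a else rev_a
      aln_b <- local_align(if (plus) reads$seq[i] else rc[i], pair$seq_b,
                           params, band_width)
    } else {
      fwd_b <- local_align(reads$seq[i], pair$seq_b, params, band_width)
      rev_b <- local_align(rc[i], pair$seq_b, params, band_width)
      plus <- fwd_a$score + fwd_b$score >= rev_a$score + rev_b$score
      aln_a <- if (plus) fwd_a else rev_a
      aln_b <- if (plus) fwd_b else rev_b
    }
    orient[i] <- if (plus) "+" else "-"
    score_a[i] <- aln_a$score; score_b[i] <- aln_b$score
    frac[i] <- max(aln_a$score, aln_b$score) /
      (params$match * nchar(reads$seq[i]))
    calls <- .site_calls_from_maps(aln_a$t_base, aln_b$t_base, ci)
    disc[i, ] <- calls$disc
    amb[i, ] <- calls$amb
  }
  structure(list(disc = disc, amb = amb, orientation = orient,
                 score_frac = frac, score_a = score_a, score_b = score_b,
                 best_gene = ifelse(score_a >= score_b, "A", "B"),
                 id = reads$id,
                 disc_rows = ci$disc_rows, amb_rows = ci$amb_rows),
            class = "site_calls")
}

#' @export
print.site_calls <- function(x, ...) {
  cat(sprintf("<site_calls> %d reads x (%d discriminating + %d ambiguous) sites\n",
              nrow(x$disc), ncol(x$disc), ncol(x$amb)))
  invisible(x)
}

#' Subset site calls by read
#' @param x a `site_calls` object.
#' @param i read index vector.
#' @param ... ignored.
#' @export
`[.site_calls` <- function(x, i, ...) {
  structure(list(disc = x$disc[i, , drop = FALSE],
                 amb = x$amb[i, , drop = FALSE],
                 orientation = x$orientation[i], score_frac = x$score_frac[i],
                 score_a = x$score_a[i], score_b = x$score_b[i],
                 best_gene = x$best_gene[i], id = x$id[i],
                 disc_rows = x$disc_rows, amb_rows = x$amb_rows),
            class = "site_calls")
}
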