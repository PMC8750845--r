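#' Construct a paralog gene pair
#'
#' Container for the two paralog genomic sequences that define the coordinate
#' frame of the whole analysis (gene A is the default reference paralog, e.g.
#' CYP11B1; gene B its highly similar partner, e.g. CYP11B2).
#'
#' @param name_a,name_b sequence identifiers.
#' @param seq_a,seq_b DNA strings; lowercase is accepted and uppercased.
#' @param origin_a,origin_b optional genomic origin strings
#'   (e.g. "chr8:142876120-142879816"), carried into reports.
#' @return an object of class `gene_pair`.
#' @export
gene_pair <- function(name_a, seq_a, name_b, seq_b,
                      origin_a = NULL, origin_b = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (nm in c("a", "b")) {
    s <- if (nm == "a") seq_a else seq_b
    id <- if (nm == "a") name_a else name_b
    if (!nzchar(s)) stop("empty sequence for record '", id, "'")
    if (grepl("[^ACGTN]", s))
      stop("non-nucleotide characters in record '", id, "'")
    n_n <- nchar(gsub("[^N]", "", s))
    if (n_n > 0L)
      warning(sprintf("record '%s' contains %d N bases", id, n_n))
  }
  structure(list(name_a = name_a, name_b = name_b,
                 seq_a = seq_a, seq_b = seq_b,
                 origin_a = origin_a, origin_b = origin_b),
            class = "gene_pair")
}

#' @export
print.gene_pair <- function(x, ...) {
  cat(sprintf("<gene_pair> A: %s (%d bp)  B: %s (%d bp)\n",
              x$name_a, nchar(x$seq_a), x$name_b, nchar(x$seq_b)))
  invisible(x)
}

#' Load the paralog pair from a FASTA file
#'
#' Reads the two paralog genomic sequences. By default the first two records
#' are used as gene A and gene B; alternatively name the records to use.
#'
#' @param fasta path to a FASTA file with at least two records.
#' @param names optional character vector of two record names selecting and
#'   ordering gene A and gene B.
#' @return a [gene_pair()].
#' @export
load_reference_pair <- function(fasta, names = NULL) {
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(fasta),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-nucleotide characters in FASTA '", fasta, "'")
    })
  if (length(seqs) < 2L)
    stop("need two sequences: FASTA '", fasta, "' has ", length(seqs),
         " record(s)")
  ids <- sub("\\s.*$", "", names(seqs))
  if (!is.null(names)) {
    stopifnot(length(names) == 2L)
    miss <- setdiff(names, ids)
    if (length(miss))
      stop("record(s) not found in FASTA: ", paste(miss, collapse = ", "))
    seqs <- seqs[match(names, ids)]
    ids <- names
  } else {
    seqs <- seqs[1:2]
    ids <- ids[1:2]
  }
  gene_pair(ids[1], as.character(seqs[[1]]), ids[2], as.character(seqs[[2]]))
}

#' Align the two paralogs into a common column frame
#'
#' One local (Smith-Waterman) alignment of the full gene-A sequence against
#' the full gene-B sequence. For a genuinely homologous pair this covers
#' nearly all of both sequences and provides the alignment-column frame in
#' which informative sites are defined.
#'
#' @param pair a [gene_pair()].
#' @param params [align_params()].
#' @param min_coverage minimum fraction of each sequence that must fall inside
#'   the aligned span; below this the pair is rejected as non-homologous.
#' @return an object of class `pair_alignment`: the `ct_alignment` plus the
#'   pair, per-gene coverage and the identity fraction over non-gap columns.
#' @export
align_gene_pair <- function(pair, params = align_params(),
                            min_coverage = 0.5) {
  stopifnot(inherits(pair, "gene_pair"))
  aln <- local_align(pair$seq_a, pair$seq_b, params)
  if (aln$score <= 0L) stop("sequences do not appear homologous")
  cov_a <- (aln$q_end - aln$q_start + 1L) / nchar(pair$seq_a)
  cov_b <- (aln$t_end - aln$t_start + 1L) / nchar(pair$seq_b)
  if (cov_a < min_coverage || cov_b < min_coverage)
    stop(sprintf(
      "sequences do not appear homologous (aligned coverage %.2f / %.2f)",
      cov_a, cov_b))
  both <- aln$qpos > 0L & aln$tpos > 0L
  a_chr <- strsplit(pair$seq_a, "", fixed = TRUE)[[1]]
  b_chr <- strsplit(pair$seq_b, "", fixed = TRUE)[[1]]
  ident <- mean(a_chr[aln$qpos[both]] == b_chr[aln$tpos[both]])
  structure(list(pair = pair, score = aln$score,
                 q_start = aln$q_start, q_end = aln$q_end,
                 t_start = aln$t_start, t_end = aln$t_end,
                 qpos = aln$qpos, tpos = aln$tpos,
                 coverage_a = cov_a, coverage_b = cov_b,
                 identity = ident, params = params),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf(
    "<pair_alignment> %s vs %s: %d columns, identity %.3f, coverage %.2f/%.2f\n",
    x$pair$name_a, x$pair$name_b, length(x$qpos), x$identity,
    x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Classify alignment columns into discriminating and ambiguous sites
#'
#' Every aligned column is classified: columns where the two paralogs carry
#' different bases, and columns where exactly one paralog is gapped, are
#' *discriminating* (they reveal which paralog a read segment came from);
#' columns where the paralogs agree are *ambiguous* (mismatches there gauge
#' the sequencing/PCR error floor). Columns touching an `N` base are treated
#' as ambiguous, never discriminating.
#'
#' With `count_gap_runs = TRUE` (default) consecutive gap columns belonging
#' to one indel are collapsed into a single discriminating site for the gene
#' that carries bases there, so an indel counts once rather than once per
#' base; set `FALSE` to count per column. The rule used is recorded in the
#' catalog.
#'
#' @param aln a [align_gene_pair()] result.
#' @param count_gap_runs collapse each single-sided gap run into one site?
#' @return an object of class `site_catalog`: a data frame of sites (`column`,
#'   `kind`, `base_a`, `base_b`, `pos_a`, `pos_b`, `anchor_a`, `anchor_b`,
#'   `run_length`) plus counts `n_discriminating_a`, `n_discriminating_b`,
#'   `n_ambiguous`. `pos_*` are 1-based positions in each gene's own
#'   coordinates (`NA` where the gene is gapped); `anchor_*` always give a
#'   usable coordinate in that gene (for gapped sites, the last aligned
#'   position before the run).
#' @export
extract_informative_sites <- function(aln, count_gap_runs = TRUE) {
  stopifnot(inherits(aln, "pair_alignment"))
  a_chr <- strsplit(aln$pair$seq_a, "", fixed = TRUE)[[1]]
  b_chr <- strsplit(aln$pair$seq_b, "", fixed = TRUE)[[1]]
  qp <- aln$qpos; tp <- aln$tpos
  ncol <- length(qp)
  base_a <- ifelse(qp > 0L, a_chr[pmax(qp, 1L)], "-")
  base_b <- ifelse(tp > 0L, b_chr[pmax(tp, 1L)], "-")
  has_n <- base_a == "N" | base_b == "N"
  gap_in_a <- qp == 0L
  gap_in_b <- tp == 0L
  disc <- (base_a != base_b) & !has_n
  # group id: 0 for non-gap columns; gap runs of the same side share an id
  grp <- integer(ncol)
  run_id <- 0L
  i <- 1L
  while (i <= ncol) {
    if (disc[i] && (gap_in_a[i] || gap_in_b[i])) {
      side <- gap_in_a[i]
      j <- i
      while (j < ncol && disc[j + 1L] &&
             (if (side) gap_in_a[j + 1L] else gap_in_b[j + 1L]) &&
             !(if (side) gap_in_b[j + 1L] else gap_in_a[j + 1L])) j <- j + 1L
      run_id <- run_id + 1L
      grp[i:j] <- run_id
      i <- j + 1L
    } else i <- i + 1L
  }
  # anchors: last seen position in each gene (0 before the first)
  anchor_a <- cummax(qp)
  anchor_b <- cummax(tp)

  plain <- if (count_gap_runs) which(grp == 0L) else seq_len(ncol)
  sites <- data.frame(
    column = plain,
    kind = ifelse(disc[plain], "discriminating", "ambiguous"),
    base_a = base_a[plain], base_b = base_b[plain],
    pos_a = ifelse(qp[plain] > 0L, qp[plain], NA_integer_),
    pos_b = ifelse(tp[plain] > 0L, tp[plain], NA_integer_),
    anchor_a = pmax(anchor_a[plain], 1L),
    anchor_b = pmax(anchor_b[plain], 1L),
    run_length = 1L,
    stringsAsFactors = FALSE)
  if (count_gap_runs && run_id > 0L) {
    run_rows <- lapply(split(which(grp > 0L), grp[grp > 0L]), function(run) {
      in_a <- !gap_in_a[run[1]]  # TRUE: bases live in gene A (gap in B)
      data.frame(
        column = run[1],
        kind = "discriminating",
        base_a = if (in_a) paste(base_a[run], collapse = "") else "-",
        base_b = if (in_a) "-" else paste(base_b[run], collapse = ""),
        pos_a = if (in_a) qp[run[1]] else NA_integer_,
        pos_b = if (in_a) NA_integer_ else tp[run[1]],
        anchor_a = max(anchor_a[run[1]], 1L),
        anchor_b = max(anchor_b[run[1]], 1L),
        run_length = length(run),
        stringsAsFactors = FALSE)
    })
    sites <- rbind(sites, do.call(rbind, run_rows))
  }
  sites <- sites[order(sites$column), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(
    sites = sites, pair = aln$pair, params = aln$params,
    gap_run_counting = count_gap_runs,
    n_discriminating_a = sum(sites$kind == "discriminating" & !is.na(sites$pos_a)),
    n_discriminating_b = sum(sites$kind == "discriminating" & !is.na(sites$pos_b)),
    n_ambiguous = sum(sites$kind == "ambiguous"),
    n_masked = 0L),
    class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf(
    "<site_catalog> %s/%s: %d/%d discriminating (A/B), %d ambiguous, %d masked\n",
    x$pair$name_a, x$pair$name_b, x$n_discriminating_a, x$n_discriminating_b,
    x$n_ambiguous, x$n_masked))
  invisible(x)
}

#' Mask ambiguous sites at known polymorphic positions
#'
#' Ambiguous sites overlapping known polymorphisms (a dbSNP subset restricted
#' to the paralog intervals) are excluded from mismatch-rate statistics: a
#' polymorphism at an ambiguous site would inflate the apparent error floor.
#' Discriminating sites are never masked by this rule.
#'
#' @param catalog a [extract_informative_sites()] catalog.
#' @param positions a data frame with columns `gene` (`"A"`/`"B"` or the
#'   record names) and `pos` (1-based position in that gene), or a path to a
#'   two-column TSV of the same.
#' @param dbsnp_build optional free-text build label, recorded in the catalog.
#' @return the catalog with matching ambiguous sites set to `kind = "masked"`
#'   and `n_masked`/`n_ambiguous` updated.
#' @export
mask_polymorphic_sites <- function(catalog, positions, dbsnp_build = NULL) {
  stopifnot(inherits(catalog, "site_catalog"))
  if (is.character(positions) && length(positions) == 1L)
    positions <- utils::read.table(positions, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  if (nrow(positions) == 0L) return(catalog)
  stopifnot(all(c("gene", "pos") %in% names(positions)))
  gene <- positions$gene
  gene[gene == catalog$pair$name_a] <- "A"
  gene[gene == catalog$pair$name_b] <- "B"
  if (!all(gene %in% c("A", "B")))
    stop("unknown gene label(s): ",
         paste(unique(positions$gene[!gene %in% c("A", "B")]), collapse = ", "))
  span <- ifelse(gene == "A", nchar(catalog$pair$seq_a),
                 nchar(catalog$pair$seq_b))
  out_of_span <- positions$pos < 1L | positions$pos > span
  if (any(out_of_span)) {
    warning(sum(out_of_span), " position(s) outside the gene span ignored")
    positions <- positions[!out_of_span, , drop = FALSE]
    gene <- gene[!out_of_span]
  }
  s <- catalog$sites
  hit <- rep(FALSE, nrow(s))
  for (k in seq_along(gene)) {
    if (gene[k] == "A") hit <- hit | (!is.na(s$pos_a) & s$pos_a == positions$pos[k])
    else hit <- hit | (!is.na(s$pos_b) & s$pos_b == positions$pos[k])
  }
  if (any(hit & s$kind == "discriminating"))
    warning(sum(hit & s$kind == "discriminating"),
            " position(s) target discriminating sites; only ambiguous sites",
            " are masked — left unchanged")
  to_mask <- hit & s$kind == "ambiguous"
  s$kind[to_mask] <- "masked"
  catalog$sites <- s
  catalog$n_masked <- sum(s$kind == "masked")
  catalog$n_ambiguous <- sum(s$kind == "ambiguous")
  if (!is.null(dbsnp_build)) catalog$dbsnp_build <- dbsnp_build
  catalog
}

#' Spacing statistics of discriminating sites
#'
#' Distances between consecutive discriminating sites in one gene's own
#' coordinates. Dense spacing is what makes fine crossover localization
#' possible; the largest gap bounds the best-case resolution locally.
#'
#' @param catalog a [site_catalog].
#' @param gene `"A"` or `"B"`: whose coordinates to measure in.
#' @return list with `median_bp`, `min_bp`, `max_bp`, `n` (number of gaps).
#' @export
spacing_stats <- function(catalog, gene = c("A", "B")) {
  gene <- match.arg(gene)
  s <- catalog$sites
  pos <- if (gene == "A") s$pos_a else s$pos_b
  pos <- sort(pos[s$kind == "discriminating" & !is.na(pos)])
  if (length(pos) < 2L)
    stop("need at least two discriminating sites in gene ", gene)
  gaps <- diff(pos)
  list(median_bp = stats::median(gaps), min_bp = min(gaps),
       max_bp = max(gaps), n = length(gaps))
}

#' Load an exon/intron gene model
#'
#' Reads a BED (0-based half-open; converted to 1-based) or GFF3 file of
#' labelled features (e.g. `E1`, `I1`, `E2`, ...) on the reference paralog's
#' own coordinates. Features must be sorted and non-overlapping; BED names or
#' GFF3 `Name`/`ID` attributes supply the labels.
#'
#' @param path BED or GFF3 file.
#' @return an object of class `gene_model`: data frame `features` with
#'   `label`, `start`, `end` (1-based, inclusive).
#' @export
load_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  label <- if (!is.null(df$name)) df$name
           else if (!is.null(df$Name)) df$Name
           else if (!is.null(df$ID)) df$ID
           else stop("gene model features carry no name/label column")
  feats <- data.frame(label = as.character(label),
                      start = df$start, end = df$end,
                      stringsAsFactors = FALSE)
  gene_model(feats)
}

#' @rdname load_gene_model
#' @param features data frame with `label`, `start`, `end` (1-based inclusive).
#' @export
gene_model <- function(features) {
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  if (nrow(features) > 1L &&
      any(features$start[-1] <= features$end[-nrow(features)]))
    stop("gene model features overlap")
  if (nrow(features) > 1L &&
      any(features$start[-1] != features$end[-nrow(features)] + 1L))
    warning("gene model has gaps between consecutive features")
  structure(list(features = features), class = "gene_model")
}

#' Label an interval with the gene-model features it overlaps
#'
#' The label is `"<first overlapped feature>-<last overlapped feature>"`
#' (e.g. an interval running from exon 2 into intron 2 gives `"E2-I2"`); an
#' interval inside a single feature gives that feature's label alone.
#'
#' @param model a [gene_model].
#' @param start,end 1-based inclusive interval on the same coordinates.
#' @return a region label, or `"outside-model"` (with a warning) when the
#'   interval does not touch the model span.
#' @export
annotate_interval <- function(model, start, end) {
  stopifnot(inherits(model, "gene_model"), start <= end)
  f <- model$features
  hit <- which(f$end >= start & f$start <= end)
  if (length(hit) == 0L) {
    warning(sprintf("interval %d-%d lies outside the gene model", start, end))
    return("outside-model")
  }
  first <- f$label[hit[1]]
  last <- f$label[hit[length(hit)]]
  if (first == last) first else paste0(first, "-", last)
}

#' Export the site catalog as TSV
#'
#' One row per site: `column`, `kind`, `base_a`, `base_b`, `pos_a`, `pos_b`,
#' `run_length` (positions 1-based; `NA` where the gene is gapped).
#'
#' @param catalog a [site_catalog].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(catalog, path) {
  cols <- c("column", "kind", "base_a", "base_b", "pos_a", "pos_b",
            "run_length")
  utils::write.table(catalog$sites[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
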