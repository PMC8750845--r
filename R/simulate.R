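#' Per-base sequencing error model
#'
#' Independent per-base substitution, insertion and deletion probabilities
#' emulating noisy long reads. Defaults (5% substitution, 2% insertion, 3%
#' deletion) give the ~10% aggregate error typical of the nanopore reads the
#' method was designed for. The model is i.i.d. per base — no
#' homopolymer-aware errors — which is sufficient to exercise the
#' error-exclusion rule and the background statistics.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in [0, 0.3).
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.05, ins_rate = 0.02, del_rate = 0.03) {
  stopifnot(sub_rate >= 0, sub_rate < 0.3, ins_rate >= 0, ins_rate < 0.3,
            del_rate >= 0, del_rate < 0.3)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate),
            class = "error_model")
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

#' Generate a toy paralog pair with known differences
#'
#' Gene A is uniform-random DNA; gene B is a copy carrying independent
#' per-base substitutions (to a different base) at rate `divergence` and
#' short (1-3 bp) insertions/deletions at rate `indel_rate`. The default 6%
#' divergence mirrors the ~94% identity of the CYP11B1/CYP11B2 pair that
#' motivates the method.
#'
#' @param length gene length in bp (>= 500).
#' @param divergence per-base substitution probability in (0, 0.2); 0 allowed
#'   for an identical pair.
#' @param indel_rate per-base indel probability.
#' @param seed RNG seed.
#' @return list with `pair` (a [gene_pair()]) and `truth`, a data frame of
#'   introduced differences (`pos_a`, 1-based position in gene A; `type`
#'   `sub`/`ins`/`del`; `len`).
#' @export
make_toy_gene_pair <- function(length = 4000L, divergence = 0.06,
                               indel_rate = 0.002, seed = 1L) {
  stopifnot(length >= 500L, divergence >= 0, divergence < 0.2,
            indel_rate >= 0, indel_rate < 0.05)
  set.seed(seed)
  a <- sample(.BASES, length, replace = TRUE)
  b <- a
  sub_at <- which(stats::runif(length) < divergence)
  for (p in sub_at) b[p] <- sample(setdiff(.BASES, a[p]), 1L)
  truth <- data.frame(pos_a = sub_at,
                      type = rep("sub", base::length(sub_at)),
                      len = rep(1L, base::length(sub_at)),
                      stringsAsFactors = FALSE)
  indel_at <- which(stats::runif(length) < indel_rate)
  indel_at <- setdiff(indel_at, sub_at)
  # apply indels right-to-left so earlier positions stay valid
  b_list <- as.list(b)
  for (p in rev(indel_at)) {
    len <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {  # insertion in B after position p
      b_list[[p]] <- paste0(b_list[[p]],
                            paste(sample(.BASES, len, replace = TRUE),
                                  collapse = ""))
      truth <- rbind(truth, data.frame(pos_a = p, type = "ins", len = len,
                                       stringsAsFactors = FALSE))
    } else {                      # deletion in B starting at position p
      drop <- p:min(p + len - 1L, length)
      for (q in drop) b_list[[q]] <- ""
      truth <- rbind(truth, data.frame(pos_a = p, type = "del",
                                       len = base::length(drop),
                                       stringsAsFactors = FALSE))
    }
  }
  truth <- truth[order(truth$pos_a), , drop = FALSE]
  rownames(truth) <- NULL
  pair <- gene_pair("toyA", paste(a, collapse = ""),
                    "toyB", paste(unlist(b_list), collapse = ""))
  list(pair = pair, truth = truth)
}

#' Evenly spaced synthetic exon/intron model for a toy gene
#'
#' Alternating exon/intron features (`E1, I1, E2, ...`) covering positions
#' 1..`length`, so crossover intervals on toy genes get the same style of
#' region label (e.g. `"E2-I2"`) as a real gene model would give.
#'
#' @param length gene length in bp.
#' @param n_exons number of exons (introns fill the spaces between them).
#' @return a [gene_model].
#' @export
make_toy_gene_model <- function(length = 4000L, n_exons = 5L) {
  n_feat <- 2L * n_exons - 1L
  bounds <- floor(seq(0L, length, length.out = n_feat + 1L))
  labs <- character(n_feat)
  labs[seq(1L, n_feat, by = 2L)] <- paste0("E", seq_len(n_exons))
  labs[seq(2L, n_feat, by = 2L)] <- paste0("I", seq_len(n_exons - 1L))
  gene_model(data.frame(label = labs, start = bounds[-length(bounds)] + 1L,
                        end = bounds[-1L], stringsAsFactors = FALSE))
}

#' Build a chimeric amplicon template
#'
#' The 5' part of gene A up to crossover position `c` joined to the aligned
#' 3' part of gene B: `template = A[1..c] + B[(c'+1)..end]`, where `c'` is
#' the gene-B position aligned to gene-A position `c`. If `c` falls in an
#' alignment gap it is snapped to the nearest aligned column (recorded in the
#' result).
#'
#' @param pair a [gene_pair()].
#' @param crossover_a crossover position, 1-based in gene-A coordinates.
#' @param aln optional precomputed [align_gene_pair()] result.
#' @return list with `template` (DNA string), `crossover_a` (after any
#'   snapping), `crossover_b` (the aligned gene-B position), `snapped`.
#' @export
make_chimera <- function(pair, crossover_a, aln = NULL) {
  if (is.null(aln)) aln <- align_gene_pair(pair)
  stopifnot(crossover_a >= 1L, crossover_a <= nchar(pair$seq_a))
  both <- aln$qpos > 0L & aln$tpos > 0L
  qa <- aln$qpos[both]; tb <- aln$tpos[both]
  k <- which(qa == crossover_a)
  snapped <- FALSE
  if (length(k) == 0L) {  # crossover falls in a gap column: snap
    k <- which.min(abs(qa - crossover_a))
    snapped <- TRUE
  }
  c_a <- qa[k[1]]; c_b <- tb[k[1]]
  template <- paste0(substr(pair$seq_a, 1L, c_a),
                     substr(pair$seq_b, c_b + 1L, nchar(pair$seq_b)))
  list(template = template, crossover_a = c_a, crossover_b = c_b,
       snapped = snapped)
}

# apply the error model to one sequence (character vector of bases in, string out)
.mutate_read <- function(bases, em) {
  n <- length(bases)
  u_del <- stats::runif(n) < em$del_rate
  u_sub <- stats::runif(n) < em$sub_rate
  u_ins <- stats::runif(n) < em$ins_rate
  out <- bases
  for (p in which(u_sub & !u_del))
    out[p] <- sample(setdiff(.BASES, bases[p]), 1L)
  ins_at <- which(u_ins)
  ins_bases <- if (length(ins_at)) sample(.BASES, length(ins_at),
                                          replace = TRUE) else character(0)
  out[ins_at] <- paste0(out[ins_at], ins_bases)
  out[u_del & !u_ins] <- ""
  out[u_del & u_ins] <- substring(out[u_del & u_ins],
                                  nchar(out[u_del & u_ins]),
                                  nchar(out[u_del & u_ins]))
  paste(out, collapse = "")
}

#' Simulate noisy amplicon reads from a template
#'
#' Every on-target read spans the whole template (single long-range PCR
#' product) with i.i.d. per-base errors; a fraction is reverse-complemented
#' and a fraction replaced by uniform-random off-target sequences of similar
#' length. Fixed seed gives fully reproducible reads (and byte-identical
#' FASTQ via [write_fastq()]).
#'
#' @param template DNA string.
#' @param n_reads number of reads.
#' @param error an [error_model()].
#' @param rc_fraction fraction of reads reverse-complemented.
#' @param off_target_fraction fraction replaced by random sequences.
#' @param seed RNG seed.
#' @return list with `reads` (a [read_set()]) and `truth` (class
#'   `sim_truth`): the simulation parameters plus per-read `is_off_target`
#'   and `is_rc` flags.
#' @export
simulate_reads <- function(template, n_reads = 200L, error = error_model(),
                           rc_fraction = 0.5, off_target_fraction = 0,
                           seed = 1L) {
  stopifnot(rc_fraction >= 0, rc_fraction <= 1,
            off_target_fraction >= 0, off_target_fraction <= 1)
  set.seed(seed)
  tmpl <- strsplit(template, "", fixed = TRUE)[[1]]
  is_off <- stats::runif(n_reads) < off_target_fraction
  is_rc <- stats::runif(n_reads) < rc_fraction
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    seqs[i] <- if (is_off[i]) .random_seq(length(tmpl)) else
      .mutate_read(tmpl, error)
  }
  seqs[is_rc] <- ct_revcomp(seqs[is_rc])
  reads <- read_set(sprintf("read_%04d", seq_len(n_reads)), seqs)
  truth <- structure(list(n_reads = n_reads, error = error,
                          rc_fraction = rc_fraction,
                          off_target_fraction = off_target_fraction,
                          seed = seed, template_length = length(tmpl),
                          is_off_target = is_off, is_rc = is_rc),
                     class = "sim_truth")
  list(reads = reads, truth = truth)
}

#' Simulate a complete call-ready sample
#'
#' Convenience wrapper chaining [make_toy_gene_pair()],
#' [make_toy_gene_model()], [make_chimera()] and [simulate_reads()]: one call
#' yields the paralog pair, gene model, chimeric (or pure-paralog) template,
#' noisy reads and the full ground truth.
#'
#' @param length toy gene length.
#' @param divergence,indel_rate pair parameters ([make_toy_gene_pair()]).
#' @param crossover_a crossover position in gene-A coordinates; the default
#'   (`NULL`) places it mid-intron-2 of the toy model. Use `type = "pure_b"`
#'   or `"pure_a"` for non-chimeric templates (negative controls).
#' @param type template type: chimera, pure gene B, or pure gene A.
#' @param n_reads,error,rc_fraction,off_target_fraction read parameters
#'   ([simulate_reads()]).
#' @param seed RNG seed; pair, template and reads all derive from it.
#' @return list with `pair`, `model`, `catalog_truth` (pair differences),
#'   `template`, `crossover_a`, `crossover_b`, `reads`, `truth`.
#' @export
simulate_sample <- function(length = 4000L, divergence = 0.06,
                            indel_rate = 0.002, crossover_a = NULL,
                            type = c("chimera", "pure_b", "pure_a"),
                            n_reads = 200L, error = error_model(),
                            rc_fraction = 0.5, off_target_fraction = 0,
                            seed = 1L) {
  type <- match.arg(type)
  tp <- make_toy_gene_pair(length, divergence, indel_rate, seed = seed)
  model <- make_toy_gene_model(length)
  if (type == "chimera") {
    if (is.null(crossover_a)) {
      i2 <- model$features[model$features$label == "I2", ]
      crossover_a <- as.integer((i2$start + i2$end) %/% 2L)
    }
    ch <- make_chimera(tp$pair, crossover_a)
    template <- ch$template
    c_a <- ch$crossover_a; c_b <- ch$crossover_b
  } else {
    template <- if (type == "pure_b") tp$pair$seq_b else tp$pair$seq_a
    c_a <- NA_integer_; c_b <- NA_integer_
  }
  sim <- simulate_reads(template, n_reads, error, rc_fraction,
                        off_target_fraction, seed = seed + 1L)
  list(pair = tp$pair, model = model, catalog_truth = tp$truth,
       template = template, type = type,
       crossover_a = c_a, crossover_b = c_b,
       reads = sim$reads, truth = sim$truth)
}
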