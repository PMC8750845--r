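# Hand-built catalogs and call matrices for unit-testing the profile and
# caller layers without running any alignment.

# substitution-type discriminating sites at disc_pos, ambiguous at amb_pos
synth_catalog <- function(disc_pos, amb_pos) {
  pos <- sort(c(disc_pos, amb_pos))
  is_d <- pos %in% disc_pos
  sites <- data.frame(
    column = seq_along(pos), kind = ifelse(is_d, "discriminating", "ambiguous"),
    base_a = ifelse(is_d, "A", "G"), base_b = ifelse(is_d, "C", "G"),
    pos_a = pos, pos_b = pos, anchor_a = pos, anchor_b = pos,
    run_length = 1L, stringsAsFactors = FALSE)
  structure(list(sites = sites,
                 pair = gene_pair("synthA", strrep("A", max(pos) + 10L),
                                  "synthB", strrep("A", max(pos) + 10L)),
                 gap_run_counting = TRUE,
                 n_discriminating_a = sum(is_d), n_discriminating_b = sum(is_d),
                 n_ambiguous = sum(!is_d), n_masked = 0L),
            class = "site_catalog")
}

# wrap bare call matrices (reads x sites) as a site_calls object
synth_calls <- function(catalog, disc, amb) {
  s <- catalog$sites
  n <- nrow(disc)
  structure(list(disc = disc, amb = amb,
                 orientation = rep("+", n), score_frac = rep(1, n),
                 score_a = rep(0L, n), score_b = rep(0L, n),
                 best_gene = rep("A", n), id = sprintf("synth_%d", seq_len(n)),
                 disc_rows = which(s$kind == "discriminating"),
                 amb_rows = which(s$kind == "ambiguous")),
            class = "site_calls")
}

# profile data frame for testing the fit and the fusion decision directly
synth_profile <- function(disc_pos, disc_rate, amb_pos = integer(0),
                          amb_rate = numeric(0), n = 100L,
                          reference_gene = "A") {
  prof <- rbind(
    data.frame(site = seq_along(disc_pos), position = disc_pos,
               kind = "discriminating", n = n,
               m = round(disc_rate * n), rate = disc_rate,
               used = TRUE, stringsAsFactors = FALSE),
    if (length(amb_pos))
      data.frame(site = length(disc_pos) + seq_along(amb_pos),
                 position = amb_pos, kind = "ambiguous", n = n,
                 m = round(amb_rate * n), rate = amb_rate, used = TRUE,
                 stringsAsFactors = FALSE))
  prof <- prof[order(prof$position), , drop = FALSE]
  structure(prof, class = c("mismatch_profile", "data.frame"),
            reference_gene = reference_gene, min_site_coverage = 5L,
            n_reads = n)
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
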