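test_that("FASTA loading validates and normalizes the paralog pair", {
  fa <- write_temp_fasta(c(geneA = "acgtACGTacgt", geneB = "ACGTACGTACGA"))
  pair <- load_reference_pair(fa)
  expect_s3_class(pair, "gene_pair")
  expect_equal(pair$seq_a, "ACGTACGTACGT")  # lowercase accepted, uppercased
  expect_equal(pair$name_b, "geneB")

  one <- write_temp_fasta(c(only = "ACGT"))
  expect_error(load_reference_pair(one), "need two sequences")

  bad <- write_temp_fasta(c(a = "ACGT", b = "ACXT"))
  expect_error(load_reference_pair(bad), "non-nucleotide")

  named <- load_reference_pair(fa, names = c("geneB", "geneA"))
  expect_equal(named$name_a, "geneB")
})

test_that("pair alignment covers homologous pairs and rejects unrelated ones", {
  set.seed(21)
  a <- random_dna(1500)
  pair <- gene_pair("A", a, "B", mutate_dna(a, 0.06))
  aln <- align_gene_pair(pair)
  expect_gte(aln$coverage_a, 0.95)
  expect_gte(aln$coverage_b, 0.95)
  expect_gt(aln$identity, 0.9)
  # every base appears in at most one column, in order
  qp <- aln$qpos[aln$qpos > 0]
  expect_identical(qp, sort(unique(qp)))

  unrelated <- gene_pair("A", random_dna(1000), "B", random_dna(1000))
  expect_error(align_gene_pair(unrelated), "homologous")
})

test_that("identical sequences give zero discriminating sites", {
  s <- random_dna(800)
  aln <- align_gene_pair(gene_pair("A", s, "B", s))
  catalog <- extract_informative_sites(aln)
  expect_equal(catalog$n_discriminating_a, 0L)
  expect_equal(catalog$n_discriminating_b, 0L)
  expect_equal(catalog$n_ambiguous, nchar(s))
})

test_that("a single-sided indel is one discriminating site for one gene", {
  # gene B carries one extra base: a gap-in-A column
  a <- paste0(random_dna(60), "AAAA", random_dna(60))
  b <- sub("AAAA", "AATAA", a, fixed = TRUE)
  aln <- align_gene_pair(gene_pair("A", a, "B", b))
  catalog <- extract_informative_sites(aln)
  oracle <- sw_oracle(a, b)  # confirm the alignment really has one gap column
  expect_equal(sum(oracle$qpos == 0), 1L)
  expect_equal(catalog$n_discriminating_b, 1L)
  expect_equal(catalog$n_discriminating_a, 0L)
  site <- catalog$sites[catalog$sites$kind == "discriminating", ]
  expect_equal(site$base_a, "-")
  expect_equal(site$run_length, 1L)
})

test_that("gap-run collapsing counts an indel once, per-column counts its length", {
  a <- paste0(random_dna(50), "GGGGG", random_dna(50))
  b <- sub("GGGGG", "GG", a, fixed = TRUE)  # 3 bp deletion in B
  aln <- align_gene_pair(gene_pair("A", a, "B", b))
  runs <- extract_informative_sites(aln, count_gap_runs = TRUE)
  cols <- extract_informative_sites(aln, count_gap_runs = FALSE)
  expect_equal(runs$n_discriminating_a, 1L)
  expect_equal(cols$n_discriminating_a, 3L)
  expect_equal(runs$sites$run_length[runs$sites$kind == "discriminating"], 3L)
})

test_that("per-column classification partitions the aligned columns", {
  set.seed(31)
  for (seed in 1:3) {
    tp <- make_toy_gene_pair(900, 0.05, 0.004, seed = seed)
    aln <- align_gene_pair(tp$pair)
    catalog <- extract_informative_sites(aln, count_gap_runs = FALSE)
    expect_equal(catalog$n_ambiguous +
                   sum(catalog$sites$kind == "discriminating"),
                 length(aln$qpos))
  }
})

test_that("swapping gene A and gene B swaps the per-gene counts", {
  tp <- make_toy_gene_pair(1200, 0.06, 0.003, seed = 5)
  p <- tp$pair
  swapped <- gene_pair(p$name_b, p$seq_b, p$name_a, p$seq_a)
  c1 <- extract_informative_sites(align_gene_pair(p))
  c2 <- extract_informative_sites(align_gene_pair(swapped))
  expect_equal(c1$n_discriminating_a, c2$n_discriminating_b)
  expect_equal(c1$n_discriminating_b, c2$n_discriminating_a)
  expect_equal(c1$n_ambiguous, c2$n_ambiguous)
})

test_that("masking hits only ambiguous sites and is monotone", {
  tp <- make_toy_gene_pair(800, 0.05, 0, seed = 9)
  catalog <- extract_informative_sites(align_gene_pair(tp$pair))
  s <- catalog$sites
  amb_pos <- s$pos_a[s$kind == "ambiguous"][1:5]
  disc_pos <- s$pos_a[s$kind == "discriminating"][1]

  masked <- mask_polymorphic_sites(
    catalog, data.frame(gene = "A", pos = amb_pos))
  expect_equal(masked$n_masked, 5L)
  expect_equal(masked$n_ambiguous, catalog$n_ambiguous - 5L)
  expect_equal(masked$n_discriminating_a, catalog$n_discriminating_a)

  expect_warning(
    m2 <- mask_polymorphic_sites(catalog,
                                 data.frame(gene = "A", pos = disc_pos)),
    "discriminating")
  expect_equal(m2$sites, catalog$sites)

  expect_warning(
    m3 <- mask_polymorphic_sites(catalog,
                                 data.frame(gene = "A", pos = 10^6)),
    "outside")
  expect_equal(m3$n_masked, 0L)

  # empty set: identity
  m4 <- mask_polymorphic_sites(catalog, data.frame(gene = character(0),
                                                   pos = integer(0)))
  expect_identical(m4$sites, catalog$sites)
})

test_that("spacing statistics are gaps between consecutive sites", {
  catalog <- synth_catalog(c(10L, 21L, 32L), c(5L, 40L))
  sp <- spacing_stats(catalog, "A")
  expect_equal(sp$median_bp, 11)
  expect_equal(sp$min_bp, 11L)
  expect_equal(sp$max_bp, 11L)

  sp2 <- spacing_stats(synth_catalog(c(5L, 6L), integer(0)), "A")
  expect_equal(unlist(sp2[c("median_bp", "min_bp", "max_bp")]),
               c(median_bp = 1, min_bp = 1, max_bp = 1))

  expect_error(spacing_stats(synth_catalog(10L, 20L), "A"), "two")
})

test_that("gene models load from BED and label intervals", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open; E2 covers 1-based 101..200, I2 201..400
  writeLines(c("geneA\t100\t200\tE2", "geneA\t200\t400\tI2"), bed)
  model <- load_gene_model(bed)
  expect_equal(model$features$start, c(101L, 201L))
  expect_equal(annotate_interval(model, 151, 250), "E2-I2")
  expect_equal(annotate_interval(model, 211, 220), "I2")
  expect_warning(lab <- annotate_interval(model, 901, 950), "outside")
  expect_equal(lab, "outside-model")
})

test_that("the site catalog exports as TSV", {
  tp <- make_toy_gene_pair(600, 0.05, 0, seed = 2)
  catalog <- extract_informative_sites(align_gene_pair(tp$pair))
  path <- tempfile(fileext = ".tsv")
  write_site_catalog(catalog, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(catalog$sites))
  expect_true(all(c("column", "kind", "base_a", "pos_b") %in% names(back)))
})
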