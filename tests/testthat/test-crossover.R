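test_that("profiles count informative observations per the exclusion rule", {
  catalog <- synth_catalog(disc_pos = c(100L, 200L), amb_pos = c(150L, 250L))
  # 10 reads; discriminating site 1: 9 matches_A + 1 matches_neither;
  # site 2: 4 matches_A, 6 matches_B; ambiguous site 1: 2 mismatches of 10;
  # site 2: one uncovered read
  disc <- cbind(c(rep(1L, 9), 0L), c(rep(1L, 4), rep(2L, 6)))
  amb <- cbind(c(rep(TRUE, 2), rep(FALSE, 8)), c(rep(FALSE, 9), NA))
  prof <- build_mismatch_profile(synth_calls(catalog, disc, amb), catalog)
  d <- prof[prof$kind == "discriminating", ]
  a <- prof[prof$kind == "ambiguous", ]
  expect_equal(d$n, c(9L, 10L))   # matches_neither excluded from coverage
  expect_equal(d$rate, c(0, 0.6))
  expect_equal(a$n, c(10L, 9L))
  expect_equal(a$rate, c(0.2, 0))

  # relative to gene B the discriminating rates flip
  prof_b <- build_mismatch_profile(synth_calls(catalog, disc, amb), catalog,
                                   reference_gene = "B")
  expect_equal(prof_b$rate[prof_b$kind == "discriminating"], 1 - d$rate)
})

test_that("perfect gene-A reads give an all-zero profile", {
  catalog <- synth_catalog(c(50L, 150L), c(100L, 120L))
  disc <- matrix(1L, 20, 2)
  amb <- matrix(FALSE, 20, 2)
  prof <- build_mismatch_profile(synth_calls(catalog, disc, amb), catalog)
  expect_true(all(prof$rate == 0))
  expect_true(all(prof$used))
})

test_that("masked sites are excluded and empty coverage errors", {
  catalog <- synth_catalog(c(50L, 150L), c(100L, 120L))
  catalog$sites$kind[catalog$sites$pos_a == 100L] <- "masked"
  calls <- synth_calls(catalog, matrix(1L, 10, 2),
                       matrix(FALSE, 10, 1))
  prof <- build_mismatch_profile(calls, catalog)
  expect_false(any(prof$position == 100L))
  expect_equal(sum(prof$kind == "ambiguous"), 1L)

  empty <- synth_calls(synth_catalog(10L, 20L),
                       matrix(NA_integer_, 3, 1), matrix(NA, 3, 1))
  expect_error(build_mismatch_profile(empty, synth_catalog(10L, 20L)),
               "no informative coverage")
})

test_that("background is the type-7 99th percentile of ambiguous rates", {
  # all-zero rates
  p0 <- synth_profile(c(1, 2, 3, 4), rep(0, 4), amb_pos = 11:20,
                      amb_rate = rep(0, 10))
  expect_equal(background_level(p0), 0)
  # singleton
  p1 <- synth_profile(c(1, 2, 3, 4), rep(0, 4), amb_pos = 30,
                      amb_rate = 0.05)
  expect_equal(background_level(p1), 0.05)
  # the 0.00..0.99 grid: frozen value from the sort-and-interpolate oracle
  rates <- seq(0, 0.99, by = 0.01)
  p2 <- synth_profile(c(1, 2, 3, 4), rep(0, 4),
                      amb_pos = 200 + seq_along(rates), amb_rate = rates)
  expect_equal(background_level(p2), 0.9801)
  expect_equal(pctl_oracle(rates, 0.99), 0.9801)
  # no covered ambiguous sites
  p3 <- synth_profile(c(1, 2, 3, 4), rep(0, 4))
  expect_error(background_level(p3), "ambiguous")
})

test_that("background matches the oracle on random rate vectors", {
  set.seed(77)
  for (k in 1:25) {
    rates <- round(runif(sample(3:60, 1)), 3)
    prof <- synth_profile(c(1, 2, 3, 4), rep(0, 4),
                          amb_pos = 100 + seq_along(rates), amb_rate = rates)
    expect_equal(background_level(prof), pctl_oracle(rates, 0.99))
  }
})

test_that("background is non-decreasing in any ambiguous rate", {
  set.seed(78)
  rates <- runif(30, 0, 0.2)
  prof <- synth_profile(c(1, 2), c(0, 0), amb_pos = 100 + 1:30,
                        amb_rate = rates)
  b0 <- background_level(prof)
  for (k in c(1, 15, 30)) {
    r2 <- rates; r2[k] <- r2[k] + 0.3
    p2 <- synth_profile(c(1, 2), c(0, 0), amb_pos = 100 + 1:30,
                        amb_rate = r2)
    expect_gte(background_level(p2), b0)
  }
})

test_that("foreground is the exact mean of above-background rates", {
  p <- synth_profile(1:4, c(0, 0, 1, 1))
  expect_equal(foreground_level(p, 0.02), 1.0)
  p2 <- synth_profile(1:2, c(0.5, 0.9))
  expect_equal(foreground_level(p2, 0.1), 0.7)
  p3 <- synth_profile(1:4, c(0.01, 0.02, 0.01, 0))
  expect_true(is.na(foreground_level(p3, 0.05)))
  # direct-computation check on random data
  set.seed(9)
  r <- runif(40)
  p4 <- synth_profile(seq_along(r), r)
  b <- 0.4
  expect_equal(foreground_level(p4, b), mean(r[r > b]))
})

test_that("the sigmoid fit localizes a noiseless step and flags flat data", {
  pos <- seq(10, 500, by = 10)
  y <- ifelse(pos <= 250, 0, 1)
  fit <- fit_crossover_sigmoid(synth_profile(pos, y))
  expect_true(fit$converged)
  expect_gte(fit$inflection, 250)
  expect_lte(fit$inflection, 260)
  expect_lt(abs(fit$asym_left - 0), 0.05)
  expect_lt(abs(fit$asym_right - 1), 0.05)

  flat <- fit_crossover_sigmoid(synth_profile(pos, rep(0, length(pos))))
  expect_true(flat$degenerate)
  expect_lt(flat$amplitude, 0.3)

  few <- fit_crossover_sigmoid(synth_profile(1:3, c(0, 1, 1)))
  expect_false(few$converged)
})

test_that("the fitted inflection recovers a noisy step within 2x site spacing", {
  pos <- seq(10, 500, by = 10)
  truth <- 255
  err <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed)
    y <- ifelse(pos < truth, 0, 1) + rnorm(length(pos), 0, 0.05)
    fit <- fit_crossover_sigmoid(synth_profile(pos, y))
    expect_true(fit$converged)
    err[seed] <- abs(fit$inflection - truth)
  }
  expect_lte(median(err), 2 * 10)
})

test_that("fusion is called on a clean step and refused on degenerate shapes", {
  model <- gene_model(data.frame(label = c("E2", "I2"),
                                 start = c(1L, 251L), end = c(250L, 600L)))
  pos <- seq(10, 500, by = 10)
  amb <- synth_profile(pos, ifelse(pos <= 250, 0.01, 0.97),
                       amb_pos = pos + 1, amb_rate = rep(0.01, length(pos)))
  b <- background_level(amb)
  f <- foreground_level(amb, b)
  fit <- fit_crossover_sigmoid(amb)
  call <- call_fusion(amb, fit, b, f, model)
  expect_equal(call$status, "fused")
  expect_equal(unname(call$crossover_interval), c(250, 260))
  expect_equal(call$region_label, "E2-I2")

  # all rates near zero (a pure reference-matching sample): no fusion
  flat0 <- synth_profile(pos, rep(0.01, length(pos)),
                         amb_pos = pos + 1, amb_rate = rep(0.01, length(pos)))
  b0 <- background_level(flat0)
  c0 <- call_fusion(flat0, fit_crossover_sigmoid(flat0), b0,
                    foreground_level(flat0, b0), model)
  expect_equal(c0$status, "no_fusion")
  expect_null(c0$crossover_interval)
  expect_equal(c0$region_label, "No fusion observed")

  # flat intermediate noise: refused by the plateau rule
  set.seed(12)
  noisy <- synth_profile(pos, runif(length(pos), 0.45, 0.55),
                         amb_pos = pos + 1, amb_rate = rep(0.01, length(pos)))
  bn <- background_level(noisy)
  cn <- call_fusion(noisy, fit_crossover_sigmoid(noisy), bn,
                    foreground_level(noisy, bn), model)
  expect_equal(cn$status, "no_fusion")
})

test_that("a fused call survives the label swap to the other reference", {
  catalog <- synth_catalog(disc_pos = seq(20L, 400L, by = 20L),
                           amb_pos = seq(21L, 401L, by = 20L))
  nd <- catalog$n_discriminating_a
  disc <- t(replicate(50, ifelse(seq_len(nd) <= nd / 2, 1L, 2L)))
  amb <- matrix(FALSE, 50, catalog$n_ambiguous)
  calls <- synth_calls(catalog, disc, amb)
  res_a <- chimeratrace:::.call_from_calls(calls, catalog)
  res_b <- chimeratrace:::.call_from_calls(calls, catalog,
                                           reference_gene = "B")
  expect_equal(res_a$call$status, "fused")
  expect_equal(res_b$call$status, "fused")
  expect_equal(unname(res_a$call$crossover_interval),
               unname(res_b$call$crossover_interval))
  d_a <- res_a$profile[res_a$profile$kind == "discriminating", "rate"]
  d_b <- res_b$profile[res_b$profile$kind == "discriminating", "rate"]
  expect_equal(d_a, 1 - d_b)
})

test_that("noiseless chimeric input always brackets the true breakpoint", {
  for (seed in 1:3) {
    tp <- make_toy_gene_pair(1500, 0.06, 0.002, seed = seed)
    aln <- align_gene_pair(tp$pair)
    catalog <- extract_informative_sites(aln)
    truth <- 600L + 37L * seed
    ch <- make_chimera(tp$pair, truth, aln)
    reads <- read_set(paste0("r", 1:20), rep(ch$template, 20))
    calls <- genotype_reads(reads, tp$pair, catalog)
    res <- chimeratrace:::.call_from_calls(calls, catalog)
    expect_equal(res$call$status, "fused")
    iv <- res$call$crossover_interval
    expect_lte(iv["left"], ch$crossover_a)
    expect_gte(iv["right"], ch$crossover_a)
  }
})

test_that("pure-paralog reads never produce a fusion call", {
  for (seed in 1:3) {
    tp <- make_toy_gene_pair(1200, 0.06, 0.002, seed = seed + 40)
    catalog <- extract_informative_sites(align_gene_pair(tp$pair))
    reads <- read_set(paste0("r", 1:20), rep(tp$pair$seq_b, 20))
    calls <- genotype_reads(reads, tp$pair, catalog)
    res <- chimeratrace:::.call_from_calls(calls, catalog)
    expect_equal(res$call$status, "no_fusion")
  }
})

test_that("subsampling at full depth is concordant by construction", {
  catalog <- synth_catalog(disc_pos = seq(20L, 400L, by = 20L),
                           amb_pos = seq(21L, 401L, by = 20L))
  nd <- catalog$n_discriminating_a
  disc <- t(replicate(60, ifelse(seq_len(nd) <= nd / 2, 1L, 2L)))
  amb <- matrix(FALSE, 60, catalog$n_ambiguous)
  calls <- synth_calls(catalog, disc, amb)
  expect_warning(
    tab <- subsample_stability(calls, catalog, depths = c(30L, 60L, 500L),
                               replicates = 4L, seed = 2L),
    "exceed")
  conc <- attr(tab, "concordance")
  expect_equal(conc$concordance[conc$depth == 60L], 1.0)
  expect_false(500L %in% conc$depth)
  expect_equal(nrow(tab), 8L)
})
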