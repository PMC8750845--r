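#' Aggregate per-read site calls into a mismatch-rate profile
#'
#' For each catalog site relative to the chosen reference paralog:
#' at a discriminating site only reads matching gene A or gene B exactly are
#' informative — observations matching neither are treated as sequencing/PCR
#' errors and excluded from both numerator and denominator; the mismatch
#' count is the number of reads matching the *other* paralog. At an ambiguous
#' site every covered non-gap observation counts, and a mismatch is any read
#' base differing from the shared reference base. Masked sites are excluded
#' entirely.
#'
#' @param calls a [genotype_reads()] result.
#' @param catalog the matching [extract_informative_sites()] catalog.
#' @param reference_gene `"A"` or `"B"`: whose coordinates and identity the
#'   profile is expressed against.
#' @param min_site_coverage sites with fewer informative observations than
#'   this are kept in the table but flagged `used = FALSE` and excluded from
#'   background/foreground statistics and the sigmoid fit; rate estimates
#'   from one or two reads are too unstable to use.
#' @return object of class `mismatch_profile`: data frame with `site`
#'   (catalog row), `position` (reference-gene coordinate; gapped sites are
#'   anchored at the last aligned reference base), `kind`, `n`, `m`, `rate`,
#'   `used`; attributes record the reference gene and coverage threshold.
#' @export
build_mismatch_profile <- function(calls, catalog, reference_gene = "A",
                                   min_site_coverage = 5L) {
  stopifnot(inherits(calls, "site_calls"), reference_gene %in% c("A", "B"))
  s <- catalog$sites
  m_a <- colSums(calls$disc == 1L, na.rm = TRUE)
  m_b <- colSums(calls$disc == 2L, na.rm = TRUE)
  n_d <- m_a + m_b
  m_d <- if (reference_gene == "A") m_b else m_a
  n_amb <- colSums(!is.na(calls$amb))
  m_amb <- colSums(calls$amb, na.rm = TRUE)
  pos <- if (reference_gene == "A") s$anchor_a else s$anchor_b
  prof <- rbind(
    data.frame(site = calls$disc_rows, position = pos[calls$disc_rows],
               kind = "discriminating", n = n_d, m = m_d,
               stringsAsFactors = FALSE),
    data.frame(site = calls$amb_rows, position = pos[calls$amb_rows],
               kind = "ambiguous", n = n_amb, m = m_amb,
               stringsAsFactors = FALSE))
  prof <- prof[order(prof$position, prof$site), , drop = FALSE]
  rownames(prof) <- NULL
  prof$rate <- ifelse(prof$n > 0L, prof$m / prof$n, NA_real_)
  prof$used <- prof$n >= min_site_coverage
  if (all(prof$n == 0L)) stop("no informative coverage")
  structure(prof, class = c("mismatch_profile", "data.frame"),
            reference_gene = reference_gene,
            min_site_coverage = as.integer(min_site_coverage),
            n_reads = nrow(calls$disc))
}

#' Background noise level
#'
#' The 99th percentile of the mismatch rates of the (used) ambiguous sites —
#' paralogs agree at these positions, so any mismatch there is sequencing or
#' PCR error, and the upper tail of their rates bounds the error floor.
#' Percentile convention: linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param profile a [build_mismatch_profile()] result.
#' @return the background level `b`.
#' @export
background_level <- function(profile) {
  x <- profile$rate[profile$kind == "ambiguous" & profile$used]
  if (length(x) == 0L) stop("no covered ambiguous sites")
  unname(stats::quantile(x, 0.99, type = 7, names = FALSE))
}

#' Foreground signal level
#'
#' Mean mismatch rate of the discriminating sites whose rate exceeds the
#' background — the plateau level of the paralog-B-matching segment. Absent
#' (`NA`) when no discriminating site rises above background, which is
#' itself evidence against a fusion.
#'
#' @param profile a [build_mismatch_profile()] result.
#' @param b background level from [background_level()].
#' @return the foreground level `f`, or `NA_real_`.
#' @export
foreground_level <- function(profile, b) {
  x <- profile$rate[profile$kind == "discriminating" & profile$used]
  x <- x[x > b]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' Fit a four-parameter logistic to the discriminating-site rates
#'
#' Least-squares fit of `y(x) = c + (d - c) / (1 + exp(s * (x - e)))` to the
#' (position, rate) points of the used discriminating sites: `d` is the
#' left-hand asymptote, `c` the right-hand one, `s` the slope and `e` the
#' inflection — the crossover-site estimate. Starting values come from the
#' plateau means and the midline crossing; optimizer failure is reported as
#' `converged = FALSE`, never as an error.
#'
#' @param profile a [build_mismatch_profile()] result.
#' @param min_sites minimum number of usable discriminating sites (the model
#'   has four free parameters).
#' @return object of class `sigmoid_fit`: `asym_left` (d), `asym_right` (c),
#'   `slope` (s), `inflection` (e), `amplitude`, `converged`, `degenerate`,
#'   `residual_sd`, `n_sites`, `span`.
#' @export
fit_crossover_sigmoid <- function(profile, min_sites = 4L) {
  d <- profile[profile$kind == "discriminating" & profile$used, , drop = FALSE]
  out <- structure(list(asym_left = NA_real_, asym_right = NA_real_,
                        slope = NA_real_, inflection = NA_real_,
                        amplitude = NA_real_, converged = FALSE,
                        degenerate = FALSE, residual_sd = NA_real_,
                        n_sites = nrow(d), span = range(d$position)),
                   class = "sigmoid_fit")
  if (nrow(d) < min_sites) return(out)
  o <- order(d$position)
  x <- d$position[o]; y <- d$rate[o]
  if (diff(range(y)) < 1e-9) {  # constant profile: flat degenerate "fit"
    out$asym_left <- out$asym_right <- mean(y)
    out$amplitude <- 0
    out$slope <- 0
    out$converged <- TRUE
    out$degenerate <- TRUE
    out$residual_sd <- 0
    return(out)
  }
  k <- max(3L, nrow(d) %/% 5L)
  y_left <- mean(utils::head(y, k)); y_right <- mean(utils::tail(y, k))
  mid <- (y_left + y_right) / 2
  cross <- if (y_right > y_left) which(y > mid) else which(y < mid)
  e0 <- if (length(cross)) x[cross[1]] else stats::median(x)
  s0 <- if (y_right > y_left) 0.05 else -0.05
  # with s > 0, y -> c as x -> +Inf and y -> d as x -> -Inf.
  # Levenberg-Marquardt on the raw residuals: a hard step drives the slope
  # towards infinity, where the Jacobian degenerates, so the optimizer is
  # used directly rather than through a model-object wrapper.
  resid_fn <- function(p) y - (p[1] + (p[2] - p[1]) /
                                 (1 + exp(pmin(700, p[3] * (x - p[4])))))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(cc = y_right, dd = y_left, ss = s0, e0c = e0),
                       fn = resid_fn,
                       # |slope| <= 20/bp is already a step sharper than any
                       # site spacing; the bound keeps the optimizer out of
                       # the flat slope->infinity valley of hard steps
                       lower = c(-0.5, -0.5, -20, min(x) - diff(range(x))),
                       upper = c(1.5, 1.5, 20, max(x) + diff(range(x))),
                       # 1e-6 relative tolerances: far below the sampling
                       # noise of per-site rates, and they stop the optimizer
                       # from polishing forever along the near-flat valley
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, maxfev = 5000,
                         ftol = 1e-6, ptol = 1e-6)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(out)
  p <- fit$par
  if (!all(is.finite(p))) return(out)
  # (cc, dd, ss, e) and (dd, cc, -ss, e) are the same curve; canonicalize to
  # a positive slope so asym_left is always the plateau at small x
  if (p["ss"] < 0) {
    tmp <- p["cc"]; p["cc"] <- p["dd"]; p["dd"] <- tmp
    p["ss"] <- -p["ss"]
  }
  out$asym_right <- unname(p["cc"])
  out$asym_left <- unname(p["dd"])
  out$slope <- unname(p["ss"])
  out$inflection <- unname(p["e0c"])
  out$amplitude <- abs(out$asym_left - out$asym_right)
  out$residual_sd <- sqrt(mean(fit$fvec^2))
  out$converged <- TRUE
  out$degenerate <- out$amplitude < 1e-6
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<sigmoid_fit> converged: asymptotes %.3f -> %.3f, inflection %.1f, slope %.3g (%d sites)\n",
      x$asym_left, x$asym_right, x$inflection, x$slope, x$n_sites))
  else cat("<sigmoid_fit> not converged\n")
  invisible(x)
}

#' Decide fused vs no-fusion and localize the crossover interval
#'
#' A sample is called `fused` only when all three hold: (i) the foreground is
#' defined and separated from background by at least `min_separation`;
#' (ii) the sigmoid fit converged with amplitude at least `min_amplitude` and
#' inflection inside the profile span; (iii) each plateau holds at least
#' `min_plateau_sites` discriminating sites on its own side of the midline
#' `(b + f) / 2`. The crossover interval is then bracketed by the last
#' pre-step site and the first post-step site around the inflection, and
#' labelled against the gene model. These thresholds quantify what a "clear
#' fusion pattern" means; they are this package's own operational definition
#' of a judgement the original diagnostic workflow made by eye, and all are
#' configurable.
#'
#' @param profile a [build_mismatch_profile()] result.
#' @param fit a [fit_crossover_sigmoid()] result.
#' @param b,f background and foreground levels.
#' @param model optional [gene_model] for the region label.
#' @param min_separation minimum `f - b`.
#' @param min_amplitude minimum sigmoid amplitude `|d - c|`.
#' @param min_plateau_sites minimum discriminating sites per plateau.
#' @return object of class `fusion_call`: `status` (`"fused"`/`"no_fusion"`),
#'   `crossover_interval` (named left/right positions, or NULL),
#'   `region_label`, `background`, `foreground`, `fit`, `thresholds`.
#' @export
call_fusion <- function(profile, fit, b, f, model = NULL,
                        min_separation = 0.30, min_amplitude = 0.30,
                        min_plateau_sites = 3L) {
  d <- profile[profile$kind == "discriminating" & profile$used, , drop = FALSE]
  d <- d[order(d$position), , drop = FALSE]
  thresholds <- list(min_separation = min_separation,
                     min_amplitude = min_amplitude,
                     min_plateau_sites = min_plateau_sites)
  no_fusion <- structure(
    list(status = "no_fusion", crossover_interval = NULL,
         region_label = "No fusion observed", background = b, foreground = f,
         fit = fit, thresholds = thresholds,
         reference_gene = attr(profile, "reference_gene")),
    class = "fusion_call")
  if (is.na(f) || (f - b) < min_separation) return(no_fusion)
  if (!fit$converged || fit$degenerate || fit$amplitude < min_amplitude)
    return(no_fusion)
  e <- fit$inflection
  if (is.na(e) || e < min(d$position) || e > max(d$position))
    return(no_fusion)
  midline <- (b + f) / 2
  rising <- fit$asym_right > fit$asym_left
  if (rising) {
    left_ok <- d$position < e & d$rate < midline
    right_ok <- d$position > e & d$rate > midline
  } else {
    left_ok <- d$position < e & d$rate > midline
    right_ok <- d$position > e & d$rate < midline
  }
  if (sum(left_ok) < min_plateau_sites || sum(right_ok) < min_plateau_sites)
    return(no_fusion)
  left <- max(d$position[left_ok])
  right <- min(d$position[right_ok])
  interval <- c(left = left, right = right)
  label <- if (!is.null(model))
    annotate_interval(model, min(interval), max(interval))
  else NA_character_
  structure(list(status = "fused", crossover_interval = interval,
                 region_label = label, background = b, foreground = f,
                 fit = fit, thresholds = thresholds,
                 reference_gene = attr(profile, "reference_gene")),
            class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  if (x$status == "fused")
    cat(sprintf(
      "<fusion_call> fused: crossover %d-%d (%s); background %.4f, foreground %.3f\n",
      x$crossover_interval["left"], x$crossover_interval["right"],
      x$region_label, x$background, x$foreground))
  else
    cat(sprintf("<fusion_call> no fusion observed (background %.4f)\n",
                x$background))
  invisible(x)
}

# profile -> call, used by the pipeline and by subsampling
.call_from_calls <- function(calls, catalog, model = NULL,
                             reference_gene = "A", min_site_coverage = 5L,
                             min_separation = 0.30, min_amplitude = 0.30,
                             min_plateau_sites = 3L) {
  profile <- build_mismatch_profile(calls, catalog, reference_gene,
                                    min_site_coverage)
  b <- background_level(profile)
  f <- foreground_level(profile, b)
  fit <- fit_crossover_sigmoid(profile)
  call <- call_fusion(profile, fit, b, f, model,
                      min_separation, min_amplitude, min_plateau_sites)
  list(profile = profile, background = b, foreground = f, fit = fit,
       call = call)
}

#' Fusion-call stability under read subsampling
#'
#' Re-runs the caller on random subsamples of the genotyped reads and
#' reports, per depth, how often the subsampled call (status + region label)
#' agrees with the full-depth call. This estimates the minimum sequencing
#' depth at which the call is stable.
#'
#' Genotyping is per read, so subsampling operates on the already-genotyped
#' site calls; each subsample re-runs the entire downstream caller (profile,
#' background/foreground, sigmoid fit, fusion decision).
#'
#' @param calls a [genotype_reads()] result for the full read set.
#' @param catalog the matching catalog.
#' @param depths read depths to test (sampling without replacement).
#' @param replicates subsamples per depth.
#' @param seed RNG seed.
#' @param model optional [gene_model] for labels.
#' @param ... thresholds passed through to the caller
#'   (see [call_fusion()] and [build_mismatch_profile()]).
#' @return data frame (`depth`, `replicate`, `status`, `label`,
#'   `concordant`) with the full-depth call in attribute `full_call` and the
#'   per-depth concordance in attribute `concordance`.
#' @export
subsample_stability <- function(calls, catalog,
                                depths = c(100L, 200L, 500L, 1000L, 2000L,
                                           3000L),
                                replicates = 10L, seed = 1L, model = NULL,
                                ...) {
  n <- nrow(calls$disc)
  full <- .call_from_calls(calls, catalog, model, ...)$call
  key <- function(cl) paste(cl$status, cl$region_label)
  full_key <- key(full)
  keep <- depths <= n
  if (any(!keep))
    warning("depth(s) ", paste(depths[!keep], collapse = ", "),
            " exceed the ", n, " available reads; skipped")
  depths <- depths[keep]
  rows <- list()
  set.seed(seed)
  for (dep in depths) {
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, dep)
      sub <- tryCatch(.call_from_calls(calls[idx], catalog, model, ...)$call,
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = dep, replicate = r,
        status = if (is.null(sub)) "error" else sub$status,
        label = if (is.null(sub)) NA_character_ else sub$region_label,
        concordant = !is.null(sub) && key(sub) == full_key,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  conc <- tapply(out$concordant, out$depth, mean)
  structure(out, full_call = full,
            concordance = data.frame(depth = as.integer(names(conc)),
                                     concordance = as.numeric(conc)))
}
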