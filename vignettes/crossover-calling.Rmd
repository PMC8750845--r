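---
title: "Localizing chimeric-gene crossovers from long-read amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing chimeric-gene crossovers from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unequal crossing-over between two highly similar paralogous genes produces a
chimeric gene: the 5′ part of one paralog joined to the 3′ part of the
other. The flagship example is the CYP11B1/CYP11B2 hybrid that causes
glucocorticoid-remediable aldosteronism (GRA), a heritable form of
hypertension: the two genes sit ~40 kb apart on chromosome 8q and are about
94% identical across the crossover-prone region, which makes both
paralog-specific PCR and short-read mapping unreliable. Long-range PCR of
the hybrid locus followed by nanopore sequencing yields reads that span the
whole amplicon, but at a per-base error rate comparable to the paralog
divergence itself. This package turns those noisy reads into a
crossover call with an exon/intron-resolution interval.

## The method

**Site catalog.** The two paralog sequences are aligned once with an
affine-gap Smith–Waterman alignment, giving a common column frame. Every
aligned column is classified:

* *discriminating* — the paralogs differ (substitution, or a single-sided
  gap): the read base at such a site tells which paralog that segment of
  the read came from;
* *ambiguous* — the paralogs agree: a mismatch there can only be a
  sequencing/PCR error (or a polymorphism), so these sites estimate the
  error floor.

Consecutive gap columns of one indel are collapsed into a single
discriminating site per gap run (`count_gap_runs = TRUE`), so a 3 bp indel
counts once rather than three times; the per-column variant is available and
the rule used is recorded in the catalog. Sites at known polymorphic
positions (a dbSNP subset restricted to the locus) can be masked —
masking applies only to ambiguous sites, because a polymorphism there would
inflate the apparent error floor, while discriminating sites are
definitional and stay.

**Per-read genotyping.** Each QC-passing read is aligned to both paralogs
(both orientations; the better combined score wins, forward preferred on an
exact tie) and its base at every catalog site is read off the alignment to
the site's *host* paralog — sites with a base in gene A off the A-alignment,
gap-in-A sites off the B-alignment — so indel-type sites are well defined.
At a discriminating site the observation is coded *matches A* / *matches B*
/ *matches neither*; "neither" observations are treated as sequencing or PCR
errors and excluded from both numerator and denominator of the site's rate.
This exclusion rule is what makes the profile robust to the high raw error
rate: errors at discriminating sites rarely imitate the other paralog's
base, so they are simply discarded instead of diluting the signal.

**Profile and decision statistics.** Per site, relative to the reference
paralog (gene A by default), the mismatch rate is $r_i = m_i / n_i$. The
*background* $b$ is the 99th percentile of ambiguous-site rates; the
*foreground* $f$ is the mean of discriminating-site rates above $b$. In a
fused sample the discriminating rates form a step: ~0 where reads match the
reference paralog, ~1 beyond the crossover. The step is localized by
least-squares fitting of a four-parameter logistic
$y(x) = c + (d - c) / (1 + e^{s (x - e)})$ whose inflection $e$ estimates
the crossover site.

**The fusion decision.** The original diagnostic workflow judged fusion
plots visually; this package replaces that judgement with three explicit,
configurable criteria, all of which must hold for a `fused` call:

1. separation: $f$ defined and $f - b \ge$ `min_separation` (default 0.30);
2. step shape: the 4PL fit converged, with amplitude $|d - c| \ge$
   `min_amplitude` (default 0.30) and inflection inside the profile span;
3. plateaus: at least `min_plateau_sites` (default 3) discriminating sites
   on the correct side of the midline $(b+f)/2$ in each plateau.

The crossover interval is bracketed by the last pre-step and the first
post-step discriminating site around the inflection, and labelled by the
exon/intron features it overlaps (e.g. `"E2-I2"`). Anything failing the
criteria is reported as `no_fusion` — deliberately conservative, mirroring
the use of negative controls to rule out false-positive fusions.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| match / mismatch | +2 / −3 | score | DNA local-alignment scores; the published analysis does not state its scoring, so conventional defaults are used and the catalog is checked for stability under perturbation |
| gap open / extend | 5 / 2 | cost | affine gaps; a gap of length $L$ costs $5 + 2L$ |
| `min_len` / `max_len` | 3000 / 5000 | bp | amplicon length window (inclusive); scale for toy genes |
| `min_score_frac` | 0.4 | fraction | on-target threshold as a fraction of the perfect score; real locus reads score ≳0.7, random sequence ≪0.4 |
| `band_width` | 300 | bp | alignment band half-width for read genotyping; covers indel drift (~1% net over 4 kb) and modest trimming with a wide margin; 0 = exact |
| `min_site_coverage` | 5 | reads | sites with fewer informative observations are excluded from $b$, $f$ and the fit |
| `min_separation`, `min_amplitude` | 0.30 | rate | both far below the ~0.9 separation of clean fused samples and far above background fluctuation |
| `min_plateau_sites` | 3 | sites | protects against a sigmoid fitted through noise with no real plateaus |
| `recommended_depth` | 200 | reads | depth from which calls are stable; lower inputs run with a warning |

Coordinates are 1-based and inclusive throughout, the R/Bioconductor
convention; BED input is converted on load.

## The simulator

`simulate_sample()` generates the full study design: gene A is uniform
random DNA (default 4 kb), gene B a copy at 6% substitution divergence
(matching the ~94% identity of the motivating pair) plus sparse 1–3 bp
indels (rate 0.002/bp); the chimeric template joins A and B at an
alignment-mapped crossover (default mid-intron-2 of an evenly tiled
synthetic exon/intron model); reads span the whole template with i.i.d.
per-base errors (defaults 5% substitution, 2% insertion, 3% deletion —
nanopore-like in aggregate), half reverse-complemented, optionally mixed
with random off-target reads. Everything is deterministic under a seed,
down to the FASTQ bytes.

What the simulator does *not* emulate: homopolymer-dependent and otherwise
correlated errors, quality-value information, chimeric PCR artefacts,
coverage bias, and heterozygous carriers (a real GRA sample also yields
reads from the two intact genes; the amplicon design enriches the hybrid,
and pure-paralog read sets are simulated separately as negative controls).
Passing tests therefore demonstrate correctness of the statistical machinery
under the stated error model, not performance on every pathology of real
MinION data.

## Numerical choices

* **Percentile convention** for the background: linear interpolation between
  order statistics (`stats::quantile` type 7), recorded in the run config.
* **4PL fitting**: Levenberg–Marquardt on the raw residuals
  (`minpack.lm::nls.lm`). Initial values: plateau means of the first and
  last fifth of sites, inflection at the midline crossing, slope sign from
  the step direction. A perfect step drives the slope to infinity where the
  Jacobian degenerates, so the slope is bounded at |s| ≤ 20/bp (already an
  instant step at any real site spacing) and relative tolerances are 1e-6,
  far below the sampling noise of per-site rates. The parameter pair
  $(c, d, s)$ and $(d, c, -s)$ describe the same curve; fits are
  canonicalized to positive slope so the left/right asymptotes are
  well-defined. Optimizer failure is reported as `converged = FALSE`, which
  the caller treats as evidence against fusion — never as an exception.
* **Constant profiles** short-circuit to a degenerate flat fit rather than
  exercising the optimizer on a rank-deficient problem.
* **Tie-breaking** in the aligner is fully deterministic (diagonal > up >
  left; gap opening preferred over extension on exact ties; first maximal
  cell in row-major order), so exact-output tests and byte-identical reruns
  are possible. The banded mode only skips computation; with the band
  disabled the implementation agrees exactly with an independently written
  quadratic DP oracle, and the default band is validated against the full
  dynamic program on simulated reads.
* **Orientation selection** in batch genotyping uses the gene-A score pair
  (three alignments per read) rather than the four-alignment total-score
  rule of `genotype_read()`; with paralogs at 94% identity the two rules
  only disagree on reads that fail QC anyway, and the batch rule is a third
  faster.

## Design decisions

* The upstream consensus-correction and whole-genome-mapping steps of the
  original pipeline are replaced by an optional pre-corrected-read hook
  (`external_corrected_input()`, provenance-flagged) and an internal
  alignment-score on-target filter. This removes external tool dependencies
  while preserving the contract that on-target reads are those aligning to
  the locus pair.
* The paralog pair is aligned as two full sequences in one local alignment
  and must cover ≥95% of both for the flagship-style use; a single coherent
  column frame keeps every downstream coordinate well-defined.
* The published site counts for the flagship pair (180/188 discriminating
  bases) depend on unstated alignment parameters; they are treated as
  calibration anchors — reproduced exactly under at least one documented
  configuration and to within ±5% across a parameter grid — not as
  definitional constants.
* Whether the published spacing statistics were computed on gene-A
  positions, gene-B positions or alignment columns is unstated;
  `spacing_stats()` exposes the gene choice as an argument.
* Subsampling for depth-robustness operates on per-read genotype calls:
  genotyping is strictly per-read, so re-aggregating a subsample is
  mathematically identical to re-running the pipeline on the subsampled
  FASTQ, at a fraction of the cost. Every subsample re-runs the entire
  downstream caller.

## Problem sizes used in the test-suite simulations

Simulated checks run at the study's own conditions: 4 kb pairs, 200 reads
per sample for recovery (20 seeds) and specificity (20 seeds), one
3000-read sample subsampled at depths 100–3000 with 10 replicates. Smaller
(1–2 kb, 20–60 read) instances are used for unit-level checks where the
property under test does not depend on scale.

## Known limitations

* One crossover per molecule: the model is a single 5′A→3′B junction. Double
  crossovers (gene-conversion tracts) would appear as a
  rise-and-fall profile that the sigmoid cannot represent; such samples end
  up `no_fusion` and need visual review of the fusion plot.
* Calls are per-sample; carrier mixtures (hybrid + intact alleles in one
  read set) dilute the step towards intermediate rates and are not modelled.
* No variant calling at the locus — the profile deliberately discards
  read-specific variation at discriminating sites as error.
* The fusion thresholds are operational definitions chosen for clean
  separation of step-vs-flat extremes; pathological intermediate profiles
  (e.g. a genuine fusion at the very edge of the amplicon, where one plateau
  has <3 sites) are conservatively reported as `no_fusion`.

## A worked example

```{r, eval = FALSE}
library(chimeratrace)

sim <- simulate_sample(n_reads = 200, seed = 11)  # truth: crossover at 1555
res <- run_sample(sim$reads, sim$pair, sim$model)
res$call
#> <fusion_call> fused: crossover 1539-1560 (I2); background 0.1151,
#>     foreground 0.928
render_fusion_plot(res$profile, res$call, "fusion.png",
                   sample_id = "simulated GRA-like sample")
```

The interval 1539–1560 brackets the true breakpoint (1555) and the label
matches the intron the simulator placed it in.
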