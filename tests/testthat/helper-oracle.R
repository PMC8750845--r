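# Independent oracles used to validate the package's numerical core.
#
# sw_oracle: quadratic-space affine-gap Smith-Waterman in plain R, written
# directly from the recurrences. Tie-breaking mirrors the documented
# contract (diagonal > up > left; gap matrices prefer opening over extending
# on exact ties; best cell = first maximum in row-major order), so score AND
# traceback must agree exactly with the package aligner.

sw_oracle <- function(query, target, params = align_params()) {
  code <- function(s) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    ifelse(is.na(v), 5L, v)
  }
  q <- code(query); t <- code(target)
  m <- length(q); n <- length(t)
  go <- params$gap_open; ge <- params$gap_extend
  NEG <- -268435456L
  H <- matrix(0L, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  org <- matrix(0L, m + 1, n + 1)   # 0 stop, 1 diag, 2 up, 3 left
  e_ext <- matrix(FALSE, m + 1, n + 1)
  f_ext <- matrix(FALSE, m + 1, n + 1)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in 1:m) {
    for (j in 1:n) {
      eo <- H[i + 1, j] - go - ge; ee <- E[i + 1, j] - ge
      if (eo >= ee) E[i + 1, j + 1] <- eo
      else { E[i + 1, j + 1] <- ee; e_ext[i + 1, j + 1] <- TRUE }
      fo <- H[i, j + 1] - go - ge; fe <- F[i, j + 1] - ge
      if (fo >= fe) F[i + 1, j + 1] <- fo
      else { F[i + 1, j + 1] <- fe; f_ext[i + 1, j + 1] <- TRUE }
      s <- if (q[i] == t[j] && q[i] <= 4L) params$match else params$mismatch
      h <- H[i, j] + s; o <- 1L
      if (F[i + 1, j + 1] > h) { h <- F[i + 1, j + 1]; o <- 2L }
      if (E[i + 1, j + 1] > h) { h <- E[i + 1, j + 1]; o <- 3L }
      if (h <= 0L) { h <- 0L; o <- 0L }
      H[i + 1, j + 1] <- h; org[i + 1, j + 1] <- o
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best == 0L)
    return(list(score = 0L, qpos = integer(0), tpos = integer(0)))
  qpos <- integer(0); tpos <- integer(0)
  i <- bi; j <- bj; state <- 0L
  while (i > 0L && j > 0L) {
    if (state == 0L) {
      o <- org[i + 1, j + 1]
      if (o == 0L) break
      if (o == 1L) { qpos <- c(i, qpos); tpos <- c(j, tpos); i <- i - 1L; j <- j - 1L }
      else if (o == 2L) state <- 2L
      else state <- 1L
    } else if (state == 1L) {   # gap in query, consume target
      qpos <- c(0L, qpos); tpos <- c(j, tpos)
      if (!e_ext[i + 1, j + 1]) state <- 0L
      j <- j - 1L
    } else {                    # gap in target, consume query
      qpos <- c(i, qpos); tpos <- c(0L, tpos)
      if (!f_ext[i + 1, j + 1]) state <- 0L
      i <- i - 1L
    }
  }
  list(score = best, qpos = qpos, tpos = tpos)
}

# percentile by sort-and-linear-interpolation between order statistics
pctl_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# mutate a sequence at a given per-base substitution rate
mutate_dna <- function(s, rate) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(b)) < rate)
  for (p in idx) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}
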