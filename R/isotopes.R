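# Isotope-pattern simulation by convolution of per-element distributions,
# and a similarity score for comparing an observed envelope to theory.

# Convolve two (mass, prob) distributions, merging peaks within bin_width.
.convolve_dist <- function(a, b, bin_width) {
  mz <- outer(a$mass, b$mass, "+")
  p <- outer(a$prob, b$prob, "*")
  .bin_dist(list(mass = as.vector(mz), prob = as.vector(p)), bin_width)
}

# Merge peaks closer than bin_width (greedy left-to-right on sorted masses),
# using the probability-weighted mean mass of each bin.
.bin_dist <- function(d, bin_width) {
  o <- order(d$mass)
  m <- d$mass[o]; p <- d$prob[o]
  grp <- cumsum(c(TRUE, diff(m) > bin_width))
  mass <- tapply(m * p, grp, sum) / tapply(p, grp, sum)
  prob <- tapply(p, grp, sum)
  list(mass = as.numeric(mass), prob = as.numeric(prob))
}

# Distribution of n atoms of one element (exponentiation by squaring).
.element_dist <- function(element, n, bin_width, floor_prob = 1e-12) {
  iso <- .ISOTOPES[[element]]
  acc <- list(mass = 0, prob = 1)
  base <- list(mass = iso$mass, prob = iso$abundance)
  while (n > 0) {
    if (n %% 2 == 1) {
      acc <- .convolve_dist(acc, base, bin_width)
      acc <- .prune_dist(acc, floor_prob)
    }
    n <- n %/% 2
    if (n > 0) {
      base <- .convolve_dist(base, base, bin_width)
      base <- .prune_dist(base, floor_prob)
    }
  }
  acc
}

.prune_dist <- function(d, floor_prob) {
  keep <- d$prob >= floor_prob
  if (all(keep)) return(d)
  list(mass = d$mass[keep], prob = d$prob[keep])
}

#' Simulate the isotope pattern of a formula
#'
#' Convolves the pinned per-element isotope distributions, merges peaks
#' within `bin_width`, removes peaks below `prune` times the base peak, and
#' normalises the base peak to relative abundance 1.
#'
#' @param formula an `elemental_formula`, named count vector, or string.
#' @param bin_width peak-merging width in Da (default 0.01).
#' @param prune relative-abundance floor as a fraction of the base peak
#'   (default 1e-4); `prune = 1` keeps only the base peak.
#' @return An `isotope_pattern`: data.frame with columns `mz` (ascending)
#'   and `rel_abundance` (base peak = 1).
#' @examples
#' isotope_pattern("C21H30O2")
#' @export
isotope_pattern <- function(formula, bin_width = 0.01, prune = 1e-4) {
  stopifnot(bin_width > 0, prune >= 0)
  f <- as_formula_counts(formula)
  d <- list(mass = 0, prob = 1)
  for (e in names(f)) {
    d <- .convolve_dist(d, .element_dist(e, as.integer(f[[e]]), bin_width),
                        bin_width)
  }
  d <- .bin_dist(d, bin_width)
  rel <- d$prob / max(d$prob)
  keep <- rel >= prune
  out <- data.frame(mz = d$mass[keep], rel_abundance = rel[keep])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"))
}

# Un-normalised total probability mass of a formula's isotope distribution
# (used to verify the convolution conserves probability).
isotope_total_probability <- function(formula, bin_width = 0.01) {
  f <- as_formula_counts(formula)
  d <- list(mass = 0, prob = 1)
  for (e in names(f)) {
    d <- .convolve_dist(d, .element_dist(e, as.integer(f[[e]]), bin_width, 0),
                        bin_width)
  }
  sum(d$prob)
}

#' Similarity of an observed and a theoretical isotope pattern
#'
#' Peaks are matched greedily by nearest m/z within `tol`; unmatched peaks
#' on either side contribute zero to the other vector. The score is the
#' abundance-weighted Jaccard (Ruzicka) similarity
#' \eqn{\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)} over the union of
#' matched and unmatched peaks: 1 for identical patterns, decreasing with
#' abundance deviation, penalising missing or extra peaks, and symmetric.
#'
#' @param observed,theoretical `isotope_pattern` objects (or data.frames
#'   with columns `mz`, `rel_abundance`).
#' @param tol m/z matching tolerance in Da (default 0.01).
#' @return Similarity in `[0, 1]`.
#' @export
isotope_similarity <- function(observed, theoretical, tol = 0.01) {
  stopifnot(nrow(observed) > 0, nrow(theoretical) > 0)
  pairs <- .match_peaks(observed$mz, theoretical$mz, tol)
  a <- c(observed$rel_abundance[pairs$i],
         observed$rel_abundance[setdiff(seq_len(nrow(observed)), pairs$i)],
         rep(0, nrow(theoretical) - length(pairs$j)))
  b <- c(theoretical$rel_abundance[pairs$j],
         rep(0, nrow(observed) - length(pairs$i)),
         theoretical$rel_abundance[setdiff(seq_len(nrow(theoretical)),
                                           pairs$j)])
  sum(pmin(a, b)) / sum(pmax(a, b))
}

# Greedy one-to-one nearest matching of two sorted-ish m/z lists within tol.
# Candidate pairs are taken in order of increasing |delta mz|.
.match_peaks <- function(mz_a, mz_b, tol) {
  d <- abs(outer(mz_a, mz_b, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!length(cand)) return(list(i = integer(), j = integer()))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  ii <- jj <- integer()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    ii <- c(ii, i); jj <- c(jj, j)
  }
  list(i = ii, j = jj)
}
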