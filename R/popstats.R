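#' Overlapping analysis windows
#'
#' The window width is `L / (N / 50)` bp -- wider windows for smaller
#' populations, so each window captures comparable polymorphism -- and the
#' step is half the width, so every interior site falls in exactly two
#' windows. The last window may be truncated at `L`.
#'
#' @param L Locus length in bp.
#' @param N Population size used to scale the width.
#' @param width Window width in bp; overrides the `N`-based default.
#' @return A `window_spec`: data frame of `start`, `end`, `mid` plus the
#'   `width`/`step` attributes.
#' @export
window_spec <- function(L, N = NULL, width = NULL) {
  if (is.null(width)) {
    if (is.null(N)) stop("supply either `N` or `width`")
    width <- L / (N / 50)
  }
  step <- width / 2
  starts <- seq(0, L - step, by = step)
  ends <- pmin(starts + width, L)
  structure(
    data.frame(start = starts, end = ends, mid = (starts + ends) / 2),
    width = width, step = step, L = L, class = c("window_spec", "data.frame"))
}

# rows of a hap_matrix belonging to a population selector
pop_rows <- function(m, pop) {
  if (is.numeric(pop)) return(as.integer(pop))
  switch(match.arg(pop, c("sel", "neu", "all")),
         sel = seq_len(m$n1),
         neu = if (m$n2 > 0) m$n1 + seq_len(m$n2) else
           stop("matrix has no second (neutral) population"),
         all = seq_len(m$n1 + m$n2))
}

# windowed sums of a per-site quantity via cumulative sums over the sorted
# position vector
window_sums <- function(values, positions, windows) {
  cs <- c(0, cumsum(values))
  i1 <- findInterval(windows$start, positions, left.open = TRUE)
  i2 <- findInterval(windows$end, positions, left.open = TRUE)
  cs[i2 + 1L] - cs[i1 + 1L]
}

per_site_pi <- function(mat, rows) {
  m <- length(rows)
  if (m < 2) stop("need at least 2 haplotypes for diversity")
  c1 <- .colSums(mat[rows, , drop = FALSE], m, ncol(mat))
  2 * c1 * (m - c1) / (m * (m - 1))
}

#' Windowed nucleotide diversity
#'
#' Per-site pairwise diversity summed over the sites in each window and
#' divided by the window span in bp, so values are per-site averages. Each
#' site contributes `2 c (m - c) / (m (m - 1))` for derived count `c` among
#' `m` haplotypes.
#'
#' @param m A `hap_matrix`.
#' @param pop Population selector: `"sel"`, `"neu"`, `"all"`, or row indices.
#' @param windows A [window_spec()].
#' @return Numeric vector, one value per window.
#' @export
nucleotide_diversity <- function(m, pop, windows) {
  rows <- pop_rows(m, pop)
  pis <- per_site_pi(m$mat, rows)
  window_sums(pis, m$positions, windows) / (windows$end - windows$start)
}

#' Windowed Tajima's D, sign-flipped
#'
#' Standard Tajima's D computed from the windowed diversity sum and
#' segregating-site count, with the sampled haplotype count `n * k` as sample
#' size, multiplied by -1 so that a post-sweep site-frequency-spectrum skew
#' (excess of rare variants) scores positive like the other metrics.
#' Windows with no segregating sites are `NA` (undefined, not zero).
#'
#' @inheritParams nucleotide_diversity
#' @return Numeric vector of -D, one value per window (`NA` where undefined).
#' @export
tajimas_d <- function(m, pop, windows) {
  rows <- pop_rows(m, pop)
  nh <- length(rows)
  if (nh < 3) stop("need at least 3 haplotypes for Tajima's D")
  cnt <- .colSums(m$mat[rows, , drop = FALSE], nh, ncol(m$mat))
  seg <- cnt > 0 & cnt < nh
  pis <- 2 * cnt * (nh - cnt) / (nh * (nh - 1))
  pi_sum <- window_sums(pis * seg, m$positions, windows)
  S <- window_sums(as.numeric(seg), m$positions, windows)

  i <- seq_len(nh - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (nh + 1) / (3 * (nh - 1))
  b2 <- 2 * (nh^2 + nh + 3) / (9 * nh * (nh - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nh + 2) / (a1 * nh) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)

  D <- rep(NA_real_, length(S))
  ok <- S > 0
  D[ok] <- (pi_sum[ok] - S[ok] / a1) /
    sqrt(e1 * S[ok] + e2 * S[ok] * (S[ok] - 1))
  -D
}

#' Windowed Hudson's F_ST between two populations
#'
#' `F_ST = 1 - pi_within / pi_between` as a ratio of window sums, using the
#' plug-in allele-frequency form: per site, within-population heterozygosity
#' averages `2 p_A (1 - p_A)` and `2 p_B (1 - p_B)`, and between-population
#' heterozygosity is `p_A (1 - p_B) + p_B (1 - p_A)`. With this form two
#' identical samples give exactly 0 and fixed differences without
#' within-population variation give exactly 1. Windows with zero
#' between-population diversity are `NA`.
#'
#' @inheritParams nucleotide_diversity
#' @param popA,popB Population selectors for the two groups.
#' @return Numeric vector of raw F_ST per window, in `(-Inf, 1]`.
#' @export
hudson_fst <- function(m, popA = "sel", popB = "neu", windows) {
  ra <- pop_rows(m, popA); rb <- pop_rows(m, popB)
  ma <- length(ra); mb <- length(rb)
  if (ma < 2 || mb < 2) stop("both populations need >= 2 haplotypes")
  pa <- .colSums(m$mat[ra, , drop = FALSE], ma, ncol(m$mat)) / ma
  pb <- .colSums(m$mat[rb, , drop = FALSE], mb, ncol(m$mat)) / mb
  wi <- pa * (1 - pa) + pb * (1 - pb)
  bt <- pa * (1 - pb) + pb * (1 - pa)
  wi_sum <- window_sums(wi, m$positions, windows)
  bt_sum <- window_sums(bt, m$positions, windows)
  ifelse(bt_sum > 0, 1 - wi_sum / bt_sum, NA)
}

#' Mean-standardize a metric within one replicate
#'
#' Subtracts the across-window mean and divides by the across-window standard
#' deviation (missing windows ignored), putting the metric's null expectation
#' at 0 with unit spread, comparable across metrics.
#'
#' @param values Per-window metric values (may contain `NA`).
#' @return Standardized values, same length, `NA` preserved.
#' @export
mean_standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need >= 2 defined windows to standardize")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance across windows; cannot standardize")
  (values - mean(values[ok])) / s
}

#' Extended haplotype homozygosity around a focal site
#'
#' EHH at distance `x` from the focal site is the probability that two
#' randomly drawn haplotypes carrying the focal allele are identical at every
#' site between the focal site and `x`. It is 1 at the focal site and
#' non-increasing outward, decaying as recombination (and mutation) break up
#' the core haplotype.
#'
#' @param m A `hap_matrix` (phased by construction).
#' @param pop Population selector.
#' @param focal Column index of the focal site.
#' @param allele Focal allele, 0 (ancestral) or 1 (derived); `NULL` uses all
#'   haplotypes of the population (the cross-population variant's convention).
#' @param stop_below Truncate the scan once EHH drops below this value
#'   (0 = full curve).
#' @return Data frame with `position` (bp) and `ehh`, ordered by position,
#'   containing the focal site (`ehh = 1`).
#' @export
ehh <- function(m, pop, focal, allele = 1L, stop_below = 0) {
  rows <- pop_rows(m, pop)
  mat <- m$mat[rows, , drop = FALSE]
  if (is.null(allele)) {
    carriers <- seq_len(nrow(mat))
  } else {
    carriers <- which(mat[, focal] == allele)
  }
  nc <- length(carriers)
  if (nc < 2) stop("focal allele has fewer than 2 carriers")
  S <- ncol(mat)
  scan <- function(js) {
    if (length(js) == 0) return(numeric(0))
    grp <- rep(1L, nc)
    out <- numeric(length(js))
    for (jj in seq_along(js)) {
      a <- mat[carriers, js[jj]]
      grp <- match(grp * 2L + a, unique(grp * 2L + a))
      tab <- tabulate(grp)
      out[jj] <- sum(tab * (tab - 1)) / (nc * (nc - 1))
      if (out[jj] < stop_below) { out <- out[seq_len(jj)]; break }
    }
    out
  }
  right <- scan(seq_len(S)[seq_len(S) > focal])
  left <- scan(rev(seq_len(S)[seq_len(S) < focal]))
  jr <- focal + seq_along(right)
  jl <- focal - seq_along(left)
  data.frame(
    position = c(rev(m$positions[jl]), m$positions[focal], m$positions[jr]),
    ehh = c(rev(left), 1, right))
}

#' Integrated EHH
#'
#' Trapezoidal integral (in bp) of the EHH curve outward from the focal site
#' in both directions, each direction truncated at the last point with
#' `EHH >= cutoff`.
#'
#' @param curve Output of [ehh()].
#' @param focal_pos Focal site position in bp.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return Integrated EHH in bp (0 if the curve is degenerate).
#' @export
ihh <- function(curve, focal_pos, cutoff = 0.05) {
  trap_out <- function(pos, val) {
    # pos ordered outward from focal
    keep <- which(val >= cutoff)
    if (length(keep) == 0) return(0)
    upto <- max(keep)
    pos <- pos[seq_len(upto)]; val <- val[seq_len(upto)]
    if (length(pos) < 2) return(0)
    sum(diff(pos) * (utils::head(val, -1) + utils::tail(val, -1)) / 2)
  }
  r <- curve$position >= focal_pos
  l <- curve$position <= focal_pos
  trap_out(curve$position[r], curve$ehh[r]) +
    trap_out(rev(-curve$position[l]), rev(curve$ehh[l]))
}

#' Within-population iHS scores (unstandardized)
#'
#' For each site whose minor-allele frequency reaches `maf`, computes the
#' integrated EHH for the ancestral- and derived-allele carriers and the raw
#' score `ln(iHH_A / iHH_D)`. Positive raw values mean long derived
#' haplotypes, the hard-sweep signature. Standardize across replicates in
#' derived-frequency bins with [standardize_ihs()].
#'
#' @inheritParams ehh
#' @param maf Minor-allele-frequency floor for focal sites.
#' @param cutoff EHH truncation threshold passed to [ihh()].
#' @return A tibble with `position`, `freq` (derived frequency) and
#'   `ihs_raw` (`NA` where either allele's iHH is 0).
#' @export
ihs <- function(m, pop, maf = 0.05, cutoff = 0.05) {
  rows <- pop_rows(m, pop)
  nh <- length(rows)
  cnt <- .colSums(m$mat[rows, , drop = FALSE], nh, ncol(m$mat))
  p <- cnt / nh
  focal_sites <- which(pmin(p, 1 - p) >= maf)
  raw <- rep(NA_real_, length(focal_sites))
  for (i in seq_along(focal_sites)) {
    f <- focal_sites[i]
    iA <- ihh(ehh(m, rows, f, allele = 0L, stop_below = cutoff),
              m$positions[f], cutoff)
    iD <- ihh(ehh(m, rows, f, allele = 1L, stop_below = cutoff),
              m$positions[f], cutoff)
    if (iA > 0 && iD > 0) raw[i] <- log(iA / iD)
  }
  tibble::tibble(position = m$positions[focal_sites],
                 freq = p[focal_sites], ihs_raw = raw)
}

#' Standardize iHS scores in derived-frequency bins
#'
#' Raw iHS depends on the derived-allele frequency, so scores are centred and
#' scaled within equal-width frequency bins, pooled across all replicates of
#' a parameter combination (per-replicate site counts are too small to bin).
#'
#' @param tbl A tibble of raw scores (rows from one or more [ihs()] calls
#'   concatenated), with columns `freq` and `ihs_raw`.
#' @param bins Number of equal-width frequency bins on (0, 1).
#' @return `tbl` with an added `ihs` column (`NA` where the bin has fewer
#'   than 2 defined scores).
#' @export
standardize_ihs <- function(tbl, bins = 50) {
  b <- pmin(pmax(ceiling(tbl$freq * bins), 1L), bins)
  z <- rep(NA_real_, nrow(tbl))
  for (bi in unique(b)) {
    idx <- which(b == bi & !is.na(tbl$ihs_raw))
    if (length(idx) >= 2) {
      s <- stats::sd(tbl$ihs_raw[idx])
      if (s > 0) z[idx] <- (tbl$ihs_raw[idx] - mean(tbl$ihs_raw[idx])) / s
    }
  }
  tbl$ihs <- z
  tbl
}

#' Cross-population EHH scores (XP-EHH)
#'
#' Per site, the log-ratio of population-wide integrated EHH between the two
#' populations, `ln(iHH_A / iHH_B)`; the EHH here is computed over all
#' haplotypes of a population regardless of allele. Scores are standardized
#' by the within-replicate mean and standard deviation. Positive values mean
#' unusually long haplotypes in population A (the selected one, by default).
#'
#' @inheritParams ihs
#' @param popA,popB Population selectors (A is the putatively selected one).
#' @return A tibble with `position`, `xpehh_raw` and `xpehh` (standardized);
#'   `NA` where either population's iHH is 0.
#' @export
xpehh <- function(m, popA = "sel", popB = "neu", cutoff = 0.05) {
  S <- ncol(m$mat)
  raw <- rep(NA_real_, S)
  for (f in seq_len(S)) {
    iA <- ihh(ehh(m, popA, f, allele = NULL, stop_below = cutoff),
              m$positions[f], cutoff)
    iB <- ihh(ehh(m, popB, f, allele = NULL, stop_below = cutoff),
              m$positions[f], cutoff)
    if (iA > 0 && iB > 0) raw[f] <- log(iA / iB)
  }
  ok <- !is.na(raw)
  std <- rep(NA_real_, S)
  if (sum(ok) >= 2 && stats::sd(raw[ok]) > 0) {
    std[ok] <- (raw[ok] - mean(raw[ok])) / stats::sd(raw[ok])
  }
  tibble::tibble(position = m$positions, xpehh_raw = raw, xpehh = std)
}

#' Windowed summary table for one replicate
#'
#' Convenience wrapper computing, per window: diversity in both populations,
#' sign-flipped Tajima's D in the selected population, and raw plus
#' mean-standardized Hudson's F_ST.
#'
#' @inheritParams nucleotide_diversity
#' @return A tibble with one row per window.
#' @export
window_table <- function(m, windows) {
  tbl <- tibble::tibble(
    mid = windows$mid,
    pi_sel = nucleotide_diversity(m, "sel", windows),
    tajd_neg_sel = tajimas_d(m, "sel", windows))
  if (m$n2 > 0) {
    tbl$pi_neu <- nucleotide_diversity(m, "neu", windows)
    tbl$fst_raw <- hudson_fst(m, "sel", "neu", windows)
    tbl$fst_std <- mean_standardize(tbl$fst_raw)
  }
  tbl
}
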