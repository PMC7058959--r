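#' Locus configuration
#'
#' Describes the simulated sequence: length `L` in bp (default 1 Mb), the
#' selected-site position (default the middle of the locus), and per-site
#' per-generation mutation and recombination rates. The population-scaled
#' composite rates are `theta = 2 N k mu` per site and `rho = 2 N k r`:
#' ploidy enters through the genome copy number `N k`.
#'
#' @param L Locus length in bp.
#' @param sel_pos Position of the selected site in bp (in `[0, L]`).
#' @param mu Per-site per-generation mutation rate.
#' @param r Per-adjacent-bp per-generation recombination rate.
#' @return A `locus_config` list.
#' @export
locus_config <- function(L = 1e6, sel_pos = L / 2, mu = 1e-8, r = 1e-8) {
  if (L <= 0) stop("`L` must be positive")
  if (sel_pos < 0 || sel_pos > L) stop("`sel_pos` must lie in [0, L]")
  if (mu < 0 || r < 0) stop("`mu` and `r` must be >= 0")
  structure(list(L = L, sel_pos = sel_pos, mu = mu, r = r),
            class = "locus_config")
}

#' Sampling demography
#'
#' Two populations of `N` individuals each, split from a common ancestral
#' population of the same size. `n` individuals (`n * k` haplotypes) are
#' sampled per population, `tau_post` generations after fixation of the
#' sweeping allele (0 = immediately at fixation). With
#' `sample_mode = "alleles"` a fixed number of haplotypes `n_alleles` is
#' drawn per population instead, so that ploidies can be compared at equal
#' allele counts rather than equal individual counts.
#'
#' @param N Individuals per population.
#' @param k Ploidy used for genome copy number (haplotypes per individual and
#'   rate scaling). May differ from the ploidy that generated the sweep
#'   trajectory, which is how trajectory and diversity/recombination effects
#'   are decomposed.
#' @param n Sampled individuals per population.
#' @param tau_post Generations between fixation and sampling.
#' @param sample_mode `"individuals"` (sample `n * k` haplotypes) or
#'   `"alleles"` (sample `n_alleles` haplotypes).
#' @param n_alleles Haplotypes per population when `sample_mode = "alleles"`.
#' @return A `demography` list with the per-population haplotype count
#'   `n_hap`.
#' @export
demography <- function(N, k, n = 10, tau_post = 0,
                       sample_mode = c("individuals", "alleles"),
                       n_alleles = NULL) {
  sample_mode <- match.arg(sample_mode)
  if (k < 2 || k %% 2 != 0) stop("`k` must be an even integer >= 2")
  if (tau_post < 0) stop("`tau_post` must be >= 0")
  n_hap <- if (sample_mode == "individuals") as.integer(n * k) else {
    if (is.null(n_alleles)) stop("`n_alleles` required when sample_mode='alleles'")
    as.integer(n_alleles)
  }
  if (n_hap > N * k) stop("cannot sample more haplotypes than the population holds")
  structure(list(N = as.integer(N), k = as.integer(k), n = as.integer(n),
                 tau_post = tau_post, sample_mode = sample_mode,
                 n_hap = n_hap),
            class = "demography")
}

new_hap_matrix <- function(mat, positions, n1, n2, k, L) {
  structure(list(mat = mat, positions = positions, n1 = as.integer(n1),
                 n2 = as.integer(n2), k = as.integer(k), L = L),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf(
    "hap_matrix: %d + %d haplotypes (k=%d), %d segregating sites on [0, %g)\n",
    x$n1, x$n2, x$k, ncol(x$mat), x$L))
  invisible(x)
}

#' @export
`==.hap_matrix` <- function(e1, e2) {
  identical(unname(e1$mat), unname(e2$mat)) &&
    isTRUE(all.equal(e1$positions, e2$positions, tolerance = 1e-12)) &&
    e1$n1 == e2$n1 && e1$n2 == e2$n2 && e1$L == e2$L
}

#' Simulate a post-sweep haplotype sample
#'
#' Backward-time structured coalescent conditioned on a forward-time sweep
#' trajectory. Sampling happens `tau_post` generations after fixation; going
#' backwards, lineages pass through a neutral post-fixation phase, then the
#' sweep phase (selected population only) in which coalescence is restricted
#' to allelic classes whose sizes follow the trajectory, and finally the
#' merged ancestral population. The two daughter populations split at the
#' trajectory's origin, which is when the beneficial mutation arose. Mutation
#' placement is infinite-sites ([drop_mutations()]).
#'
#' @param traj A fixed `sweep_trajectory` (its ploidy may differ from
#'   `demog$k`; that mismatch is deliberate in decomposition experiments).
#' @param demog A [demography()].
#' @param locus A [locus_config()].
#' @return A `hap_matrix`: rows are haplotypes (first the selected
#'   population's `n_hap`, then the neutral population's), columns are
#'   segregating sites with bp positions.
#' @export
simulate_sweep_sample <- function(traj, demog, locus = locus_config()) {
  if (!isTRUE(traj$fixed)) stop("trajectory is not fixation-conditioned")
  g <- .sim_arg_cpp(
    n1 = demog$n_hap, n2 = demog$n_hap, N = demog$N, k = demog$k,
    L = locus$L, sel_pos = locus$sel_pos, rec_rate = locus$r,
    tau_post = demog$tau_post, traj = traj$freqs, split_gens = 0,
    sweep = TRUE)
  sites <- drop_mutations(g, locus)
  new_hap_matrix(sites$mat, sites$positions, demog$n_hap, demog$n_hap,
                 demog$k, locus$L)
}

#' Simulate a neutral haplotype sample
#'
#' Same demography with no sweep: one population (`two_pops = FALSE`) or two
#' populations that split `split_gens` generations before sampling and merge
#' (backwards) into a single ancestral population.
#'
#' @inheritParams simulate_sweep_sample
#' @param split_gens Generations since the population split (ignored for a
#'   single population).
#' @param two_pops Simulate two sampled populations?
#' @return A `hap_matrix` (with `n2 = 0` for a single population).
#' @export
simulate_neutral_sample <- function(demog, locus = locus_config(),
                                    split_gens = 0, two_pops = FALSE) {
  if (split_gens < 0) stop("`split_gens` must be >= 0")
  n2 <- if (two_pops) demog$n_hap else 0L
  g <- .sim_arg_cpp(
    n1 = demog$n_hap, n2 = n2, N = demog$N, k = demog$k,
    L = locus$L, sel_pos = locus$sel_pos, rec_rate = locus$r,
    tau_post = 0, traj = numeric(0), split_gens = split_gens,
    sweep = FALSE)
  sites <- drop_mutations(g, locus)
  new_hap_matrix(sites$mat, sites$positions, demog$n_hap, n2, demog$k,
                 locus$L)
}

#' Simulate the genealogy only (no mutations)
#'
#' Lower-level access to the coalescent engine: returns the branch table
#' (class `sweep_genealogy`) that [drop_mutations()] consumes. Useful for
#' checking coalescence-time distributions directly, e.g. the pairwise TMRCA
#' of two haplotypes in a neutral population of `N k` copies is exponential
#' with mean `N k` generations.
#'
#' @inheritParams simulate_neutral_sample
#' @param n_hap Number of sampled haplotypes (single population).
#' @return A `sweep_genealogy` list: per branch-segment row `t0`, `t1`
#'   (generations back), `left`, `right` (bp), and the descendant-leaf sets
#'   in compressed form (`carriers_ptr`, `carriers`), plus `tmrca`.
#' @export
simulate_neutral_genealogy <- function(n_hap, demog, locus = locus_config()) {
  g <- .sim_arg_cpp(
    n1 = as.integer(n_hap), n2 = 0L, N = demog$N, k = demog$k,
    L = locus$L, sel_pos = locus$sel_pos, rec_rate = locus$r,
    tau_post = 0, traj = numeric(0), split_gens = 0, sweep = FALSE)
  g$L <- locus$L
  class(g) <- "sweep_genealogy"
  g
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The number of mutations is Poisson with mean `mu` times the total branch
#' "area" (bp x generations) of the genealogy; each mutation falls on a
#' branch-segment with probability proportional to its area and at a uniform
#' position within it, and is carried by that branch's descendant leaves.
#' Positions are quantized to 1e-6 fractions of `L` (the resolution of the
#' ms `positions:` line); the rare collision is redrawn, preserving the
#' infinite-sites property.
#'
#' @param genealogy A branch table from the coalescent engine.
#' @param locus A [locus_config()].
#' @return List with `mat` (0/1 haplotype-by-site matrix) and `positions`
#'   (strictly increasing bp coordinates).
#' @export
drop_mutations <- function(genealogy, locus) {
  L <- locus$L
  w <- (genealogy$t1 - genealogy$t0) * (genealogy$right - genealogy$left)
  W <- sum(w)
  n_leaves <- genealogy$n_leaves
  if (W <= 0) {
    return(list(mat = matrix(0L, n_leaves, 0), positions = numeric(0)))
  }
  S <- stats::rpois(1L, locus$mu * W)
  if (S == 0L) {
    return(list(mat = matrix(0L, n_leaves, 0), positions = numeric(0)))
  }
  rows <- sample.int(length(w), S, replace = TRUE, prob = w)
  draw_pos <- function(rw) {
    p <- genealogy$left[rw] + stats::runif(length(rw)) *
      (genealogy$right[rw] - genealogy$left[rw])
    round(p / L, 6) * L
  }
  pos <- draw_pos(rows)
  for (tries in 1:100) {
    dup <- duplicated(pos)
    if (!any(dup)) break
    pos[dup] <- draw_pos(rows[dup])
  }
  if (anyDuplicated(pos)) {  # pathological density: drop the collisions
    keep <- !duplicated(pos)
    rows <- rows[keep]; pos <- pos[keep]; S <- length(pos)
  }
  o <- order(pos)
  rows <- rows[o]; pos <- pos[o]
  mat <- matrix(0L, n_leaves, S)
  ptr <- genealogy$carriers_ptr
  for (j in seq_len(S)) {
    rw <- rows[j]
    car <- genealogy$carriers[(ptr[rw] + 1L):ptr[rw + 1L]]
    mat[car, j] <- 1L
  }
  list(mat = mat, positions = pos)
}
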