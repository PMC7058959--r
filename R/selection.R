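#' Selection model for an autopolyploid beneficial mutation
#'
#' Bundles the parameters governing selection on a single locus in an
#' autopolyploid Wright-Fisher population: ploidy `k` (chromosome copies per
#' individual), population size `N` (individuals), selection coefficient `s`
#' (fitness difference between the alternative homozygotes), and the dominance
#' scalar `H` which maps derived-allele dosage to a dominance coefficient.
#'
#' A genotype carrying `d` of `k` derived copies has fitness `1 + h(d) * s`
#' with `h(d) = (d/k)^tau`. The exponent `tau` is derived from the dominance
#' scalar as `tau = 10^(-H)`, so `H = 0` is additive (`h(d) = d/k`), negative
#' `H` (recessive-like) gives `tau > 1` (convex `h`), and positive `H`
#' (dominant-like) gives `0 < tau < 1` (concave `h`).
#'
#' @param k Even integer ploidy, >= 2.
#' @param N Number of individuals, >= 2. The population carries `N * k`
#'   chromosome copies.
#' @param s Selection coefficient; the derived homozygote has fitness `1 + s`.
#' @param H Dominance scalar, in the open interval (-0.5, 0.5).
#' @param tau_map Function mapping `H` to the dominance exponent `tau`;
#'   defaults to `10^(-H)`. Exposed as a hook because the mapping is a model
#'   choice, not a law.
#' @return An object of class `selection_model` with fields `k`, `N`, `s`,
#'   `H`, `tau` and the dominance vector `h` (length `k + 1`, indexed by
#'   derived dosage `0..k`).
#' @examples
#' m <- selection_model(k = 4, N = 1000, s = 0.01, H = 0)
#' m$h  # 0, 0.25, 0.5, 0.75, 1
#' @export
selection_model <- function(k, N, s, H = 0, tau_map = function(H) 10^(-H)) {
  if (length(k) != 1L || !is.finite(k) || k < 2 || k %% 2 != 0) {
    stop("`k` must be a single even integer >= 2, got ", deparse(k))
  }
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2, got ", deparse(N))
  }
  if (!is.finite(s)) stop("`s` must be finite")
  h <- dominance_coefficients(H, k, tau_map = tau_map)
  structure(
    list(k = as.integer(k), N = as.integer(N), s = s, H = H,
         tau = tau_map(H), h = h),
    class = "selection_model"
  )
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("selection_model: k=%d N=%d s=%g H=%g (tau=%.4g)\n",
              x$k, x$N, x$s, x$H, x$tau))
  cat("h(d), d=0..k:", signif(x$h, 4), "\n")
  invisible(x)
}

#' Dosage-dependent dominance coefficients
#'
#' Computes the vector `h(d) = (d/k)^tau` for derived dosage `d = 0..k`,
#' with `tau = tau_map(H)` (default `10^(-H)`). `h(0) = 0` and `h(k) = 1`
#' exactly for every `H`, so the homozygotes anchor the fitness scale.
#'
#' @inheritParams selection_model
#' @return Numeric vector of length `k + 1`.
#' @examples
#' dominance_coefficients(0, 4)      # additive: 0 .25 .5 .75 1
#' dominance_coefficients(-0.4, 2)   # recessive-like heterozygote
#' @export
dominance_coefficients <- function(H, k, tau_map = function(H) 10^(-H)) {
  if (length(H) != 1L || !is.finite(H) || H <= -0.5 || H >= 0.5) {
    stop("`H` must lie in the open interval (-0.5, 0.5), got ", deparse(H))
  }
  if (length(k) != 1L || !is.finite(k) || k < 2 || k %% 2 != 0) {
    stop("`k` must be a single even integer >= 2, got ", deparse(k))
  }
  tau <- tau_map(H)
  d <- 0:k
  h <- (d / k)^tau
  h[1] <- 0
  h[k + 1] <- 1
  h
}

#' Expected derived-allele frequency after one generation of selection
#'
#' Deterministic selection update for arbitrary even ploidy. Genotypes are
#' enumerated by derived dosage `d ~ Binomial(k, p)` (random union of gametes,
#' polysomic inheritance); each contributes its transmission fraction `d/k`
#' of derived alleles weighted by fitness `1 + h(d) s`, normalized by mean
#' fitness:
#' \deqn{\hat p = \frac{\sum_d \binom{k}{d} p^d (1-p)^{k-d} (d/k)(1 + h_d s)}
#'                     {\sum_d \binom{k}{d} p^d (1-p)^{k-d} (1 + h_d s)}}
#'
#' @param p Current derived-allele frequency in `[0, 1]`.
#' @param model A [selection_model()].
#' @return Expected frequency in the next generation, in `[0, 1]`.
#' @export
expected_frequency <- function(p, model) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  vapply(p, expected_frequency1, numeric(1),
         k = model$k, s = model$s, h = model$h)
}

# scalar core, used in the hot trajectory loop
expected_frequency1 <- function(p, k, s, h) {
  if (p == 0) return(0)
  if (p == 1) return(1)
  d <- 0:k
  w <- choose(k, d) * p^d * (1 - p)^(k - d)
  fit <- 1 + h * s
  den <- sum(w * fit)
  if (den <= 0) stop("mean fitness <= 0; selection model is degenerate (s <= -1)")
  sum(w * (d / k) * fit) / den
}

#' One generation of Wright-Fisher genotype sampling
#'
#' Realizes the next-generation frequency by binomial sampling of `N`
#' individuals' genotype dosages around the selection expectation `phat`.
#' The sum of `N` iid `Binomial(k, phat)` dosages is exactly
#' `Binomial(N k, phat)`, which is what is drawn; the result is the total
#' derived copy count divided by `N k`, always a multiple of `1/(N k)`.
#' Uses R's global RNG, so `set.seed()` makes it reproducible.
#'
#' @param phat Expected frequency in `[0, 1]`.
#' @param N Number of individuals.
#' @param k Ploidy.
#' @return Realized frequency in the next generation.
#' @export
wright_fisher_step <- function(phat, N, k) {
  if (phat < 0 || phat > 1) stop("`phat` must lie in [0, 1]")
  stats::rbinom(1L, N * k, phat) / (N * k)
}

#' Mean and variance of fitness at a given allele frequency
#'
#' Genotype dosage is `Binomial(k, p)` under random union of gametes; fitness
#' is `1 + h(d) s`. Higher ploidies spread the same allele frequency over more
#' dosage classes, so at intermediate frequencies the variance in fitness --
#' the fuel of selection -- shrinks with `k`.
#'
#' @inheritParams expected_frequency
#' @return A list with elements `mean` and `variance`.
#' @export
fitness_moments <- function(p, model) {
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  d <- 0:model$k
  w <- stats::dbinom(d, model$k, p)
  fit <- 1 + model$h * model$s
  m <- sum(w * fit)
  v <- sum(w * fit^2) - m^2
  list(mean = m, variance = max(v, 0))
}
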