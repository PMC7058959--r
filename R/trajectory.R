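#' Simulate a fixation-conditioned allele-frequency trajectory
#'
#' Forward Wright-Fisher simulation of a new beneficial mutation. The
#' mutation arises in single copy (frequency `1/(k N)`) and each generation
#' the deterministic selection expectation ([expected_frequency()]) is
#' perturbed by binomial genotype sampling ([wright_fisher_step()]) until the
#' allele fixes or is lost. Lost runs are discarded and counted; the first
#' fixed run is returned (rejection sampling, i.e. conditioning on fixation).
#'
#' @param model A [selection_model()].
#' @param max_attempts Attempt budget for the rejection sampler. With additive
#'   selection the per-attempt fixation probability is roughly `2s/k`, so the
#'   budget needs to comfortably exceed `k/(2s)`.
#' @return An object of class `sweep_trajectory`: a list with `freqs`
#'   (frequencies `p_0 .. p_T`, forward time, one per generation; `p_0 =
#'   1/(kN)`, `p_T = 1`), `fixed = TRUE`, `attempts` (number of lost runs
#'   before this one), and the model parameters.
#' @examples
#' set.seed(1)
#' tr <- simulate_trajectory(selection_model(k = 2, N = 100, s = 0.5))
#' length(tr$freqs)  # fixation time + 1
#' @export
simulate_trajectory <- function(model, max_attempts = 1e6) {
  if (max_attempts < 1) stop("`max_attempts` must be >= 1")
  k <- model$k; N <- model$N; s <- model$s; h <- model$h
  kN <- k * N
  p0 <- 1 / kN
  for (attempt in seq_len(max_attempts)) {
    p <- p0
    freqs <- numeric(256L)
    freqs[1L] <- p
    t <- 1L
    repeat {
      phat <- expected_frequency1(p, k, s, h)
      p <- stats::rbinom(1L, kN, phat) / kN
      t <- t + 1L
      if (t > length(freqs)) freqs <- c(freqs, numeric(length(freqs)))
      freqs[t] <- p
      if (p == 0 || p == 1) break
    }
    if (p == 1) {
      return(structure(
        list(freqs = freqs[seq_len(t)], fixed = TRUE,
             attempts = attempt - 1L, k = k, N = N, s = s, H = model$H),
        class = "sweep_trajectory"
      ))
    }
  }
  stop("conditioning failed: no fixation in ", max_attempts,
       " attempts (k=", k, ", N=", N, ", s=", s, ", H=", model$H, ")")
}

#' @export
print.sweep_trajectory <- function(x, ...) {
  cat(sprintf(
    "sweep_trajectory: k=%d N=%d s=%g H=%g | T=%d generations, %d lost attempts\n",
    x$k, x$N, x$s, x$H, length(x$freqs) - 1L, x$attempts))
  invisible(x)
}

#' Deterministic (infinite-population) selection trajectory
#'
#' Iterates the selection expectation with no drift, from `p0` until the
#' frequency reaches `threshold` (default `1 - 1/(kN)`, the deterministic
#' analogue of fixation). Useful as the infinite-`N` reference curve for
#' stochastic trajectories.
#'
#' @inheritParams simulate_trajectory
#' @param p0 Starting frequency, strictly inside (0, 1).
#' @param threshold Stop once the frequency reaches this value.
#' @param max_generations Generation cap; exceeded (e.g. with `s = 0`) is an
#'   error, since the path would never terminate.
#' @return Numeric vector of frequencies, forward time, ending at the first
#'   value `>= threshold`.
#' @export
deterministic_trajectory <- function(model, p0 = 1 / (model$k * model$N),
                                     threshold = 1 - 1 / (model$k * model$N),
                                     max_generations = 1e6) {
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie strictly inside (0, 1)")
  k <- model$k; s <- model$s; h <- model$h
  freqs <- numeric(1024L)
  p <- p0
  freqs[1L] <- p
  t <- 1L
  while (p < threshold) {
    if (t >= max_generations) {
      stop("deterministic trajectory did not reach ", threshold, " within ",
           max_generations, " generations")
    }
    p <- expected_frequency1(p, k, s, h)
    t <- t + 1L
    if (t > length(freqs)) freqs <- c(freqs, numeric(length(freqs)))
    freqs[t] <- p
  }
  freqs[seq_len(t)]
}

#' Fixation-time and fixation-probability summaries
#'
#' Runs [simulate_trajectory()] `n_reps` times and summarizes fixation times
#' (in generations) and the fixation probability estimated as
#' fixations / total attempts (rejected runs included).
#'
#' @inheritParams simulate_trajectory
#' @param n_reps Number of fixed trajectories to collect.
#' @return A list with `mean_T`, `median_T`, `T` (vector of fixation times),
#'   `fixations`, `attempts` (total, including the successful runs) and
#'   `p_fix = fixations / attempts`.
#' @export
fixation_stats <- function(model, n_reps, max_attempts = 1e6) {
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  T_fix <- integer(n_reps)
  attempts <- 0L
  for (r in seq_len(n_reps)) {
    tr <- simulate_trajectory(model, max_attempts = max_attempts)
    T_fix[r] <- length(tr$freqs) - 1L
    attempts <- attempts + tr$attempts + 1L
  }
  list(mean_T = mean(T_fix), median_T = as.numeric(stats::median(T_fix)),
       T = T_fix,
       fixations = n_reps, attempts = attempts, p_fix = n_reps / attempts)
}

#' Write / read a trajectory in the package's text format
#'
#' The format is a comment header `# k N s H seed` followed by one frequency
#' per line, forward in time. `write_mssel_trajectory()` writes the reversed
#' two-column (time-backwards, frequency) layout that trajectory-conditioned
#' coalescent samplers consume.
#'
#' @param traj A `sweep_trajectory`.
#' @param path File path.
#' @param seed Optional seed to record in the header (not used on read).
#' @return `read_trajectory()` returns a `sweep_trajectory`; the writers
#'   return `path` invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NA) {
  header <- sprintf("# %d %d %g %g %s", traj$k, traj$N, traj$s, traj$H,
                    format(seed))
  writeLines(c(header, format(traj$freqs, digits = 17, trim = TRUE,
                              scientific = FALSE)), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#\\s*", "", lines[1L]), "\\s+")[[1L]]
  if (!startsWith(lines[1L], "#") || length(hdr) < 4L) {
    stop("malformed trajectory header in ", path)
  }
  freqs <- as.numeric(lines[-1L])
  if (anyNA(freqs)) stop("non-numeric frequency line in ", path)
  structure(
    list(freqs = freqs, fixed = freqs[length(freqs)] == 1,
         attempts = NA_integer_,
         k = as.integer(hdr[1L]), N = as.integer(hdr[2L]),
         s = as.numeric(hdr[3L]), H = as.numeric(hdr[4L])),
    class = "sweep_trajectory"
  )
}

#' @rdname write_trajectory
#' @export
write_mssel_trajectory <- function(traj, path) {
  # backward time in generations from fixation, frequency at that time
  fr <- rev(traj$freqs)
  writeLines(sprintf("%d\t%.17g", seq_along(fr) - 1L, fr), path)
  invisible(path)
}
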