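#' Experiment configuration
#'
#' A parameter grid for end-to-end sweep experiments: every combination of
#' ploidy `k`, selection coefficient `s`, dominance scalar `H`, population
#' size `N` and sampling delay `tau_post` becomes a grid cell, run `reps`
#' times. With `decompose = TRUE` the trajectory ploidy and the genomic
#' ploidy are crossed independently, separating the sweep-trajectory effect
#' (longer fixation at higher ploidy) from the diversity/recombination
#' effect (higher `theta`/`rho` at higher ploidy).
#'
#' @param k Ploidies (even integers).
#' @param s Selection coefficients.
#' @param H Dominance scalars in (-0.5, 0.5).
#' @param N Population sizes.
#' @param n Sampled individuals per population.
#' @param tau_post Sampling delays (generations after fixation).
#' @param reps Replicates per cell.
#' @param seed Master seed; each replicate derives its own seed from it.
#' @param sample_mode,n_alleles See [demography()].
#' @param mu,r,L,sel_pos See [locus_config()].
#' @param decompose Cross trajectory ploidy and genomic ploidy?
#' @param max_attempts Rejection-sampling budget per trajectory.
#' @param haplotype_stats Also compute iHS and XP-EHH per replicate?
#' @return An `experiment_config` list with a `cells` data frame.
#' @export
experiment_config <- function(k = c(2, 4), s = 0.01, H = 0, N = 1000,
                              n = 10, tau_post = 0, reps = 10, seed = 1,
                              sample_mode = "individuals", n_alleles = NULL,
                              mu = 1e-8, r = 1e-8, L = 1e6, sel_pos = L / 2,
                              decompose = FALSE, max_attempts = 1e6,
                              haplotype_stats = FALSE) {
  if (reps < 1) stop("`reps` must be >= 1")
  cells <- if (decompose) {
    expand.grid(k_traj = k, k_genomic = k, s = s, H = H, N = N,
                tau_post = tau_post, KEEP.OUT.ATTRS = FALSE)
  } else {
    g <- expand.grid(k_traj = k, s = s, H = H, N = N, tau_post = tau_post,
                     KEEP.OUT.ATTRS = FALSE)
    g$k_genomic <- g$k_traj
    g
  }
  cells <- cells[, c("k_traj", "k_genomic", "s", "H", "N", "tau_post")]
  for (kk in unique(c(cells$k_traj, cells$k_genomic))) {
    invisible(selection_model(kk, max(N), max(s), H[1]))  # validates k
  }
  structure(
    list(cells = cells, n = n, reps = as.integer(reps), seed = as.integer(seed),
         sample_mode = sample_mode, n_alleles = n_alleles,
         locus = locus_config(L = L, sel_pos = sel_pos, mu = mu, r = r),
         max_attempts = max_attempts, haplotype_stats = haplotype_stats),
    class = "experiment_config")
}

#' The headline parameter grid
#'
#' Ploidies 2, 4 and 8 crossed with selection coefficients 0.001/0.01/0.1,
#' dominance scalars -0.4/0/0.4 and population sizes 1000/10000, sampling
#' `n = 10` individuals per population -- the full factorial explored in the
#' study this package reproduces, with a reduced default replicate count so
#' it is runnable at desk scale. Window widths follow `L/(N/50)`: 50 kb for
#' `N = 1000`, 5 kb for `N = 10000`.
#'
#' @param reps Replicates per cell (desk-scale default).
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
default_paper_grid <- function(reps = 5, seed = 1) {
  experiment_config(k = c(2, 4, 8), s = c(0.001, 0.01, 0.1),
                    H = c(-0.4, 0, 0.4), N = c(1000, 10000),
                    n = 10, reps = reps, seed = seed)
}

replicate_seed <- function(master, cell_idx, rep_idx) {
  (as.numeric(master) + cell_idx * 100003 + rep_idx * 101) %% 2147483647
}

#' Run an experiment grid end-to-end
#'
#' For every cell and replicate: simulate a fixation-conditioned trajectory
#' (at the cell's trajectory ploidy), simulate the two-population coalescent
#' sample (at the genomic ploidy), compute windowed statistics and the peak
#' summary. Each replicate runs under its own seed derived from the master
#' seed, so identical configs reproduce identical tables and any single
#' replicate can be regenerated in isolation. A failing replicate is
#' recorded and skipped; a cell whose replicates all fail aborts the run.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the three result tables
#'   are written as TSV (`trajectories.tsv`, `windows.tsv`, `peaks.tsv`).
#' @param verbose Print one progress line per replicate?
#' @return A list of tibbles: `trajectories` (one row per replicate),
#'   `windows` (one row per window per replicate), `peaks` (one row per
#'   replicate), and `errors` (possibly empty).
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  cells <- config$cells
  traj_rows <- list(); win_rows <- list(); peak_rows <- list()
  err_rows <- list(); site_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, , drop = FALSE]
    rownames(cell) <- NULL
    model <- selection_model(cell$k_traj, cell$N, cell$s, cell$H)
    windows <- window_spec(config$locus$L, N = cell$N)
    n_fail <- 0L
    for (ri in seq_len(config$reps)) {
      seed <- replicate_seed(config$seed, ci, ri)
      res <- tryCatch({
        set.seed(seed)
        t_start <- proc.time()[["elapsed"]]
        traj <- simulate_trajectory(model, max_attempts = config$max_attempts)
        demog <- demography(cell$N, cell$k_genomic, n = config$n,
                            tau_post = cell$tau_post,
                            sample_mode = config$sample_mode,
                            n_alleles = config$n_alleles)
        m <- simulate_sweep_sample(traj, demog, config$locus)
        wt <- window_table(m, windows)
        pk <- peak_summary(wt, config$locus$sel_pos)
        sites <- NULL
        if (isTRUE(config$haplotype_stats)) {
          xp <- xpehh(m)
          ih <- ihs(m, "sel")
          pk$xpehh_max <- suppressWarnings(max(xp$xpehh, na.rm = TRUE))
          sites <- cbind(
            cell, replicate = ri, seed = seed,
            rbind(
              data.frame(metric = "xpehh", position = xp$position,
                         value = xp$xpehh, freq = NA_real_),
              data.frame(metric = "ihs_raw", position = ih$position,
                         value = ih$ihs_raw, freq = ih$freq)))
        }
        runtime <- proc.time()[["elapsed"]] - t_start
        list(traj = traj, wt = wt, pk = pk, m = m, sites = sites,
             runtime = runtime)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        err_rows[[length(err_rows) + 1L]] <- cbind(
          cell, replicate = ri, seed = seed,
          message = conditionMessage(res))
        if (verbose) {
          cat(sprintf("cell %d rep %d FAILED: %s\n", ci, ri,
                      conditionMessage(res)))
        }
        next
      }
      traj_rows[[length(traj_rows) + 1L]] <- cbind(
        cell, replicate = ri, seed = seed,
        T_fix = length(res$traj$freqs) - 1L, attempts = res$traj$attempts,
        S = ncol(res$m$mat))
      win_rows[[length(win_rows) + 1L]] <- cbind(
        cell, replicate = ri, seed = seed, res$wt)
      peak_rows[[length(peak_rows) + 1L]] <- cbind(
        cell, replicate = ri, seed = seed, res$pk)
      if (!is.null(res$sites)) {
        site_rows[[length(site_rows) + 1L]] <- res$sites
      }
      if (verbose) {
        cat(sprintf(
          "cell %d rep %d seed %d: T=%d attempts=%d S=%d (%.2fs)\n",
          ci, ri, seed, length(res$traj$freqs) - 1L, res$traj$attempts,
          ncol(res$m$mat), res$runtime))
      }
    }
    if (n_fail == config$reps) {
      stop("all ", config$reps, " replicates failed in cell ", ci,
           " (k_traj=", cell$k_traj, ", k_genomic=", cell$k_genomic,
           ", s=", cell$s, ", H=", cell$H, ", N=", cell$N, ")")
    }
  }
  out <- list(
    trajectories = tibble::as_tibble(do.call(rbind, traj_rows)),
    windows = tibble::as_tibble(do.call(rbind, win_rows)),
    peaks = tibble::as_tibble(do.call(rbind, peak_rows)),
    errors = if (length(err_rows)) tibble::as_tibble(do.call(rbind, err_rows))
             else tibble::tibble())
  if (isTRUE(config$haplotype_stats) && length(site_rows)) {
    sites <- tibble::as_tibble(do.call(rbind, site_rows))
    ih <- sites[sites$metric == "ihs_raw", ]
    if (nrow(ih) > 0) {
      std <- standardize_ihs(
        tibble::tibble(freq = ih$freq, ihs_raw = ih$value))
      sites$value[sites$metric == "ihs_raw"] <- std$ihs
      sites$metric[sites$metric == "ihs_raw"] <- "ihs"
    }
    out$sites <- sites
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("trajectories", "windows", "peaks")) {
      utils::write.table(
        out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
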