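# Statistical checks of the coalescent engine. Replicate counts here are
# kept modest (the acceptance suite runs the full-size calibrations); the
# 3-sigma bands use the observed spread, so they are honest at this scale.

test_that("pairwise TMRCA in a neutral population is about N*k generations", {
  set.seed(10)
  d <- demography(500, 4, n = 10)
  lo <- locus_config(r = 0)
  tm <- replicate(600, simulate_neutral_genealogy(2, d, lo)$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 500 * 4), 3 * se)
  # exponential: sd about equal to mean
  expect_lt(abs(sd(tm) / mean(tm) - 1), 0.2)
})

test_that("neutral diversity calibrates to theta = 2*N*k*mu and D to 0", {
  set.seed(11)
  w1 <- window_spec(1e6, width = 2e6)  # one full-locus window
  res <- sapply(c(2, 4), function(k) {
    d <- demography(1000, k, n = 10)
    pis <- numeric(120); Ds <- numeric(120)
    for (i in 1:120) {
      hm <- simulate_neutral_sample(d, locus_config())
      pis[i] <- nucleotide_diversity(hm, "sel", w1)[1]
      Ds[i] <- tajimas_d(hm, "sel", w1)[1]
    }
    c(pi = mean(pis), se = sd(pis) / sqrt(120),
      D = mean(Ds), Dse = sd(Ds) / sqrt(120))
  })
  for (j in 1:2) {
    theta <- 2 * 1000 * c(2, 4)[j] * 1e-8
    expect_lt(abs(res["pi", j] - theta), 3 * res["se", j])
    expect_lt(abs(res["D", j]), 3 * res["Dse", j])
  }
  # factor-of-two effect of ploidy on baseline diversity
  ratio_se <- res["pi", 2] / res["pi", 1] *
    sqrt((res["se", 1] / res["pi", 1])^2 + (res["se", 2] / res["pi", 2])^2)
  expect_lt(abs(res["pi", 2] / res["pi", 1] - 2), 3 * ratio_se)
})

test_that("segregating sites follow the Watterson expectation and scale with mu", {
  set.seed(12)
  d <- demography(500, 2, n = 5)  # 10 haplotypes
  S1 <- replicate(150, ncol(simulate_neutral_sample(d, locus_config())$mat))
  expected <- 2 * 500 * 2 * 1e-8 * 1e6 * sum(1 / (1:9))
  expect_lt(abs(mean(S1) - expected), 3 * sd(S1) / sqrt(150))
  S2 <- replicate(150, ncol(simulate_neutral_sample(
    d, locus_config(mu = 2e-8))$mat))
  r <- mean(S2) / mean(S1)
  r_se <- r * sqrt((sd(S1) / mean(S1))^2 + (sd(S2) / mean(S2))^2) / sqrt(150)
  expect_lt(abs(r - 2), 3 * r_se)
})

test_that("drop_mutations handles degenerate genealogies and segregates sites", {
  lo <- locus_config()
  empty <- list(t0 = numeric(0), t1 = numeric(0), left = numeric(0),
                right = numeric(0), carriers_ptr = 0L, carriers = integer(0),
                n_leaves = 4L)
  out <- drop_mutations(empty, lo)
  expect_identical(ncol(out$mat), 0L)
  # zero branch length => zero sites
  zerolen <- list(t0 = c(0, 0), t1 = c(0, 0), left = c(0, 0),
                  right = c(1e6, 1e6), carriers_ptr = c(0L, 1L, 2L),
                  carriers = c(1L, 2L), n_leaves = 2L)
  expect_identical(ncol(drop_mutations(zerolen, lo)$mat), 0L)
  # simulated samples: positions strictly increasing, all columns segregating
  set.seed(13)
  d <- demography(500, 2, n = 10)
  hm <- simulate_neutral_sample(d, lo)
  expect_true(all(diff(hm$positions) > 0))
  cs <- colSums(hm$mat)
  expect_true(all(cs > 0 & cs < nrow(hm$mat)))
  expect_identical(nrow(hm$mat), 20L)  # leaf conservation
})

test_that("sweep sampler requires a fixed trajectory and reduces diversity", {
  set.seed(14)
  fake <- structure(list(freqs = c(0.01, 0.5), fixed = FALSE),
                    class = "sweep_trajectory")
  expect_error(simulate_sweep_sample(fake, demography(100, 2)),
               "not fixation-conditioned")
  # diversity at the selected site is strongly reduced relative to the
  # neutral population of the same replicate
  m <- selection_model(2, 500, 0.2, 0)
  w <- window_spec(1e6, N = 500)
  ctr <- which.min(abs(w$mid - 5e5))
  rel <- replicate(30, {
    tr <- simulate_trajectory(m)
    hm <- simulate_sweep_sample(tr, demography(500, 2, n = 10))
    wt <- window_table(hm, w)
    wt$pi_sel[ctr] / mean(wt$pi_neu)
  })
  expect_lt(mean(rel), 0.5)
})

test_that("a near-fixed constant pseudo-trajectory degenerates to neutrality", {
  # sweep machinery run on x = 0.999 for longer than typical TMRCA should be
  # statistically indistinguishable from the neutral baseline
  set.seed(15)
  N <- 300
  pseudo <- structure(list(freqs = c(rep(0.999, 10 * N * 2), 1), fixed = TRUE),
                      class = "sweep_trajectory")
  d <- demography(N, 2, n = 10)
  w1 <- window_spec(1e6, width = 2e6)
  stat <- replicate(80, {
    hm <- simulate_sweep_sample(pseudo, d, locus_config())
    c(nucleotide_diversity(hm, "sel", w1)[1], tajimas_d(hm, "sel", w1)[1])
  })
  theta <- 2 * N * 2 * 1e-8
  expect_lt(abs(mean(stat[1, ]) - theta), 3 * sd(stat[1, ]) / sqrt(80))
  expect_lt(abs(mean(stat[2, ], na.rm = TRUE)),
            3 * sd(stat[2, ], na.rm = TRUE) / sqrt(80))
})

test_that("sample_mode = 'alleles' fixes the haplotype count across ploidies", {
  set.seed(16)
  d <- demography(200, 4, n = 10, sample_mode = "alleles", n_alleles = 12)
  expect_identical(d$n_hap, 12L)
  hm <- simulate_neutral_sample(d, locus_config())
  expect_identical(nrow(hm$mat), 12L)
  expect_error(demography(10, 2, n = 100), "cannot sample")
})
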