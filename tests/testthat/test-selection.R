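test_that("dominance coefficients: additive, recessive-like, dominant-like", {
  # additive: linear in dosage
  expect_equal(dominance_coefficients(0, 4), c(0, 0.25, 0.5, 0.75, 1))
  # frozen from the direct arithmetic oracle (0.5)^(10^0.4), (0.5)^(10^-0.4)
  m <- selection_model(2, 100, 0.1, H = -0.4)
  expect_equal(m$tau, 2.511886, tolerance = 1e-6)
  expect_equal(m$h[2], 0.1753262, tolerance = 1e-6)
  m <- selection_model(2, 100, 0.1, H = 0.4)
  expect_equal(m$tau, 0.398107, tolerance = 1e-6)
  expect_equal(m$h[2], 0.7588532, tolerance = 1e-6)
})

test_that("dominance vector endpoints, monotonicity and continuity at H = 0", {
  for (H in c(-0.49, -0.2, 0, 0.3, 0.49)) {
    for (k in c(2, 4, 8)) {
      h <- dominance_coefficients(H, k)
      expect_identical(h[1], 0)
      expect_identical(h[k + 1], 1)
      expect_true(all(diff(h) > 0))
    }
  }
  # continuity: h approaches the additive line as H -> 0 from both sides
  for (eps in c(1e-6, -1e-6)) {
    expect_equal(dominance_coefficients(eps, 8), (0:8) / 8, tolerance = 1e-4)
  }
})

test_that("dominance and model constructors reject invalid domains", {
  expect_error(dominance_coefficients(0.5, 2), "open interval")
  expect_error(dominance_coefficients(-0.7, 2), "open interval")
  expect_error(dominance_coefficients(0, 3), "even")
  expect_error(dominance_coefficients(0, 0), "even")
  expect_error(selection_model(5, 100, 0.1), "even")
  expect_error(selection_model(2, 1, 0.1), "N")
})

test_that("expected_frequency matches hand enumeration and absorbing states", {
  m2 <- selection_model(2, 100, 0.1, 0)
  # 3 diploid genotypes by hand: 0.5375 / 1.05
  expect_equal(expected_frequency(0.5, m2), 0.511904762, tolerance = 1e-9)
  m4 <- selection_model(4, 100, 0.1, 0)
  # frozen from the genotype-enumeration oracle; also equals the additive
  # closed form (p + s E[d^2]/k^2) / (1 + s p)
  expect_equal(expected_frequency(0.1, m4), 0.1022277228, tolerance = 1e-9)
  # absorbing states and neutrality
  for (m in list(m2, m4, selection_model(8, 50, 0.3, -0.3))) {
    expect_identical(expected_frequency(0, m), 0)
    expect_identical(expected_frequency(1, m), 1)
  }
  m0 <- selection_model(4, 100, 0, 0.2)
  p <- c(0.1, 0.33, 0.9)
  expect_equal(expected_frequency(p, m0), p, tolerance = 1e-14)
  expect_error(expected_frequency(1.2, m2), "\\[0, 1\\]")
})

test_that("expected_frequency equals term-by-term genotype enumeration", {
  set.seed(101)
  for (rep in 1:200) {
    k <- sample(c(2, 4, 6, 8), 1)
    p <- runif(1)
    s <- runif(1, -0.5, 0.5)
    H <- runif(1, -0.49, 0.49)
    m <- selection_model(k, 100, s, H)
    expect_equal(expected_frequency(p, m),
                 oracle_expected_frequency(p, k, s, H), tolerance = 1e-12)
  }
  # diploid additive case reduces to the textbook update via the same oracle
  for (p in seq(0.05, 0.95, by = 0.15)) {
    s <- 0.08
    textbook <- p * (1 + s * (p + (1 - p) / 2)) / (1 + s * p)
    expect_equal(expected_frequency(p, selection_model(2, 100, s, 0)),
                 textbook, tolerance = 1e-12)
  }
})

test_that("wright_fisher_step: degenerate inputs, determinism, moments", {
  expect_identical(wright_fisher_step(0, 1000, 4), 0)
  expect_identical(wright_fisher_step(1, 1000, 4), 1)
  set.seed(99); a <- wright_fisher_step(0.3, 1000, 4)
  set.seed(99); b <- wright_fisher_step(0.3, 1000, 4)
  expect_identical(a, b)
  expect_lt(abs(a * 4000 - round(a * 4000)), 1e-9)
  # unbiasedness and binomial variance at 1e5 draws
  set.seed(7)
  draws <- replicate(1e5, wright_fisher_step(0.3, 1000, 4))
  se <- sqrt(0.3 * 0.7 / 4000 / 1e5)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  expect_lt(abs(var(draws) / (0.3 * 0.7 / 4000) - 1), 0.05)
})

test_that("fitness moments: exact diploid values and variance ordering", {
  m2 <- selection_model(2, 100, 0.1, 0)
  fm <- fitness_moments(0.5, m2)
  # enumerate: 0.25*1 + 0.5*1.05 + 0.25*1.1 = 1.05; E[f^2] - 1.05^2
  expect_equal(fm$mean, 1.05, tolerance = 1e-12)
  expect_equal(fm$variance, 0.00125, tolerance = 1e-12)
  expect_identical(fitness_moments(0, m2)$variance, 0)
  expect_identical(fitness_moments(1, m2)$variance, 0)
  v <- sapply(c(2, 4, 8), function(k) {
    fitness_moments(0.5, selection_model(k, 100, 0.1, 0))$variance
  })
  expect_true(v[3] < v[2] && v[2] < v[1])
})
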