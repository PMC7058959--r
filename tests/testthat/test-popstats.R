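test_that("window scheme: width L/(N/50), half-width steps, full coverage", {
  w <- window_spec(1e6, N = 1000)
  expect_equal(attr(w, "width"), 5e4)
  expect_equal(attr(w, "step"), 2.5e4)
  expect_equal(w$start[1], 0)
  expect_true(all(diff(w$start) == 2.5e4))
  expect_lte(max(w$end), 1e6)
  # every interior position is covered by exactly two windows
  for (pos in c(30000, 5e5, 987654)) {
    hits <- sum(pos >= w$start & pos < w$end)
    expect_identical(hits, 2L)
  }
  w10k <- window_spec(1e6, N = 10000)
  expect_equal(attr(w10k, "width"), 5e3)
})

test_that("windowed pi matches the all-pairs brute force", {
  w <- window_spec(1000, width = 1000)
  m <- toy_matrix(matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE),
                  positions = c(200, 700))
  expect_equal(nucleotide_diversity(m, "all", w)[1], (2 / 3 + 2 / 3) / 1000)
  set.seed(30)
  for (i in 1:20) {
    rm <- random_matrix(10, 20)
    w2 <- window_spec(1000, width = 400)
    got <- nucleotide_diversity(rm, "all", w2)
    want <- sapply(seq_len(nrow(w2)), function(j) {
      oracle_pi(rm$mat, rm$positions, w2$start[j], w2$end[j])
    })
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Tajima's D: brute-force agreement, sign convention, missing windows", {
  # one singleton among 4 haplotypes: classic negative D, so -D > 0
  m <- toy_matrix(matrix(c(1, 0, 0, 0), 4, 1), positions = 500)
  w <- window_spec(1000, width = 1000)
  expect_gt(tajimas_d(m, "all", w)[1], 0)
  expect_equal(tajimas_d(m, "all", w)[1],
               -oracle_tajima_d(m$mat, m$positions, 0, 1000),
               tolerance = 1e-12)
  # S = 0 window is missing, not zero
  empty <- toy_matrix(matrix(0L, 4, 0), numeric(0))
  expect_true(is.na(tajimas_d(empty, "all", w)[1]))
  set.seed(31)
  for (i in 1:10) {
    rm <- random_matrix(12, 25)
    w2 <- window_spec(1000, width = 500)
    got <- tajimas_d(rm, "all", w2)
    want <- -sapply(seq_len(nrow(w2)), function(j) {
      oracle_tajima_d(rm$mat, rm$positions, w2$start[j], w2$end[j])
    })
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("statistics are invariant to row and column order", {
  set.seed(32)
  rm <- random_matrix(8, 15)
  w <- window_spec(1000, width = 500)
  perm_rows <- sample(8)
  m2 <- toy_matrix(rm$mat[perm_rows, ], rm$positions)
  expect_equal(nucleotide_diversity(rm, "all", w),
               nucleotide_diversity(m2, "all", w))
  expect_equal(tajimas_d(rm, "all", w), tajimas_d(m2, "all", w))
})

test_that("Hudson F_ST: identical pops 0, fixed differences 1, standardization", {
  w <- window_spec(1000, width = 250)
  base <- random_matrix(4, 12)
  dup <- toy_matrix(rbind(base$mat, base$mat), base$positions,
                    n1 = 4, n2 = 4)
  raw <- hudson_fst(dup, "sel", "neu", w)
  expect_true(all(abs(raw[!is.na(raw)]) < 1e-12))
  # fixed difference at every site, no within-pop variation
  fixd <- toy_matrix(rbind(matrix(1L, 3, 5), matrix(0L, 3, 5)),
                     positions = seq(100, 900, length.out = 5),
                     n1 = 3, n2 = 3)
  rawf <- hudson_fst(fixd, "sel", "neu", w)
  expect_true(all(rawf[!is.na(rawf)] == 1))
  set.seed(33)
  mixed <- toy_matrix(random_matrix(8, 30)$mat,
                      sort(runif(30, 0, 1000)), n1 = 4, n2 = 4)
  std <- mean_standardize(hudson_fst(mixed, "sel", "neu", w))
  expect_equal(mean(std, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(std, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(mean_standardize(c(1, NA, NA)), ">= 2 defined")
})

test_that("EHH is 1 at the focal site and non-increasing outward", {
  set.seed(34)
  for (i in 1:10) {
    rm <- random_matrix(12, 18)
    cnt <- colSums(rm$mat)
    focal <- which(cnt >= 2 & cnt <= 10)[1]
    skip_if(is.na(focal))
    curve <- ehh(rm, "all", focal, allele = 1L)
    fi <- which(curve$position == rm$positions[focal])
    expect_equal(curve$ehh[fi], 1)
    expect_true(all(diff(curve$ehh[fi:nrow(curve)]) <= 1e-12))
    expect_true(all(diff(rev(curve$ehh[1:fi])) <= 1e-12))
  }
  expect_error(ehh(toy_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1), 500),
                   "all", 1, allele = 1L), "fewer than 2")
})

test_that("iHH integrates the EHH curve with truncation at the cutoff", {
  # hand-built curve: focal at 500, EHH 1 -> 0.5 -> 0.04 rightwards;
  # truncation keeps the [500, 600] trapezoid only
  curve <- data.frame(position = c(400, 500, 600, 700),
                      ehh = c(0.5, 1, 0.5, 0.04))
  got <- ihh(curve, 500, cutoff = 0.05)
  expect_equal(got, 100 * (1 + 0.5) / 2 + 100 * (0.5 + 1) / 2)
})

test_that("XP-EHH is 0 for identical populations; iHS respects the maf floor", {
  set.seed(35)
  base <- random_matrix(6, 20)
  dup <- toy_matrix(rbind(base$mat, base$mat), base$positions, n1 = 6, n2 = 6)
  xp <- xpehh(dup)
  expect_true(all(abs(xp$xpehh_raw[!is.na(xp$xpehh_raw)]) < 1e-12))
  rm <- random_matrix(20, 25)
  tbl <- ihs(rm, "all", maf = 0.2)
  p <- tbl$freq
  expect_true(all(pmin(p, 1 - p) >= 0.2))
  std <- standardize_ihs(rbind(tbl, tbl, tbl))
  ok <- !is.na(std$ihs)
  skip_if(!any(ok))
  expect_lt(abs(mean(std$ihs[ok])), 1)  # roughly centred after binning
})
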