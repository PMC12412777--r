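test_that("DVH curves match the counting oracle on random fixtures", {
  set.seed(20)
  for (rep in 1:30) {
    d <- c(6, 5, 4)
    dose <- array(runif(prod(d), 0, 70), d)
    mask <- array(as.numeric(runif(prod(d)) < 0.5), d)
    if (sum(mask) == 0) mask[1, 1, 1] <- 1
    curve <- dvh(dose, mask, n_bins = 100)
    voxels <- dose[mask == 1]
    oracle <- vapply(curve$dose_Gy, function(t) mean(voxels >= t), numeric(1))
    expect_equal(curve$volume_fraction, oracle, tolerance = 1e-12)
    expect_true(all(diff(curve$volume_fraction) <= 0))
    expect_equal(curve$volume_fraction[1], 1)
  }
})

test_that("DVH step cases: uniform dose and two dose levels", {
  d <- c(4, 4, 2)
  mask <- array(1, d)
  uniform <- dvh(array(50, d), mask, n_bins = 10)
  expect_true(all(uniform$volume_fraction[uniform$dose_Gy <= 50] == 1))

  two <- array(20, d); two[1:2, , ] <- 60
  curve <- dvh(two, mask, n_bins = 100)
  mid <- curve$volume_fraction[curve$dose_Gy > 20 & curve$dose_Gy <= 60]
  expect_true(all(mid == 0.5))
  expect_error(dvh(array(1, d), array(0, d)), "empty")
})

test_that("Dx% follows the sorted-voxel order statistic", {
  expect_equal(dose_at_volume(rep(60, 40), 95), 60)
  d95 <- dose_at_volume(1:100, 95)
  expect_gte(d95, 5); expect_lte(d95, 6)
  expect_equal(dose_at_volume(c(3, 9, 7, 1), 100), 1)  # D100% = minimum
  expect_error(dose_at_volume(1:10, 0), "volume_pct")
  expect_error(dose_at_volume(1:10, 101), "volume_pct")
})

test_that("Dx% read off the DVH curve satisfies its defining property within a bin", {
  # the curve-based Dx is the largest grid dose still covering x% of the
  # volume: at that dose coverage is >= x%, one bin higher it drops below
  set.seed(22)
  for (rep in 1:10) {
    voxels <- runif(200, 10, 70)
    d <- c(200, 1, 1)
    curve <- dvh(array(voxels, d), array(1, d), n_bins = 1000)
    bin <- diff(curve$dose_Gy[1:2])
    for (x in c(2, 50, 95, 98, 99)) {
      dc <- dose_at_volume(curve, x)
      expect_gte(mean(voxels >= dc), x / 100)
      expect_lt(mean(voxels >= dc + bin + 1e-9), x / 100)
      # and it brackets the interpolated order statistic within the local
      # spacing of the sorted doses
      dv <- dose_at_volume(voxels, x)
      gap <- max(diff(sort(voxels)))
      expect_lt(abs(dc - dv), bin + gap + 1e-9)
    }
  }
})

test_that("homogeneity index matches its definition and is scale invariant", {
  expect_equal(homogeneity(60, 60, 60), 0)
  expect_equal(homogeneity(63, 57, 60), 0.1)
  expect_equal(homogeneity(63 * 3, 57 * 3, 60 * 3), 0.1)
  expect_error(homogeneity(63, 57, 0), "D50")
})

test_that("percent error is absolute, prescription-normalized and symmetric", {
  expect_equal(percent_error(60, 60, 70), 0)
  expect_equal(percent_error(72, 68.4, 72), 5)
  expect_equal(percent_error(68.4, 72, 72), 5)
  expect_error(percent_error(60, 60, 0), "prescription")
})

test_that("metric ordering invariants hold on many random fixtures", {
  set.seed(23)
  for (rep in 1:200) {
    v <- runif(sample(20:200, 1), 0, sample(c(20, 70), 1))
    d2 <- dose_at_volume(v, 2); d50 <- dose_at_volume(v, 50)
    d95 <- dose_at_volume(v, 95); d98 <- dose_at_volume(v, 98)
    d99 <- dose_at_volume(v, 99)
    expect_true(max(v) >= d2 && d2 >= d50 && d50 >= d95 &&
                  d95 >= d98 && d98 >= d99 && d99 >= 0)
  }
})

test_that("dose_metrics reports all indices per structure", {
  set.seed(24)
  d <- c(6, 6, 4)
  dose <- array(runif(prod(d), 0, 70), d)
  masks <- list(spinal_cord = array(1, d),
                parotid_left = array(as.numeric(runif(prod(d)) < 0.4), d),
                empty_one = array(0, d))
  rep <- dose_metrics(dose, masks)
  expect_equal(nrow(rep), 2)  # empty structure dropped
  row <- rep[rep$structure == "spinal_cord", ]
  expect_equal(row$Dmax, max(dose))
  expect_equal(row$Dmean, mean(dose))
  expect_equal(row$homogeneity, (row$D2 - row$D98) / row$D50)
})

test_that("paired Wilcoxon p-values match exact enumeration for n <= 10", {
  set.seed(25)
  for (n in c(5, 6, 8, 10)) {
    for (rep in 1:10) {
      a <- runif(n, 0, 10)
      b <- a + rnorm(n, 0.5, 1.2)          # tie-free paired errors
      expect_equal(paired_wilcoxon_p(a, b), exact_wilcoxon_p(a - b),
                   tolerance = 1e-10)
    }
  }
  # all differences of one sign: the opposing rank sum is zero, giving the
  # smallest attainable two-sided p at that n
  d <- 1:6
  expect_equal(exact_wilcoxon_p(d), 2 / 2^6, tolerance = 1e-12)
  expect_equal(paired_wilcoxon_p(d + 10, rep(10, 6)), 2 / 2^6, tolerance = 1e-10)
})

test_that("compare_plans reproduces hand-computed means and flags degeneracy", {
  set.seed(26)
  d <- c(5, 5, 4)
  masks_one <- list(spinal_cord = array(1, d))
  gt <- list(); pa <- list(); pb <- list(); masks <- list()
  for (i in 1:6) {
    gt[[i]] <- array(runif(prod(d), 20, 60), d)
    pa[[i]] <- gt[[i]] + rnorm(prod(d), 1, 0.3)
    pb[[i]] <- gt[[i]] + rnorm(prod(d), 3, 0.3)
    masks[[i]] <- masks_one
  }
  presc <- rep(60, 6)
  cmp <- compare_plans(gt, pa, pb, masks, presc)
  expect_equal(nrow(cmp), 2)  # Dmean and Dmax for one structure

  # hand-computed mean error for Dmean, model A
  errs <- vapply(1:6, function(i) {
    percent_error(mean(gt[[i]]), mean(pa[[i]]), 60)
  }, numeric(1))
  row <- cmp[cmp$metric == "Dmean", ]
  expect_equal(row$mean_a, mean(errs), tolerance = 1e-10)
  expect_equal(row$sd_a, sd(errs), tolerance = 1e-10)
  expect_false(row$degenerate)
  expect_true(row$mean_b > row$mean_a)

  # identical predictions: degenerate comparison, p = 1
  cmp2 <- compare_plans(gt, pa, pa, masks, presc)
  expect_true(all(cmp2$p_value == 1))
  expect_true(all(cmp2$degenerate))
  expect_false(any(cmp2$significant))

  expect_error(compare_plans(gt[1:3], pa, pb, masks, presc), "paired")
})
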