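test_that("cauchyProfile matches the closed form and its symmetries", {
  expect_equal(cauchyProfile(0), 1 / pi)
  expect_equal(cauchyProfile(1), 1 / (2 * pi))   # halved at x = gamma
  expect_equal(cauchyProfile(2), cauchyProfile(-2))
  expect_equal(cauchyProfile(3, gamma = 2, x0 = 3), 1 / (2 * pi))
  expect_true(all(cauchyProfile(seq(-50, 50, 0.5)) > 0))
  # peak at x0
  xs <- seq(-5, 5, 0.01)
  expect_equal(xs[which.max(cauchyProfile(xs, x0 = 1.5))], 1.5)
  expect_error(cauchyProfile(0, gamma = 0), "gamma")
  expect_error(cauchyProfile(0, gamma = -1), "gamma")
})

test_that("buildKernel produces the negated, mean-subtracted L x T template", {
  k <- buildKernel(cauchyParams())
  expect_identical(dim(k), c(8L, 9L))
  expect_lt(abs(sum(k)), 1e-10 * 72 * max(abs(k)))
  # every row is identical
  expect_true(all(apply(k, 2, function(col) diff(range(col)) == 0)))
  # centre column held the pre-subtraction minimum -1/pi in every row
  expect_equal(unname(k[, 5]), rep(-1 / pi - mean(-cauchyProfile(-4:4)), 8))
  expect_true(all(k[, 5] <= k))  # centre column is the minimum
  # non-default size
  k2 <- buildKernel(cauchyParams(T = 5L, L = 3L))
  expect_identical(dim(k2), c(3L, 5L))
  expect_lt(abs(sum(k2)), 1e-10 * 15 * max(abs(k2)))
})

test_that("parameter validation rejects out-of-domain configurations", {
  expect_error(cauchyParams(gamma = -1), "gamma")
  expect_error(cauchyParams(T = 8L), "odd")
  expect_error(cauchyParams(T = 1L), "odd")
  expect_error(cauchyParams(L = 0L), "positive")
  expect_error(cauchyParams(nOrientations = 0L), "positive")
})

test_that("buildBank rotates the embedded template over [0, pi)", {
  bank <- buildBank(cauchyParams())
  expect_length(bankKernels(bank), 12)
  expect_equal(bankOrientations(bank), (0:11) * pi / 12)
  expect_equal(diff(bankOrientations(bank)), rep(pi / 12, 11))
  side <- nrow(bankKernels(bank)[[1]])
  expect_identical(side, 13L)          # smallest odd side >= sqrt(9^2+8^2)
  expect_identical(side %% 2L, 1L)
  # k = 0 kernel is the embedded unrotated base kernel
  base <- buildKernel(cauchyParams())
  emb <- matrix(0, side, side)
  emb[2 + seq_len(8), 2 + seq_len(9)] <- base
  expect_equal(bankKernels(bank)[[1]], emb - mean(emb), tolerance = 1e-12)
  # every rotated kernel is zero-mean
  for (k in bankKernels(bank))
    expect_lt(abs(mean(k)), 1e-10 * max(abs(k)))
})

test_that("maxResponse annihilates constants and matches the brute-force oracle", {
  bank <- defaultBank()
  expect_lt(max(abs(maxResponse(matrix(0.7, 30, 30), bank))), 1e-6)

  set.seed(42)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(maxResponse(img, bank),
               bruteMaxResponse(img, bankKernels(bank)),
               tolerance = 1e-8)
  # also with a non-default bank (fewer orientations, other size)
  bank2 <- buildBank(cauchyParams(T = 5L, L = 4L, nOrientations = 4L))
  img2 <- matrix(runif(24 * 24), 24, 24)
  expect_equal(maxResponse(img2, bank2),
               bruteMaxResponse(img2, bankKernels(bank2)),
               tolerance = 1e-8)
  expect_error(maxResponse(matrix(c(1, NA, 1, 1), 2), bank), "finite")
})

test_that("the maximizing orientation tracks the vessel angle at all 12 bank angles", {
  bank <- defaultBank()
  for (k in 0:11) {
    theta <- k * pi / 12
    img <- barImage(64, theta, barWidth = 3)
    center <- barCenterline(64, theta)
    means <- vapply(bankKernels(bank), function(kn) {
      single <- new("MatchedFilterBank", kernels = list(kn),
                    orientations = 0,
                    params = cauchyParams(nOrientations = 1L))
      mean(maxResponse(img, single)[center])
    }, numeric(1))
    expect_identical(which.max(means) - 1L, k,
                     label = sprintf("argmax orientation for theta index %d", k))
  }
})

test_that("deeper vessels never reduce the centreline response", {
  bank <- defaultBank()
  img1 <- barImage(48, 0, barWidth = 3, bg = 1, fg = 0.8)   # shallow dip
  img2 <- barImage(48, 0, barWidth = 3, bg = 1, fg = 0.6)   # doubled depth
  center <- barCenterline(48, 0)
  expect_gte(mean(maxResponse(img2, bank)[center]),
             mean(maxResponse(img1, bank)[center]))
})

test_that("rescaleUnit maps affinely onto [0,1] with a degenerate-constant rule", {
  expect_equal(rescaleUnit(matrix(c(0, 10, 5, 5), 2)),
               matrix(c(0, 1, 0.5, 0.5), 2))
  expect_equal(rescaleUnit(matrix(3, 4, 4)), matrix(0, 4, 4))
  set.seed(1)
  r <- rescaleUnit(matrix(rnorm(100), 10))
  expect_equal(range(r), c(0, 1))
  expect_error(rescaleUnit(matrix(c(1, Inf, 0, 0), 2)), "finite")
})
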