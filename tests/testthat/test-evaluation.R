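randomRasters <- function(seed, n = 16) {
  withr::with_seed(seed, list(
    pred = matrix(rbinom(n * n, 1, 0.4), n),
    gt = matrix(rbinom(n * n, 1, 0.3), n),
    fov = matrix(rbinom(n * n, 1, 0.8), n),
    prob = matrix(runif(n * n), n)))
}

test_that("confusionCounts matches the brute-force counting oracle", {
  for (seed in 1:5) {
    r <- randomRasters(seed)
    counts <- confusionCounts(r$pred, r$gt, r$fov)
    expect_identical(counts, bruteConfusion(r$pred, r$gt, r$fov))
    expect_identical(sum(counts), as.integer(sum(r$fov)))
  }
  r <- randomRasters(6)
  # perfect and inverted predictions
  expect_true(all(confusionCounts(r$gt, r$gt, r$fov)[c("FP", "FN")] == 0))
  inv <- confusionCounts(1 - r$gt, r$gt, r$fov)
  expect_true(all(inv[c("TP", "TN")] == 0))
  expect_error(confusionCounts(r$pred, r$gt[1:8, 1:8], r$fov), "dimensions")
  expect_error(confusionCounts(r$prob, r$gt, r$fov), "0/1")
})

test_that("segMetrics computes the four ratios with undefined 0/0 cells", {
  m <- segMetrics(c(TP = 40, TN = 50, FP = 5, FN = 5))
  expect_equal(m[["acc"]], 0.90)
  expect_equal(round(m[["sen"]], 4), 0.8889)
  expect_equal(round(m[["spc"]], 4), 0.9091)
  expect_equal(round(m[["prc"]], 4), 0.8889)
  # perfect prediction limit
  expect_equal(unname(segMetrics(c(TP = 10, TN = 20, FP = 0, FN = 0))),
               rep(1, 4))
  # numerator-zero and undefined cases
  expect_equal(segMetrics(c(TP = 0, TN = 5, FP = 0, FN = 5))[["sen"]], 0)
  expect_true(is.na(segMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))[["sen"]]))
  expect_true(is.na(segMetrics(c(TP = 0, TN = 5, FP = 0, FN = 5))[["prc"]]))
  expect_error(segMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("rocSweep matches per-threshold brute-force recomputation", {
  r <- randomRasters(7)
  taus <- seq(0.05, 0.95, by = 0.05)
  pts <- rocSweep(r$prob, r$gt, r$fov, taus)
  # brute force: one confusion per threshold via the counting oracle
  brute <- t(vapply(taus, function(tau) {
    cc <- bruteConfusion((r$prob >= tau) * 1, r$gt, r$fov)
    c(cc[["FP"]] / (cc[["FP"]] + cc[["TN"]]),
      cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]))
  }, numeric(2)))
  brute <- rbind(brute, c(0, 0), c(1, 1))
  brute <- brute[order(brute[, 1], brute[, 2]), ]
  expect_equal(unname(pts), unname(brute))
  expect_true(!is.unsorted(pts[, 1]))
  expect_error(rocSweep(r$prob, matrix(1, 16, 16), r$fov), "all vessel")
  expect_error(rocSweep(r$prob, matrix(0, 16, 16), r$fov), "background")
  expect_error(rocSweep(r$prob, r$gt, r$fov, taus = c(0.5, 0.2)), "increasing")
})

test_that("ROC is monotone in the threshold and conserves class totals", {
  r <- randomRasters(8)
  taus <- seq(0.01, 0.99, by = 0.01)
  sel <- r$fov == 1
  nPos <- sum(r$gt[sel] == 1); nNeg <- sum(r$gt[sel] == 0)
  prev <- c(Inf, Inf)
  for (tau in taus) {
    cc <- confusionCounts((r$prob >= tau) * 1, r$gt, r$fov)
    expect_identical(cc[["TP"]] + cc[["FN"]], nPos)
    expect_identical(cc[["TN"]] + cc[["FP"]], nNeg)
    cur <- c(cc[["FP"]] / nNeg, cc[["TP"]] / nPos)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("aurocTrapezoid integrates reference geometries and rejects bad input", {
  expect_equal(aurocTrapezoid(rbind(c(0, 0), c(1, 1))), 0.5)
  expect_equal(aurocTrapezoid(rbind(c(0, 0), c(0, 1), c(1, 1))), 1.0)
  expect_equal(aurocTrapezoid(rbind(c(0, 0), c(0.5, 0.5), c(1, 1))), 0.5)
  expect_error(aurocTrapezoid(rbind(c(0, 0), c(2, 1))), "\\[0, 1\\]")
  expect_error(aurocTrapezoid(rbind(c(0.5, 0), c(0.2, 1), c(1, 1))), "sorted")
  expect_error(aurocTrapezoid(rbind(c(0.1, 0), c(1, 1))), "start")
})

test_that("perfect separation yields AUROC 1; random scores chance level", {
  r <- randomRasters(9)
  # prob equal to gt: curve passes through (0, 1)
  pts <- rocSweep(r$gt, r$gt, r$fov)
  expect_true(any(pts[, 1] == 0 & pts[, 2] == 1))
  expect_equal(aurocTrapezoid(pts), 1.0)
  # uniform random scores on balanced labels, 10,000 pixels
  withr::with_seed(10, {
    gt <- matrix(rbinom(10000, 1, 0.5), 100)
    prob <- matrix(runif(10000), 100)
  })
  auroc <- aurocTrapezoid(rocSweep(prob, gt, matrix(1, 100, 100)))
  expect_lt(abs(auroc - 0.5), 0.02)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  # mapping the threshold grid through the same transform leaves every
  # binarization, hence the ROC vertex set, unchanged
  r <- randomRasters(11)
  taus <- seq(0.001, 0.999, 0.001)
  a1 <- aurocTrapezoid(rocSweep(r$prob, r$gt, r$fov, taus = taus))
  a2 <- aurocTrapezoid(rocSweep(r$prob^3, r$gt, r$fov, taus = taus^3))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("tauSensitivity rows equal independently recomposed metrics", {
  r <- randomRasters(12)
  taus <- seq(0.1, 0.9, by = 0.1)
  tab <- tauSensitivity(r$prob, r$gt, r$fov, taus)
  expect_identical(nrow(tab), length(taus))
  i <- 4
  m <- segMetrics(confusionCounts((r$prob >= taus[i]) * 1, r$gt, r$fov))
  expect_equal(unlist(tab[i, -1], use.names = FALSE), unname(m))
  # default grid has 99 rows; sen non-increasing, spc non-decreasing
  full <- tauSensitivity(r$prob, r$gt, r$fov)
  expect_identical(nrow(full), 99L)
  expect_true(all(diff(full$sen) <= 1e-12))
  expect_true(all(diff(full$spc) >= -1e-12))
})

test_that("evaluateSegmentation bundles counts, metrics, ROC and the tau table", {
  r <- randomRasters(13)
  rep <- evaluateSegmentation(r$prob, r$gt, r$fov, tau = 0.5)
  expect_s4_class(rep, "EvalReport")
  expect_identical(rep@counts,
                   confusionCounts((r$prob >= 0.5) * 1, r$gt, r$fov))
  expect_equal(rep@auroc, aurocTrapezoid(rep@roc))
  expect_identical(nrow(rep@tauTable), 99L)
  expect_output(show(rep), "AUROC")
})

test_that("package AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  r <- randomRasters(14)
  sel <- r$fov == 1
  ref <- as.numeric(pROC::auc(pROC::roc(r$gt[sel], r$prob[sel],
                                        quiet = TRUE, direction = "<")))
  ours <- aurocTrapezoid(rocSweep(r$prob, r$gt, r$fov,
                                  taus = sort(unique(r$prob[sel]))[-1]))
  expect_equal(ours, ref, tolerance = 1e-10)
})
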