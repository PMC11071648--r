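test_that("volume discard removes the leading timepoints everywhere", {
  run <- toyRun(t = 100, v = 5)
  out <- discardVolumes(run)
  expect_equal(nrow(boldData(out)), 92L)
  expect_equal(boldData(out), boldData(run)[9:100, ])
  expect_equal(motionParams(out), motionParams(run)[9:100, ])
  expect_identical(boldData(discardVolumes(run, 0)), boldData(run))
  expect_error(discardVolumes(toyRun(t = 8, v = 2)), "below the run length")
})

test_that("grand-mean scaling hits its target and guards degeneracy", {
  run <- toyRun(t = 30, v = 4)
  run@data <- run@data + 500
  out <- grandMeanScale(run)
  expect_equal(mean(boldData(out)), 10000, tolerance = 1e-10)
  expect_equal(boldData(grandMeanScale(out)), boldData(out),
               tolerance = 1e-12)
  zero <- toyRun(t = 20, v = 3)
  zero@data[] <- 0
  expect_error(grandMeanScale(zero), "zero")
})

test_that("the Friston expansion matches its definition", {
  set.seed(4)
  motion <- matrix(rnorm(60), ncol = 6)
  f <- friston24(motion)
  expect_equal(ncol(f), 24L)
  lag <- rbind(0, motion[-10, ])
  expect_equal(unname(f), unname(cbind(motion, lag, motion^2, lag^2)))
  expect_equal(unname(f[1, 7:12]), rep(0, 6))
  expect_equal(unname(f[1, 19:24]), rep(0, 6))
  expect_true(all(friston24(matrix(0, 10, 6)) == 0))
  expect_error(friston24(matrix(0, 10, 5)), "6")
})

test_that("nuisance regression projects out the design exactly", {
  run <- toyRun(t = 20, v = 6)
  des <- nuisanceDesign(run)
  out <- nuisanceRegress(run, des)
  x <- designMatrix(des)
  expect_lt(max(abs(crossprod(x, boldData(out)))), 1e-8)
  # oracle: per-column lm.fit residuals
  oracle <- apply(boldData(run), 2,
                  function(y) stats::lm.fit(x, y)$residuals)
  expect_equal(unname(boldData(out)), unname(oracle), tolerance = 1e-10)
  # idempotence
  expect_equal(boldData(nuisanceRegress(out, des)), boldData(out),
               tolerance = 1e-10)
  # intercept only = demeaning
  int <- new("NuisanceDesign",
             design = matrix(1, 20, 1, dimnames = list(NULL, "intercept")))
  expect_equal(unname(boldData(nuisanceRegress(run, int))),
               unname(scale(boldData(run), scale = FALSE)),
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- new("NuisanceDesign",
             design = matrix(1, 19, 1, dimnames = list(NULL, "intercept")))
  expect_error(nuisanceRegress(run, bad), "rows")
})

test_that("rank-deficient nuisance designs are handled by the pseudo-inverse", {
  run <- toyRun(t = 20, v = 3)
  x <- cbind(intercept = 1, a = rnorm(20))
  x <- cbind(x, b = x[, "a"])              # duplicated column
  colnames(x) <- c("intercept", "a", "b")
  des <- new("NuisanceDesign", design = x)
  out <- nuisanceRegress(run, des)
  expect_lt(max(abs(crossprod(x, boldData(out)))), 1e-8)
})

test_that("detrending removes polynomial trends up to degree two", {
  t <- 50
  tt <- seq_len(t)
  quad <- outer(tt, c(1, 2), function(i, j) 3 * j + 0.5 * j * i - 0.01 * i^2)
  run <- toyRun(t = t, v = 2, data = quad)
  out <- detrendRun(run)
  expect_lt(max(abs(boldData(out))), 1e-8)
  rnd <- toyRun(t = t, v = 4, seed = 5)
  det <- detrendRun(rnd)
  oracle <- apply(boldData(rnd), 2, function(y)
    stats::residuals(stats::lm(y ~ tt + I(tt^2))))
  expect_equal(unname(boldData(det)), unname(oracle), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(boldData(det)))), 1e-10)
  expect_error(detrendRun(toyRun(t = 2, v = 1)), "3 timepoints")
})

test_that("the band-pass filter has the right frequency response", {
  t <- 620; tr <- 0.645
  tt <- (seq_len(t) - 1) * tr
  inBand <- sin(2 * pi * 0.05 * tt)
  stopBand <- sin(2 * pi * 0.4 * tt)
  dc <- rep(3, t)
  run <- toyRun(t = t, v = 3, data = cbind(inBand, stopBand, dc), tr = tr)
  out <- boldData(bandpassFilter(run))
  mid <- 150:470
  expect_lt(max(abs(out[mid, 1] - inBand[mid])) / max(abs(inBand)), 0.05)
  expect_lt(max(abs(out[, 2])) / max(abs(stopBand)), 0.10)
  expect_lt(max(abs(out[, 3])), 1e-8)
  expect_error(bandpassFilter(run, 0.01, 1), "Nyquist")
  expect_error(bandpassFilter(run, 0.2, 0.1), "lowHz")
})

test_that("transforms preserve shape and record provenance in order", {
  surf <- makeMesh(0)
  parc <- makeParcellation(surf, 2, seed = 1)
  maps <- makeSeedMaps(surf, nSeeds = 1, seed = 1)
  run <- simulateBold(surf, parc, maps, toyCohort(1), effects = list(),
                      tPoints = 60, seed = 1)[[1]]
  out <- preprocessRun(run)
  expect_equal(ncol(boldData(out)), ncol(boldData(run)))
  expect_lte(nrow(boldData(out)), nrow(boldData(run)))
  expect_match(paste(out@provenance, collapse = " "),
               "discard.*grand_mean.*nuisance.*bandpass.*detrend")
  expect_error(preprocessRun(run, order = c("discard", "wat")), "unknown")
})
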