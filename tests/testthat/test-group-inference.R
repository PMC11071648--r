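test_that("the default group design has the documented structure", {
  co <- toyCohort(30)
  des <- buildDesign(co)
  x <- designMatrix(des)
  expect_equal(colnames(x),
               c("intercept", "age_c", "age_c2", "sex", "sex_age",
                 "sex_age2"))
  expect_lt(abs(sum(x[, "age_c"])), 1e-10)
  expect_setequal(unique(x[, "sex"]), c(0.5, -0.5))
  expect_equal(qr(x)$rank, 6L)
  cov <- matrix(rnorm(30), ncol = 1)
  expect_equal(ncol(designMatrix(buildDesign(co, cov))), 7L)
  constCo <- new("Cohort", table = data.frame(
    subject_id = c("a", "b"), age = c(30, 30),
    sex = c("male", "female")))
  expect_error(buildDesign(constCo), "constant")
  expect_error(contrastVector(des, "nope"), "no design column")
})

test_that("vertex GLM t equals the closed-form simple-regression t", {
  set.seed(1)
  n <- 10
  x <- rnorm(n)
  y <- matrix(0.4 * x + rnorm(n), ncol = 1)
  design <- cbind(intercept = 1, x = x)
  stat <- fitVertexGLM(y, design, c(0, 1))
  r <- cor(x, y[, 1])
  tOracle <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(stat@t, tOracle, tolerance = 1e-10)
  expect_equal(stat@df, n - 2)
})

test_that("vertex GLM matches lm() on random instances", {
  set.seed(2)
  co <- toyCohort(20)
  des <- buildDesign(co)
  maps <- matrix(rnorm(20 * 15), nrow = 20)
  ct <- contrastVector(des, "age_c")
  stat <- fitVertexGLM(maps, des, ct, "age_lin")
  x <- designMatrix(des)
  for (v in c(1, 7, 15)) {
    fit <- lm(maps[, v] ~ x - 1)
    sm <- summary(fit)$coefficients
    expect_equal(stat@t[v], sm["xage_c", "t value"], tolerance = 1e-8)
    expect_equal(stat@p[v], sm["xage_c", "Pr(>|t|)"], tolerance = 1e-8)
  }
  expect_error(fitVertexGLM(maps, des, rep(0, 6)), "zero")
  expect_error(fitVertexGLM(maps[1:5, ], designMatrix(des)[1:5, ], ct),
               "more subjects")
})

test_that("uncorrected vertexwise type-I error matches alpha on null maps", {
  set.seed(3)
  co <- toyCohort(30)
  des <- buildDesign(co)
  maps <- matrix(rnorm(30 * 10000), nrow = 30)
  stat <- fitVertexGLM(maps, des, contrastVector(des, "age_c"))
  rate <- mean(stat@p < 0.05)
  # binomial 99.9% band around 0.05 over 10,000 tests
  expect_gt(rate, 0.05 - 3.3 * sqrt(0.05 * 0.95 / 10000))
  expect_lt(rate, 0.05 + 3.3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("a planted age slope produces strong network-level t values", {
  surf <- makeMesh(2)
  co <- makeCohort(n = 60, nMale = 25, seed = 4)
  des <- buildDesign(co)
  ages <- cohortTable(co)$age - mean(cohortTable(co)$age)
  patch <- which(socotraj:::.surfaceGeodesicTo(surf, 1) < 55)
  maps <- randomSmoothMaps(60, surf, fwhm_mm = 0, seed = 4)
  maps[, patch] <- maps[, patch] +
    outer(ages, rep(0.05, length(patch)))
  stat <- fitVertexGLM(maps, des, contrastVector(des, "age_c"))
  expect_gt(mean(stat@t[patch]), 3)
  expect_gt(mean(stat@beta[patch]), 0)   # sign convention
})

test_that("smoothness estimation matches theory for white and smoothed noise", {
  surf <- makeMesh(2)
  resid <- randomSmoothMaps(40, surf, fwhm_mm = 0, seed = 5)
  est <- estimateSmoothness(resid, surf)
  h <- mean(socotraj:::.edgeLengths(surf@left))
  expect_lt(abs(est@fwhm - h * sqrt(2 * log(2))) / (h * sqrt(2 * log(2))),
            0.2)
  expect_equal(unname(est@resels[1]), 4)    # two spheres
  expect_equal(unname(est@resels[2]), 0)
  area <- 2 * sum(triangleAreas(surf@left))
  expect_equal(unname(est@resels[3]), area / est@fwhm^2, tolerance = 1e-10)
  # kernel-smoothed noise recovers the kernel width
  sm <- randomSmoothMaps(40, surf, fwhm_mm = 60, seed = 6)
  est2 <- estimateSmoothness(sm, surf)
  expect_lt(abs(est2@fwhm - 60) / 60, 0.25)
  # doubling the mesh scale doubles the FWHM on the same data
  big <- makeMesh(2, radius_mm = 200)
  expect_equal(estimateSmoothness(sm, big)@fwhm, 2 * est2@fwhm,
               tolerance = 1e-10)
  # zero-variance vertices are excluded with a warning
  degenerate <- resid
  degenerate[, 5] <- 0
  expect_warning(estimateSmoothness(degenerate, surf), "zero-variance")
  expect_error(estimateSmoothness(resid[1:2, ], surf), "at least 3")
})

test_that("RFT correction returns sensible, monotone cluster p-values", {
  surf <- makeMesh(2)
  v <- nVertices(surf)
  sm <- new("SmoothnessEstimate", fwhm = 35,
            resels = c(4, 0, 2 * sum(triangleAreas(surf@left)) / 35^2))
  # sub-threshold map: empty result
  quiet <- new("VertexStatMap", beta = numeric(v), t = rep(0.5, v),
               p = rep(0.6, v), df = 50, contrast = "c",
               residuals = matrix(rnorm(3 * v), nrow = 3))
  expect_equal(nrow(clusterTable(
    rftClusterCorrect(quiet, sm, surf))), 0L)
  # two clusters, equal peak, different area -> larger area, smaller p
  adj <- surfaceAdjacency(surf)
  tval <- rep(0, v)
  big <- c(1, adj[[1]])                  # a vertex and its neighbours
  small <- big[length(big)] + 50
  tval[big] <- 6
  tval[small] <- 6
  stat <- new("VertexStatMap", beta = tval, t = tval, p = tval, df = 50,
              contrast = "c", residuals = matrix(rnorm(3 * v), nrow = 3))
  res <- clusterTable(rftClusterCorrect(stat, sm, surf))
  expect_equal(nrow(res), 2L)
  expect_lt(res$p_corrected[1], res$p_corrected[2])
  expect_gt(res$area_mm2[1], res$area_mm2[2])
  expect_error(rftClusterCorrect(stat, sm, surf, alpha = 1.5), "alpha")
  expect_error(rftClusterCorrect(stat, sm, surf, clusterFormingZ = -1),
               "positive")
})

test_that("RFT stays conservative-to-calibrated on unsmoothed null maps", {
  surf <- makeMesh(2)
  co <- makeCohort(n = 40, nMale = 20, seed = 7)
  des <- buildDesign(co)
  ct <- contrastVector(des, "age_c")
  rej <- vapply(1:100, function(r) {
    maps <- randomSmoothMaps(40, surf, fwhm_mm = 0, seed = 1000 + r)
    stat <- fitVertexGLM(maps, des, ct)
    smo <- estimateSmoothness(stat@residuals, surf)
    any(clusterTable(rftClusterCorrect(stat, smo, surf))$significant)
  }, TRUE)
  expect_lte(mean(rej), 0.10)
})

test_that("permutation correction has its estimator floor and finds strong effects", {
  surf <- makeMesh(2)
  co <- makeCohort(n = 40, nMale = 20, seed = 8)
  des <- buildDesign(co)
  ct <- contrastVector(des, "age_c")
  ages <- cohortTable(co)$age - mean(cohortTable(co)$age)
  maps <- randomSmoothMaps(40, surf, fwhm_mm = 50, seed = 9)
  patch <- which(socotraj:::.surfaceGeodesicTo(surf, 1) < 55)
  maps[, patch] <- maps[, patch] + outer(ages, rep(0.08, length(patch)))
  res <- permutationCorrect(maps, des, ct, surf, nPerm = 199, seed = 1)
  tab <- clusterTable(res)
  expect_true(all(tab$p_corrected >= 1 / 200))
  expect_equal(min(tab$p_corrected), 1 / 200)    # strong effect at the floor
  top <- res@members[[1]]
  expect_gt(length(intersect(top, patch)), 0)
  expect_error(permutationCorrect(maps, des, ct, surf, nPerm = 50),
               "nPerm")
  expect_error(permutationCorrect(maps, des, rep(1, 6), surf, nPerm = 100),
               "single-column")
})

test_that("RFT and permutation agree on planted-effect clusters", {
  surf <- makeMesh(2)
  co <- makeCohort(n = 40, nMale = 20, seed = 10)
  des <- buildDesign(co)
  ct <- contrastVector(des, "age_c")
  ages <- cohortTable(co)$age - mean(cohortTable(co)$age)
  patch <- which(socotraj:::.surfaceGeodesicTo(surf, 1) < 55)
  agree <- 0L
  for (r in 1:20) {
    maps <- randomSmoothMaps(40, surf, fwhm_mm = 50, seed = 2000 + r)
    maps[, patch] <- maps[, patch] + outer(ages, rep(0.06, length(patch)))
    stat <- fitVertexGLM(maps, des, ct)
    smo <- estimateSmoothness(stat@residuals, surf)
    rft <- rftClusterCorrect(stat, smo, surf)
    prm <- permutationCorrect(maps, des, ct, surf, nPerm = 199,
                              seed = 3000 + r)
    sigIn <- function(res) {
      hit <- vapply(res@members,
                    function(m) length(intersect(m, patch)) > 0, TRUE)
      any(hit & clusterTable(res)$significant)
    }
    agree <- agree + (sigIn(rft) == sigIn(prm))
  }
  expect_gte(agree / 20, 0.8)
})
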