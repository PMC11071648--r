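test_that("noiseless runs are exact mixtures of the latent courses", {
  surf <- makeMesh(1)
  parc <- makeParcellation(surf, 1, seed = 1)
  maps <- makeSeedMaps(surf, nSeeds = 1, seed = 1)
  co <- toyCohort(2)
  runs <- simulateBold(surf, parc, maps, co, effects = list(),
                       tPoints = 30, noiseSd = 0, baseline = 0,
                       tissueWeight = 0, seed = 1)
  run <- runs[[1]]
  gen <- run@generative
  v <- nVertices(surf)
  m <- vapply(1L, function(i) as.numeric(parcelLabels(parc) == i), numeric(v))
  recon <- gen$networkCourses %*% t(m) + gen$seedCourses %*% seedWeights(maps)
  expect_equal(unname(boldData(run)), unname(recon), tolerance = 1e-12)
})

test_that("a constant planted coupling is recovered as latent correlation", {
  surf <- makeMesh(1)
  parc <- makeParcellation(surf, 7, seed = 1)
  maps <- makeSeedMaps(surf, seed = 1)
  co <- toyCohort(3)
  eff <- list(effectSpec("empathy", "Default", beta0 = 0.5))
  runs <- simulateBold(surf, parc, maps, co, effects = eff,
                       tPoints = 4000, ar1 = 0, seed = 2)
  cors <- vapply(runs, function(r)
    cor(r@generative$seedCourses[, 1],
        r@generative$networkCourses[, 7]), 1)
  expect_true(all(abs(cors - 0.5) < 0.06))
})

test_that("default repetition time is the multiband 645 ms", {
  surf <- makeMesh(0)
  parc <- makeParcellation(surf, 1, seed = 1)
  maps <- makeSeedMaps(surf, nSeeds = 1, seed = 1)
  runs <- simulateBold(surf, parc, maps, toyCohort(1), effects = list(),
                       tPoints = 20, seed = 1)
  expect_equal(boldTr(runs[[1]]), 0.645)
})

test_that("noise-free data rank is bounded by networks plus seeds", {
  surf <- makeMesh(1)
  parc <- makeParcellation(surf, 4, seed = 2)
  maps <- makeSeedMaps(surf, nSeeds = 2, seed = 2)
  runs <- simulateBold(surf, parc, maps, toyCohort(2),
                       effects = list(), tPoints = 40, noiseSd = 0,
                       baseline = 0, tissueWeight = 0, seed = 3)
  expect_lte(qr(boldData(runs[[1]]))$rank, 4 + 2)
})

test_that("planted coupling is monotone in the linear coefficient", {
  grid <- seq(0, 0.01, by = 0.002)
  w <- vapply(grid, function(b)
    plantedCoupling(effectSpec("empathy", "Visual", beta0 = 0.1,
                               betaLin = b), age = 83, sex = "male",
                    ageCenter = 44.38), 1)
  expect_true(all(diff(w) > 0))
})

test_that("simulation is byte-identical for a fixed seed and warns on clipping", {
  surf <- makeMesh(0)
  parc <- makeParcellation(surf, 7, seed = 1)
  maps <- makeSeedMaps(surf, seed = 1)
  co <- toyCohort(3)
  r1 <- simulateBold(surf, parc, maps, co, tPoints = 25, seed = 11)
  r2 <- simulateBold(surf, parc, maps, co, tPoints = 25, seed = 11)
  expect_identical(r1, r2)
  expect_warning(
    simulateBold(surf, parc, maps, co,
                 effects = list(effectSpec("empathy", "Default",
                                           beta0 = 2)),
                 tPoints = 25, seed = 1),
    "clipped")
})

test_that("simulation validates its inputs", {
  surf <- makeMesh(0)
  parc <- makeParcellation(surf, 7, seed = 1)
  maps <- makeSeedMaps(surf, seed = 1)
  co <- toyCohort(1)
  expect_error(simulateBold(surf, parc, maps, co, tPoints = 10), "tPoints")
  expect_error(simulateBold(surf, parc, maps, co, tPoints = 25,
                            noiseSd = -1), "noiseSd")
  expect_error(
    simulateBold(surf, parc, maps, co, tPoints = 25,
                 effects = list(effectSpec("nope", "Default"))),
    "not among the seed maps")
  expect_error(
    simulateBold(surf, parc, maps, co, tPoints = 25,
                 effects = list(effectSpec("empathy", "nope"))),
    "not among the parcellation")
})
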