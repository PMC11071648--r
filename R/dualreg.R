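#' @include AllClasses.R
NULL

# Names the most collinear pair of seed maps for a helpful rank error.
.collinearPair <- function(weights, names) {
  cm <- abs(stats::cor(t(weights)))
  diag(cm) <- 0
  ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  paste(names[ij[1]], "and", names[ij[2]])
}

#' Dual regression, stage 1 (spatial)
#'
#' Regresses each timepoint's vertex vector jointly on all group seed maps
#' (plus an intercept over vertices), yielding one coefficient time series
#' per seed: the subject-specific temporal expression of each group
#' component.
#'
#' @param run a [BoldRun] whose vertex count matches the seed maps.
#' @param seeds a [SeedMapSet] with linearly independent rows.
#' @param demeanMaps center each seed map over vertices before regression.
#' @return numeric matrix (T x n_seeds) of time courses, columns named by
#'   seed.
#' @export
stage1Spatial <- function(run, seeds, demeanMaps = TRUE) {
  w <- seedWeights(seeds)
  if (ncol(w) != ncol(run@data))
    stop("seed maps cover ", ncol(w), " vertices but the run has ",
         ncol(run@data), call. = FALSE)
  s <- t(w)                                   # V x n_seeds
  if (demeanMaps) s <- scale(s, center = TRUE, scale = FALSE)
  if (qr(s)$rank < ncol(s))
    stop("seed maps are collinear (", .collinearPair(w, seedNames(seeds)),
         "); stage-1 design is rank deficient", call. = FALSE)
  x <- cbind(intercept = 1, s)
  coef <- qr.solve(x, t(run@data))            # (n_seeds+1) x T
  a <- t(coef[-1L, , drop = FALSE])
  colnames(a) <- seedNames(seeds)
  a
}

#' Dual regression, stage 2 (temporal)
#'
#' Regresses each vertex's time series jointly on the stage-1 time courses
#' (plus an intercept). With `varianceNormalize` (the default) the courses
#' are scaled to unit variance first, so the resulting spatial betas are in
#' signal units and comparable across subjects.
#'
#' @param run a [BoldRun].
#' @param timecourses numeric matrix (T x n_seeds) from [stage1Spatial()].
#' @param varianceNormalize scale each time course to unit variance.
#' @return numeric matrix (n_seeds x V) of spatial maps.
#' @export
stage2Temporal <- function(run, timecourses, varianceNormalize = TRUE) {
  if (nrow(timecourses) != nrow(run@data))
    stop("timecourses have ", nrow(timecourses),
         " rows but the run has ", nrow(run@data), call. = FALSE)
  a <- timecourses
  if (varianceNormalize) {
    sds <- apply(a, 2L, stats::sd)
    if (any(sds < 1e-12))
      stop("time course(s) with zero variance cannot be normalized: ",
           paste(colnames(a)[sds < 1e-12], collapse = ", "), call. = FALSE)
    a <- sweep(a, 2L, sds, "/")
  }
  if (qr(a)$rank < ncol(a))
    stop("stage-2 time courses are rank deficient", call. = FALSE)
  x <- cbind(intercept = 1, a)
  coef <- qr.solve(x, run@data)               # (n_seeds+1) x V
  maps <- coef[-1L, , drop = FALSE]
  rownames(maps) <- colnames(timecourses)
  maps
}

#' Two-stage dual regression
#'
#' Composition of [stage1Spatial()] and [stage2Temporal()] with residual
#' variance bookkeeping; deterministic.
#'
#' @inheritParams stage1Spatial
#' @inheritParams stage2Temporal
#' @return a [DRFit].
#' @examples
#' surf <- makeMesh(1)
#' parc <- makeParcellation(surf, 7, seed = 1)
#' maps <- makeSeedMaps(surf, seed = 1)
#' co <- makeCohort(n = 2, nMale = 1, seed = 1)
#' run <- simulateBold(surf, parc, maps, co, tPoints = 60, seed = 1)[[1]]
#' dualRegress(run, maps)
#' @export
dualRegress <- function(run, seeds, demeanMaps = TRUE,
                        varianceNormalize = TRUE) {
  a <- stage1Spatial(run, seeds, demeanMaps = demeanMaps)
  w <- seedWeights(seeds)
  s <- t(w)
  if (demeanMaps) s <- scale(s, center = TRUE, scale = FALSE)
  x1 <- cbind(1, s)
  r1 <- t(run@data) - x1 %*% qr.solve(x1, t(run@data))
  maps <- stage2Temporal(run, a, varianceNormalize = varianceNormalize)
  an <- if (varianceNormalize) sweep(a, 2L, apply(a, 2L, stats::sd), "/")
        else a
  x2 <- cbind(1, an)
  r2 <- run@data - x2 %*% qr.solve(x2, run@data)
  new("DRFit", subjectId = run@subjectId, timecourses = a, maps = maps,
      stage1ResidualVar = mean(r1^2), stage2ResidualVar = mean(r2^2),
      varianceNormalized = varianceNormalize)
}
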