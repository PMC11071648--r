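#' @include mesh.R
NULL

# Great-circle distances (mm) from every vertex of a surface to one vertex,
# infinite across hemispheres (bumps stay within their hemisphere).
.surfaceGeodesicTo <- function(surface, focus) {
  vl <- nVertices(surface@left)
  hemi <- if (focus <= vl) "left" else "right"
  mesh <- slot(surface, hemi)
  idx <- if (hemi == "left") focus else focus - vl
  co <- mesh@coords
  r <- sqrt(sum(co[idx, ]^2))
  cosang <- pmin(1, pmax(-1, (co %*% co[idx, ]) / (rowSums(co^2) / r) / r))
  d <- r * acos(cosang)
  out <- rep(Inf, nVertices(surface))
  span <- if (hemi == "left") seq_len(vl) else vl + seq_len(nrow(co))
  out[span] <- d
  out
}

#' Generate smooth seed-network spatial maps
#'
#' Each seed map is a nonnegative sum of Gaussian geodesic bumps around a
#' handful of focus vertices, emulating continuous, unthresholded
#' meta-analytic network maps. Maps may overlap: `overlapFrac` is the
#' fraction of each seed's foci drawn from a pool shared by all seeds.
#' With three seeds (the default) the maps are named `empathy`, `ToM` and
#' `moral`.
#'
#' @param surface a [CorticalSurface].
#' @param nSeeds number of seed networks (>= 1).
#' @param overlapFrac fraction in \[0, 1\] of shared foci between seeds.
#' @param seed integer RNG seed.
#' @param fociPerSeed bump count per seed map.
#' @param fwhm_mm full width at half maximum of each bump (mm).
#' @param amplitude peak weight of each bump; the default of 4 puts the
#'   maps on the scale of meta-analytic z-value maps, well above the unit
#'   network fluctuations, which keeps the spatial-regression
#'   cross-talk between seed and network courses small.
#' @param foci optional list of integer vertex-id vectors, one per seed,
#'   overriding random focus placement (used for controlled geometry).
#' @return a [SeedMapSet].
#' @export
makeSeedMaps <- function(surface, nSeeds = 3L, overlapFrac = 0.2, seed = 1L,
                         fociPerSeed = 6L, fwhm_mm = 28, amplitude = 4, foci = NULL) {
  if (nSeeds < 1L) stop("nSeeds must be >= 1", call. = FALSE)
  if (overlapFrac < 0 || overlapFrac > 1)
    stop("overlapFrac must lie in [0, 1]", call. = FALSE)
  v <- nVertices(surface)
  if (is.null(foci)) {
    set.seed(seed)
    nShared <- round(overlapFrac * fociPerSeed)
    foci <- replicate(nSeeds, sample.int(v, fociPerSeed), simplify = FALSE)
    if (nShared > 0 && nSeeds > 1) {
      # the last seed acts as the interface hub: it replaces part of its
      # foci with foci borrowed from the other seeds, so maps overlap
      # without correlating every seed pair directly
      pool <- unlist(foci[-nSeeds])
      borrowed <- sample(pool, min(nShared, length(pool)))
      foci[[nSeeds]][seq_along(borrowed)] <- borrowed
    }
  }
  sigma <- fwhm_mm / sqrt(8 * log(2))
  w <- matrix(0, nrow = nSeeds, ncol = v)
  for (i in seq_len(nSeeds)) {
    for (f in foci[[i]]) {
      d <- .surfaceGeodesicTo(surface, f)
      w[i, ] <- w[i, ] +
        amplitude * ifelse(is.finite(d), exp(-d^2 / (2 * sigma^2)), 0)
    }
  }
  nm <- if (nSeeds == 3L) c("empathy", "ToM", "moral")
        else paste0("seed", seq_len(nSeeds))
  new("SeedMapSet", weights = w, seedNames = nm)
}
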