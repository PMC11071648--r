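#' @include mesh.R
NULL

#' Surface Gaussian smoothing matrix
#'
#' Row-normalized Gaussian kernel weights on great-circle distance,
#' computed per hemisphere (no smoothing across the midline). Intended for
#' constructing smooth fields on generated spherical surfaces.
#'
#' @param surface a [CorticalSurface].
#' @param fwhm_mm kernel full width at half maximum (mm).
#' @return numeric matrix (V x V), block diagonal over hemispheres.
#' @export
surfaceSmoothingMatrix <- function(surface, fwhm_mm) {
  sig <- fwhm_mm / sqrt(8 * log(2))
  block <- function(mesh) {
    co <- mesh@coords
    r <- sqrt(sum(co[1, ]^2))
    u <- co / sqrt(rowSums(co^2))
    cosang <- tcrossprod(u)
    ang <- matrix(acos(pmin(1, pmax(-1, c(cosang)))), nrow(co))
    w <- exp(-(r * ang)^2 / (2 * sig^2))
    w / rowSums(w)
  }
  wl <- block(surface@left)
  wr <- block(surface@right)
  v <- nrow(wl)
  w <- matrix(0, 2L * v, 2L * v)
  w[seq_len(v), seq_len(v)] <- wl
  w[v + seq_len(v), v + seq_len(v)] <- wr
  w
}

#' Generate smooth Gaussian random maps
#'
#' Spatially smooth null fields: white Gaussian noise smoothed with a
#' surface kernel of the given width. These are the reference inputs for
#' calibration studies of the cluster-correction machinery, which models
#' the statistic image as a smooth random field.
#'
#' @param n number of maps (rows).
#' @param surface a [CorticalSurface].
#' @param fwhm_mm smoothing kernel FWHM in mm; 0 gives white noise.
#' @param seed integer RNG seed.
#' @return numeric matrix (n x V).
#' @export
randomSmoothMaps <- function(n, surface, fwhm_mm = 0, seed = 1L) {
  set.seed(seed)
  v <- nVertices(surface)
  maps <- matrix(stats::rnorm(n * v), nrow = n)
  if (fwhm_mm > 0)
    maps <- maps %*% t(surfaceSmoothingMatrix(surface, fwhm_mm))
  maps
}
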