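#' @include AllClasses.R mesh.R
NULL

#' Build the group-level age/sex design
#'
#' Age is centered at the cohort mean; sex is coded +1/2 (male) / -1/2
#' (female) so the sex column is the male-minus-female difference and the
#' interaction columns keep their age-slope interpretation. Default
#' columns: `intercept, age_c, age_c2, sex, sex_age, sex_age2`. Optional
#' subject-level covariates (e.g. intracranial volume, registration cost)
#' are appended as extra nuisance columns.
#'
#' @param cohort a [Cohort].
#' @param covariates optional data.frame / matrix of numeric subject-level
#'   covariates, rows aligned with the cohort.
#' @return a [GroupDesign].
#' @export
buildDesign <- function(cohort, covariates = NULL) {
  tab <- cohortTable(cohort)
  if (!nrow(tab)) stop("cohort is empty", call. = FALSE)
  if (stats::var(tab$age) == 0)
    stop("age is constant; no trajectory is estimable", call. = FALSE)
  ac <- tab$age - mean(tab$age)
  s <- ifelse(tab$sex == "male", 0.5, -0.5)
  x <- cbind(intercept = 1, age_c = ac, age_c2 = ac^2, sex = s,
             sex_age = s * ac, sex_age2 = s * ac^2)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(tab))
      stop("covariate rows must match the cohort", call. = FALSE)
    x <- cbind(x, covariates)
  }
  rownames(x) <- tab$subject_id
  new("GroupDesign", design = x, ageCenter = mean(tab$age),
      sexCoding = c(male = 0.5, female = -0.5))
}

#' Contrast vector for a named design column
#'
#' @param design a [GroupDesign].
#' @param column design column name.
#' @return numeric contrast weight vector.
#' @export
contrastVector <- function(design, column) {
  cn <- colnames(designMatrix(design))
  if (!column %in% cn)
    stop("no design column named '", column, "'", call. = FALSE)
  as.numeric(cn == column)
}

#' Vertex-wise general linear model
#'
#' Ordinary least squares at every vertex with a t contrast:
#' \eqn{t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}}
#' with two-sided p-values on n - q degrees of freedom. Residuals are kept
#' on the result for smoothness estimation.
#'
#' @param maps numeric matrix (n_subjects x V) of stacked subject maps.
#' @param design a [GroupDesign] (or bare design matrix) with n > q.
#' @param contrast numeric weight vector of length q, not all zero.
#' @param contrastName label stored on the result.
#' @return a [VertexStatMap].
#' @export
fitVertexGLM <- function(maps, design, contrast,
                         contrastName = "contrast") {
  x <- if (is(design, "GroupDesign")) designMatrix(design) else design
  n <- nrow(maps); q <- ncol(x)
  if (nrow(x) != n) stop("design rows must match map rows", call. = FALSE)
  if (n <= q) stop("need more subjects than design columns", call. = FALSE)
  if (length(contrast) != q)
    stop("contrast length must equal the design column count", call. = FALSE)
  if (all(contrast == 0)) stop("contrast is all zero", call. = FALSE)
  xtxi <- solve(crossprod(x))
  b <- xtxi %*% crossprod(x, maps)            # q x V
  resid <- maps - x %*% b
  df <- n - q
  sigma2 <- colSums(resid^2) / df
  cxx <- drop(t(contrast) %*% xtxi %*% contrast)
  cb <- drop(t(contrast) %*% b)
  tval <- cb / sqrt(sigma2 * cxx)
  tval[sigma2 == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df)
  new("VertexStatMap", beta = cb, t = tval, p = p, df = df,
      contrast = contrastName, residuals = resid)
}

#' Estimate residual smoothness and resel counts
#'
#' Each vertex's residual vector is scaled to unit norm; the mean squared
#' along-edge difference \eqn{\overline{\Delta^2}} of the normalized
#' residuals then yields
#' \eqn{\mathrm{FWHM} = \bar h \sqrt{4\ln 2 / \overline{\Delta^2}}}
#' with \eqn{\bar h} the mean edge length. Resels are (R0, R1, R2) =
#' (Euler characteristic of the search region, 0 for closed surfaces,
#' area / FWHM^2). For spatially independent noise the expected
#' \eqn{\overline{\Delta^2}} is 2, i.e. FWHM \eqn{= \bar h\sqrt{2\ln 2}}.
#'
#' @param residuals numeric matrix (n x V), n >= 3, typically from
#'   [fitVertexGLM()].
#' @param surface the [CorticalSurface] the maps live on.
#' @return a [SmoothnessEstimate].
#' @export
estimateSmoothness <- function(residuals, surface) {
  if (nrow(residuals) < 3L)
    stop("smoothness estimation needs at least 3 residual rows",
         call. = FALSE)
  norms <- sqrt(colSums(residuals^2))
  bad <- norms < 1e-12
  if (any(bad)) {
    warning(sum(bad), " zero-variance residual vertex(es) excluded",
            call. = FALSE)
    norms[bad] <- 1
  }
  u <- sweep(residuals, 2L, norms, "/")
  vl <- nVertices(surface@left)
  edges <- rbind(meshEdges(surface@left), meshEdges(surface@right) + vl)
  lens <- c(.edgeLengths(surface@left), .edgeLengths(surface@right))
  ok <- !(bad[edges[, 1]] | bad[edges[, 2]])
  d2 <- colSums((u[, edges[ok, 1], drop = FALSE] -
                 u[, edges[ok, 2], drop = FALSE])^2)
  fwhm <- mean(lens[ok]) * sqrt(4 * log(2) / mean(d2))
  area <- sum(triangleAreas(surface@left)) +
    sum(triangleAreas(surface@right))
  r0 <- eulerCharacteristic(surface@left) +
    eulerCharacteristic(surface@right)
  new("SmoothnessEstimate", fwhm = fwhm,
      resels = c(R0 = r0, R1 = 0, R2 = area / fwhm^2))
}

# Gaussian EC densities for a 2-D search region.
.ecDensity0 <- function(z) stats::pnorm(z, lower.tail = FALSE)
.ecDensity2 <- function(z) (4 * log(2)) / (2 * pi)^1.5 * z * exp(-z^2 / 2)

# t -> z Gaussianization, numerically stable in both tails.
.zFromT <- function(t, df) {
  neg <- function(tv) stats::qnorm(stats::pt(tv, df, log.p = TRUE),
                                   log.p = TRUE)
  ifelse(t <= 0, neg(t), -neg(-t))
}

# Connected components among `supra` vertices via BFS on the adjacency list.
.findClusters <- function(supra, adjacency) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  seen <- logical(length(supra))
  clusters <- list()
  for (v0 in idx) {
    if (seen[v0]) next
    comp <- integer(0)
    queue <- v0
    seen[v0] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adjacency[[v]]) {
        if (supra[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}

# Sign-split supra-threshold clusters of a z map.
.directionalClusters <- function(z, zthr, adjacency, direction) {
  cl <- list()
  if (direction %in% c("two.sided", "positive"))
    cl <- c(cl, .findClusters(z > zthr, adjacency))
  if (direction %in% c("two.sided", "negative"))
    cl <- c(cl, .findClusters(-z > zthr, adjacency))
  cl
}

.clusterResultFrame <- function(clusters, tval, vertexArea, p, alpha) {
  if (!length(clusters)) {
    return(data.frame(id = integer(0), n_vertices = integer(0),
                      area_mm2 = numeric(0), peak_t = numeric(0),
                      p_corrected = numeric(0), significant = logical(0)))
  }
  data.frame(
    id = seq_along(clusters),
    n_vertices = vapply(clusters, length, 1L),
    area_mm2 = vapply(clusters, function(m) sum(vertexArea[m]), 1),
    peak_t = vapply(clusters, function(m) max(abs(tval[m])), 1),
    p_corrected = p,
    significant = p <= alpha)
}

#' Random field theory cluster correction
#'
#' Gaussianizes the t map, forms supra-threshold connected components
#' (positive and negative excursions separately for two-sided inference)
#' and assigns each cluster a family-wise corrected p-value from the
#' standard 2-D expected-Euler-characteristic machinery: with expected
#' cluster count \eqn{E[m] = d (R_2 \rho_2(z_0) + R_0 \rho_0(z_0))},
#' expected supra-threshold resels \eqn{E[n] = d R_2 \Phi(-z_0)} (d = 2 for
#' two-sided inference) and cluster area \eqn{s} in resels,
#' \deqn{p = 1 - \exp(-E[m] \exp(-s\,E[m]/E[n])).}
#'
#' @param statmap a [VertexStatMap].
#' @param smoothness a [SmoothnessEstimate] from the model residuals.
#' @param surface the [CorticalSurface].
#' @param clusterFormingZ cluster-forming threshold on the z scale (> 0).
#' @param alpha family-wise significance level in (0, 1).
#' @param direction `"two.sided"` (default), `"positive"` or `"negative"`.
#' @return a [ClusterResult] ordered by corrected p.
#' @export
rftClusterCorrect <- function(statmap, smoothness, surface,
                              clusterFormingZ = 2.3, alpha = 0.05,
                              direction = c("two.sided", "positive",
                                            "negative")) {
  direction <- match.arg(direction)
  if (clusterFormingZ <= 0)
    stop("clusterFormingZ must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  z <- .zFromT(statmap@t, statmap@df)
  adjacency <- surfaceAdjacency(surface)
  clusters <- .directionalClusters(z, clusterFormingZ, adjacency, direction)
  vertexArea <- surfaceVertexAreas(surface)
  sides <- if (direction == "two.sided") 2 else 1
  r0 <- smoothness@resels[1]; r2 <- smoothness@resels[3]
  em <- sides * (r2 * .ecDensity2(clusterFormingZ) +
                 r0 * .ecDensity0(clusterFormingZ))
  en <- sides * r2 * stats::pnorm(clusterFormingZ, lower.tail = FALSE)
  p <- vapply(clusters, function(m) {
    s <- sum(vertexArea[m]) / smoothness@fwhm^2
    1 - exp(-em * exp(-s * em / en))
  }, 1)
  ord <- order(p)
  new("ClusterResult",
      clusters = .clusterResultFrame(clusters[ord], statmap@t, vertexArea,
                                     p[ord], alpha),
      members = clusters[ord], method = "rft",
      clusterFormingZ = clusterFormingZ, alpha = alpha)
}

# Cluster masses (sum of z excess over the threshold) of a z map.
.clusterMasses <- function(z, zthr, adjacency, direction) {
  cl <- .directionalClusters(z, zthr, adjacency, direction)
  list(clusters = cl,
       masses = vapply(cl, function(m) sum(abs(z[m]) - zthr), 1))
}

#' Permutation cluster correction (Freedman-Lane)
#'
#' Empirical family-wise cluster inference: the reduced model (contrast
#' column removed) is fitted, its residuals are permuted and added back to
#' the reduced fit, and the full-model max cluster mass (summed z excess
#' over the forming threshold) builds the null distribution. Corrected
#' p-values are `(1 + #{perm >= observed}) / (1 + nPerm)`, hence never
#' below the `1/(1 + nPerm)` floor. Serves as the empirical oracle for the
#' parametric random-field correction.
#'
#' @param maps numeric matrix (n_subjects x V).
#' @param design a [GroupDesign].
#' @param contrast numeric contrast vector with exactly one nonzero entry.
#' @param surface the [CorticalSurface].
#' @param clusterFormingZ cluster-forming threshold on the z scale.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param alpha family-wise significance level.
#' @param direction `"two.sided"`, `"positive"` or `"negative"`.
#' @return a [ClusterResult] ordered by corrected p.
#' @export
permutationCorrect <- function(maps, design, contrast, surface,
                               clusterFormingZ = 2.3, nPerm = 499L,
                               seed = 1L, alpha = 0.05,
                               direction = c("two.sided", "positive",
                                             "negative")) {
  direction <- match.arg(direction)
  if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
  x <- designMatrix(design)
  j <- which(contrast != 0)
  if (length(j) != 1L)
    stop("permutation inference supports single-column contrasts",
         call. = FALSE)
  n <- nrow(maps)
  adjacency <- surfaceAdjacency(surface)
  vertexArea <- surfaceVertexAreas(surface)

  tstat <- function(y) {
    sm <- fitVertexGLM(y, design, contrast, contrastName = "perm")
    .zFromT(sm@t, sm@df)
  }
  zobs <- tstat(maps)
  obs <- .clusterMasses(zobs, clusterFormingZ, adjacency, direction)

  x0 <- x[, -j, drop = FALSE]
  fit0 <- x0 %*% qr.solve(x0, maps)
  e0 <- maps - fit0
  set.seed(seed)
  maxMass <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    yb <- fit0 + e0[sample.int(n), , drop = FALSE]
    mb <- .clusterMasses(tstat(yb), clusterFormingZ, adjacency, direction)
    maxMass[b] <- if (length(mb$masses)) max(mb$masses) else 0
  }
  p <- vapply(obs$masses,
              function(m) (1 + sum(maxMass >= m)) / (1 + nPerm), 1)
  ord <- order(p)
  tobs <- fitVertexGLM(maps, design, contrast)@t
  new("ClusterResult",
      clusters = .clusterResultFrame(obs$clusters[ord], tobs, vertexArea,
                                     p[ord], alpha),
      members = obs$clusters[ord], method = "permutation",
      clusterFormingZ = clusterFormingZ, alpha = alpha)
}
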