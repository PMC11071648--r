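#' @import methods
NULL

#' Triangulated cortical hemisphere surface
#'
#' A closed, orientable triangle mesh standing in for one hemisphere of a
#' standard cortical surface grid. Generated meshes are recursively
#' subdivided icosahedra projected onto a sphere, so Euler's relation
#' \eqn{V - E + F = 2} holds for each hemisphere.
#'
#' @slot hemisphere `"left"` or `"right"`.
#' @slot coords numeric matrix (V x 3), vertex positions in mm.
#' @slot triangles integer matrix (F x 3), 1-based vertex index triples.
#' @export
setClass("CorticalMesh",
  representation(hemisphere = "character",
                 coords     = "matrix",
                 triangles  = "matrix"))

setValidity("CorticalMesh", function(object) {
  msg <- character(0)
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must have 3 columns")
  v <- nrow(object@coords)
  tr <- object@triangles
  if (length(tr) && (min(tr) < 1L || max(tr) > v))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

#' Two-hemisphere cortical surface
#'
#' Left and right [CorticalMesh] objects with identical topology; vertex-wise
#' data are stored left hemisphere first, then right.
#'
#' @slot left,right [CorticalMesh] objects.
#' @export
setClass("CorticalSurface",
  representation(left = "CorticalMesh", right = "CorticalMesh"))

setValidity("CorticalSurface", function(object) {
  if (object@left@hemisphere != "left" || object@right@hemisphere != "right")
    return("slots left/right must hold the matching hemispheres")
  TRUE
})

#' Discrete cortical network parcellation
#'
#' Integer network labels for every vertex of a [CorticalSurface]
#' (left-hemisphere vertices first). Label 0 marks unassigned vertices
#' (e.g. a medial wall); labels 1..K index the named networks.
#'
#' @slot labels integer vector, one entry per surface vertex.
#' @slot networkNames character vector of K unique network names.
#' @export
setClass("Parcellation",
  representation(labels = "integer", networkNames = "character"))

setValidity("Parcellation", function(object) {
  k <- length(object@networkNames)
  if (anyDuplicated(object@networkNames)) return("network names must be unique")
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) > k))
    return("labels must lie in 0..K")
  TRUE
})

#' Group-level seed network spatial maps
#'
#' Continuous, unthresholded spatial weights for each seed network: the
#' group components used as spatial predictors in the first dual-regression
#' stage.
#'
#' @slot weights numeric matrix (n_seeds x V).
#' @slot seedNames character vector of seed network names.
#' @export
setClass("SeedMapSet",
  representation(weights = "matrix", seedNames = "character"))

setValidity("SeedMapSet", function(object) {
  if (nrow(object@weights) != length(object@seedNames))
    return("one name per seed map row required")
  if (nrow(object@weights) < 1L) return("at least one seed map required")
  if (any(apply(abs(object@weights), 1L, max) == 0))
    return("seed maps must not be all-zero")
  TRUE
})

#' Study cohort phenotypes
#'
#' @slot table data.frame with columns `subject_id`, `age` (years), `sex`
#'   (`"male"`/`"female"`).
#' @export
setClass("Cohort", representation(table = "data.frame"))

setValidity("Cohort", function(object) {
  tab <- object@table
  need <- c("subject_id", "age", "sex")
  if (!all(need %in% names(tab)))
    return("cohort table needs subject_id, age, sex columns")
  if (anyDuplicated(tab$subject_id)) return("subject ids must be unique")
  if (!all(tab$sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  TRUE
})

#' Planted seed-to-network coupling effect
#'
#' Describes how the coupling weight between one seed network and one target
#' network varies with centered age \eqn{\tilde a} (years from the cohort
#' mean) and sex (coded +1/2 male, -1/2 female):
#' \deqn{w = \beta_0 + \beta_{lin}\tilde a + \beta_{quad}\tilde a^2 +
#'  s(\beta_{sex} + \beta_{sex,lin}\tilde a + \beta_{sex,quad}\tilde a^2)}
#' All coefficients are unitless couplings (per year, per year squared for
#' the age terms).
#'
#' @slot seedName,targetNetwork character scalars.
#' @slot beta0,betaLin,betaQuad,betaSex,betaSexLin,betaSexQuad numeric scalars.
#' @export
setClass("EffectSpec",
  representation(seedName = "character", targetNetwork = "character",
                 beta0 = "numeric", betaLin = "numeric", betaQuad = "numeric",
                 betaSex = "numeric", betaSexLin = "numeric",
                 betaSexQuad = "numeric"))

#' One subject's surface-sampled BOLD run
#'
#' @slot subjectId character scalar.
#' @slot data numeric matrix (T timepoints x V vertices), arbitrary units.
#' @slot tr repetition time in seconds.
#' @slot motion numeric matrix (T x 6): 3 translations (mm) then 3
#'   rotations (rad).
#' @slot tissue numeric matrix (T x 2) of designated white-matter / CSF mean
#'   signals carried alongside synthetic runs (zero columns if unknown).
#' @slot generative list of simulation-truth components (latent network and
#'   seed time courses, planted coupling); empty for real data.
#' @slot provenance character vector of applied processing steps.
#' @export
setClass("BoldRun",
  representation(subjectId = "character", data = "matrix", tr = "numeric",
                 motion = "matrix", tissue = "matrix", generative = "list",
                 provenance = "character"))

setValidity("BoldRun", function(object) {
  msg <- character(0)
  if (nrow(object@data) < 1L) msg <- c(msg, "run must have at least 1 timepoint")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (ncol(object@motion) != 6L) msg <- c(msg, "motion must have 6 columns")
  if (nrow(object@motion) != nrow(object@data))
    msg <- c(msg, "motion and data must have equal row counts")
  if (length(msg)) msg else TRUE
})

#' Temporal nuisance design matrix
#'
#' @slot design numeric matrix (T x p) with unique column names, containing
#'   exactly one intercept column (named `intercept`).
#' @export
setClass("NuisanceDesign", representation(design = "matrix"))

setValidity("NuisanceDesign", function(object) {
  cn <- colnames(object@design)
  if (is.null(cn) || anyDuplicated(cn))
    return("design needs unique column names")
  if (sum(cn == "intercept") != 1L)
    return("design must contain exactly one intercept column")
  TRUE
})

#' Subject-level dual-regression result
#'
#' Stage-1 time courses (temporal weights of each group seed map) and
#' stage-2 spatial maps (vertex-wise connectivity betas), with residual
#' variance bookkeeping for both stages.
#'
#' @slot subjectId character scalar.
#' @slot timecourses numeric matrix (T x n_seeds).
#' @slot maps numeric matrix (n_seeds x V).
#' @slot stage1ResidualVar,stage2ResidualVar nonnegative scalars.
#' @slot varianceNormalized logical: stage-1 courses scaled to unit variance
#'   before stage 2.
#' @export
setClass("DRFit",
  representation(subjectId = "character", timecourses = "matrix",
                 maps = "matrix", stage1ResidualVar = "numeric",
                 stage2ResidualVar = "numeric",
                 varianceNormalized = "logical"))

setValidity("DRFit", function(object) {
  msg <- character(0)
  if (ncol(object@timecourses) != nrow(object@maps))
    msg <- c(msg, "timecourse and map seed counts disagree")
  if (object@stage1ResidualVar < 0 || object@stage2ResidualVar < 0)
    msg <- c(msg, "residual variances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Group-level subject design matrix
#'
#' @slot design numeric matrix (n_subjects x q) with column names; default
#'   columns `intercept, age_c, age_c2, sex, sex_age, sex_age2`.
#' @slot ageCenter years subtracted from age before building polynomial terms.
#' @slot sexCoding named numeric map from sex label to design code.
#' @export
setClass("GroupDesign",
  representation(design = "matrix", ageCenter = "numeric",
                 sexCoding = "numeric"))

#' Vertex-wise GLM statistic map
#'
#' @slot beta,t,p numeric vectors (one entry per vertex).
#' @slot df residual degrees of freedom (n - q).
#' @slot contrast contrast name.
#' @slot residuals numeric matrix (n x V) of model residuals, kept for
#'   smoothness estimation.
#' @export
setClass("VertexStatMap",
  representation(beta = "numeric", t = "numeric", p = "numeric",
                 df = "numeric", contrast = "character",
                 residuals = "matrix"))

#' Residual smoothness estimate for random field theory
#'
#' @slot fwhm estimated residual smoothness (mm, full width at half maximum).
#' @slot resels numeric triple (R0, R1, R2): Euler characteristic of the
#'   search region, half boundary length in FWHM units (0 for closed
#'   surfaces) and surface area divided by FWHM squared.
#' @export
setClass("SmoothnessEstimate",
  representation(fwhm = "numeric", resels = "numeric"))

setValidity("SmoothnessEstimate", function(object) {
  if (object@fwhm <= 0) return("fwhm must be positive")
  if (length(object@resels) != 3L) return("resels must be (R0, R1, R2)")
  TRUE
})

#' Cluster-level corrected inference result
#'
#' @slot clusters data.frame with columns `id, n_vertices, area_mm2, peak_t,
#'   p_corrected, significant`, ordered by corrected p.
#' @slot members list of integer vertex-id vectors, one per cluster row.
#' @slot method `"rft"` or `"permutation"`.
#' @slot clusterFormingZ cluster-forming threshold on the z scale.
#' @slot alpha family-wise significance level.
#' @export
setClass("ClusterResult",
  representation(clusters = "data.frame", members = "list",
                 method = "character", clusterFormingZ = "numeric",
                 alpha = "numeric"))

setValidity("ClusterResult", function(object) {
  p <- object@clusters$p_corrected
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("corrected p must lie in [0, 1]")
  if (nrow(object@clusters) != length(object@members))
    return("one member set per cluster row required")
  TRUE
})

#' Fitted normative percentile trajectory
#'
#' Distributional (location-scale, optionally Box-Cox Cole-Green) regression
#' of a connectivity measure on age; percentile curves are quantiles of one
#' fitted distribution per age, so they cannot cross by construction.
#'
#' @slot family `"gaussian_ls"` or `"box_cox_cole_green"`.
#' @slot basis `"poly2"` or `"pspline"`.
#' @slot muCoefficients,sigmaCoefficients,nuCoefficients numeric vectors.
#' @slot percentiles ordered percent levels of the fitted curves.
#' @slot ageGrid evaluation grid (years).
#' @slot curves numeric matrix (n_percentiles x grid points).
#' @slot sexCurves list of per-sex curve matrices (empty unless sex entered
#'   the location model).
#' @slot logLik,bic fit statistics.
#' @slot converged logical.
#' @slot ageCenter centering constant used for the basis.
#' @slot muVcov covariance of the location coefficients.
#' @slot data data.frame of the fitted observations (age, y, optionally sex).
#' @export
setClass("TrajectoryFit",
  representation(family = "character", basis = "character",
                 muCoefficients = "numeric", sigmaCoefficients = "numeric",
                 nuCoefficients = "numeric", percentiles = "numeric",
                 ageGrid = "numeric", curves = "matrix", sexCurves = "list",
                 logLik = "numeric", bic = "numeric", converged = "logical",
                 ageCenter = "numeric", muVcov = "matrix", data = "data.frame"))

setValidity("TrajectoryFit", function(object) {
  if (is.unsorted(object@percentiles, strictly = TRUE))
    return("percentiles must be strictly increasing")
  if (nrow(object@curves) != length(object@percentiles))
    return("one curve per percentile required")
  if (ncol(object@curves) && nrow(object@curves) > 1L &&
      any(apply(object@curves, 2L, function(col) is.unsorted(col, strictly = TRUE))))
    return("percentile curves must be strictly increasing in p at every age")
  TRUE
})

#' Pipeline configuration
#'
#' Fully-defaulted, validated nested parameter list for [runPipeline()].
#' @slot config named list with sections `synthetic`, `preprocess`,
#'   `dualreg`, `glm`, `trajectory` plus global `seed`, `out_dir`, `stages`.
#' @export
setClass("PipelineConfig", representation(config = "list"))

#' Pipeline provenance log
#'
#' @slot records list of per-stage records (parameters, input hash, wall
#'   time, warnings, output files).
#' @export
setClass("ProvenanceLog", representation(records = "list"))
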