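#' @include AllGenerics.R
NULL

#' @rdname nVertices
#' @export
setMethod("nVertices", "CorticalMesh", function(x) nrow(x@coords))

#' @rdname nVertices
#' @export
setMethod("nVertices", "CorticalSurface",
          function(x) nrow(x@left@coords) + nrow(x@right@coords))

#' @rdname seedNames
#' @export
setMethod("seedNames", "SeedMapSet", function(x) x@seedNames)

#' @rdname seedWeights
#' @export
setMethod("seedWeights", "SeedMapSet", function(x) x@weights)

#' @rdname networkNames
#' @export
setMethod("networkNames", "Parcellation", function(x) x@networkNames)

#' @rdname parcelLabels
#' @export
setMethod("parcelLabels", "Parcellation", function(x) x@labels)

#' @rdname cohortTable
#' @export
setMethod("cohortTable", "Cohort", function(x) x@table)

#' @rdname boldData
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)

#' @rdname boldTr
#' @export
setMethod("boldTr", "BoldRun", function(x) x@tr)

#' @rdname motionParams
#' @export
setMethod("motionParams", "BoldRun", function(x) x@motion)

#' @rdname subjectId
#' @export
setMethod("subjectId", "BoldRun", function(x) x@subjectId)

#' @rdname subjectId
#' @export
setMethod("subjectId", "DRFit", function(x) x@subjectId)

#' @rdname drTimecourses
#' @export
setMethod("drTimecourses", "DRFit", function(x) x@timecourses)

#' @rdname drMaps
#' @export
setMethod("drMaps", "DRFit", function(x) x@maps)

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "GroupDesign", function(x) x@design)

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "NuisanceDesign", function(x) x@design)

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterResult", function(x) x@clusters)

#' @rdname trajectoryCurves
#' @export
setMethod("trajectoryCurves", "TrajectoryFit", function(x, sex = NULL) {
  curves <- if (is.null(sex)) x@curves else {
    if (!sex %in% names(x@sexCurves))
      stop("no per-sex curves for '", sex,
           "'; refit with sex in the location model", call. = FALSE)
    x@sexCurves[[sex]]
  }
  dimnames(curves) <- list(paste0("p", x@percentiles),
                           formatC(x@ageGrid, digits = 6, format = "g"))
  curves
})

setMethod("show", "CorticalMesh", function(object) {
  cat(sprintf("CorticalMesh (%s hemisphere): %d vertices, %d triangles\n",
              object@hemisphere, nrow(object@coords), nrow(object@triangles)))
})

setMethod("show", "CorticalSurface", function(object) {
  cat(sprintf("CorticalSurface: %d vertices (%d per hemisphere)\n",
              nVertices(object), nrow(object@left@coords)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d vertices, %d networks (%s)\n",
              length(object@labels), length(object@networkNames),
              paste(object@networkNames, collapse = ", ")))
})

setMethod("show", "SeedMapSet", function(object) {
  cat(sprintf("SeedMapSet: %d seed maps over %d vertices (%s)\n",
              nrow(object@weights), ncol(object@weights),
              paste(object@seedNames, collapse = ", ")))
})

setMethod("show", "Cohort", function(object) {
  tab <- object@table
  cat(sprintf(
    "Cohort: %d subjects (%d male), ages %.1f-%.1f y (mean %.2f)\n",
    nrow(tab), sum(tab$sex == "male"), min(tab$age), max(tab$age),
    mean(tab$age)))
})

setMethod("show", "BoldRun", function(object) {
  cat(sprintf("BoldRun %s: %d timepoints x %d vertices, TR %.3f s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@tr))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "DRFit", function(object) {
  cat(sprintf(
    "DRFit %s: %d seeds, %d timepoints, %d vertices (resid var %.3g / %.3g)\n",
    object@subjectId, nrow(object@maps), nrow(object@timecourses),
    ncol(object@maps), object@stage1ResidualVar, object@stage2ResidualVar))
})

setMethod("show", "GroupDesign", function(object) {
  cat(sprintf("GroupDesign: %d subjects x %d columns [%s], age centered at %.2f y\n",
              nrow(object@design), ncol(object@design),
              paste(colnames(object@design), collapse = ", "),
              object@ageCenter))
})

setMethod("show", "VertexStatMap", function(object) {
  cat(sprintf("VertexStatMap '%s': %d vertices, df = %g, max |t| = %.2f\n",
              object@contrast, length(object@t), object@df,
              max(abs(object@t))))
})

setMethod("show", "SmoothnessEstimate", function(object) {
  cat(sprintf("SmoothnessEstimate: FWHM %.2f mm; resels R0=%g R1=%g R2=%.1f\n",
              object@fwhm, object@resels[1], object@resels[2],
              object@resels[3]))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s): %d clusters, %d significant at alpha=%.3g\n",
              object@method, nrow(object@clusters),
              sum(object@clusters$significant), object@alpha))
  if (nrow(object@clusters)) print(utils::head(object@clusters, 10L))
})

setMethod("show", "TrajectoryFit", function(object) {
  cat(sprintf(
    "TrajectoryFit (%s, %s basis): n = %d, logLik %.2f, BIC %.2f\n",
    object@family, object@basis, nrow(object@data), object@logLik,
    object@bic))
  cat(sprintf("  percentiles: %s over ages %.1f-%.1f y\n",
              paste(object@percentiles, collapse = "/"),
              min(object@ageGrid), max(object@ageGrid)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig with sections:",
      paste(names(object@config), collapse = ", "), "\n")
})

setMethod("show", "ProvenanceLog", function(object) {
  cat(sprintf("ProvenanceLog: %d stage records (%s)\n",
              length(object@records),
              paste(vapply(object@records, `[[`, "", "stage"),
                    collapse = " -> ")))
})
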