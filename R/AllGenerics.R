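#' @include AllClasses.R
NULL

#' Number of vertices
#'
#' Total vertex count of a surface-indexed object (both hemispheres for a
#' [CorticalSurface]).
#' @param x object.
#' @return integer scalar.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Seed network names
#' @param x object carrying seed maps.
#' @return character vector.
#' @export
setGeneric("seedNames", function(x) standardGeneric("seedNames"))

#' Seed map weight matrix
#' @param x a [SeedMapSet].
#' @return numeric matrix (n_seeds x V).
#' @export
setGeneric("seedWeights", function(x) standardGeneric("seedWeights"))

#' Network names of a parcellation
#' @param x a [Parcellation].
#' @return character vector of K names.
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' Vertex labels of a parcellation
#' @param x a [Parcellation].
#' @return integer vector (0 = unassigned).
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))

#' Cohort phenotype table
#' @param x a [Cohort].
#' @return data.frame with subject_id, age, sex.
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))

#' BOLD data matrix
#' @param x a [BoldRun].
#' @return numeric matrix (T x V).
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' Repetition time (seconds)
#' @param x a [BoldRun].
#' @return numeric scalar.
#' @export
setGeneric("boldTr", function(x) standardGeneric("boldTr"))

#' Motion parameter traces
#' @param x a [BoldRun].
#' @return numeric matrix (T x 6).
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' Subject identifier
#' @param x object tied to one subject.
#' @return character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Stage-1 dual-regression time courses
#' @param x a [DRFit].
#' @return numeric matrix (T x n_seeds).
#' @export
setGeneric("drTimecourses", function(x) standardGeneric("drTimecourses"))

#' Stage-2 dual-regression spatial maps
#' @param x a [DRFit].
#' @return numeric matrix (n_seeds x V).
#' @export
setGeneric("drMaps", function(x) standardGeneric("drMaps"))

#' Design matrix of a design object
#' @param x a [GroupDesign] or [NuisanceDesign].
#' @return numeric matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Cluster table of a corrected inference result
#' @param x a [ClusterResult].
#' @return data.frame of clusters ordered by corrected p.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Percentile curves of a trajectory fit
#' @param x a [TrajectoryFit].
#' @param sex optionally `"male"` or `"female"` for per-sex curves.
#' @return numeric matrix (n_percentiles x grid points) with the age grid in
#'   its column names.
#' @export
setGeneric("trajectoryCurves",
           function(x, sex = NULL) standardGeneric("trajectoryCurves"))
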