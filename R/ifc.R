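#' @include AllClasses.R
NULL

#' Network-level iFC summary table
#'
#' Reduces each subject's stage-2 dual-regression maps to one intrinsic
#' functional connectivity value per (seed, network): the arithmetic mean
#' of the map over the network's vertices. One row per
#' (subject, seed, network), joined with the cohort phenotypes.
#'
#' @param fits list of [DRFit] objects (one per cohort subject).
#' @param parcellation a [Parcellation] whose vertex count matches the maps.
#' @param cohort the matching [Cohort].
#' @param networks optional subset of network names to summarize.
#' @return data.frame with columns `subject_id, age, sex, seed_name,
#'   network_name, ifc`.
#' @export
summarizeNetworkIfc <- function(fits, parcellation, cohort,
                                networks = networkNames(parcellation)) {
  labels <- parcelLabels(parcellation)
  allNets <- networkNames(parcellation)
  missing <- setdiff(networks, allNets)
  if (length(missing))
    stop("network(s) absent from the parcellation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  netIdx <- lapply(networks, function(nm) {
    idx <- which(labels == match(nm, allNets))
    if (!length(idx))
      stop("network '", nm, "' has no vertices", call. = FALSE)
    idx
  })
  tab <- cohortTable(cohort)
  rows <- lapply(fits, function(fit) {
    maps <- drMaps(fit)
    if (ncol(maps) != length(labels))
      stop("map vertex count does not match the parcellation",
           call. = FALSE)
    ph <- tab[match(subjectId(fit), tab$subject_id), ]
    if (is.na(ph$subject_id))
      stop("subject '", subjectId(fit), "' missing from the cohort",
           call. = FALSE)
    sn <- rownames(maps)
    expand <- expand.grid(network_name = networks, seed_name = sn,
                          stringsAsFactors = FALSE)
    ifc <- mapply(function(seedNm, netNm) {
      mean(maps[seedNm, netIdx[[match(netNm, networks)]]])
    }, expand$seed_name, expand$network_name)
    data.frame(subject_id = ph$subject_id, age = ph$age, sex = ph$sex,
               seed_name = expand$seed_name,
               network_name = expand$network_name,
               ifc = as.numeric(ifc), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
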