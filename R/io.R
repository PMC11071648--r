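#' @include AllClasses.R
NULL

# Minimal ASCII-encoded GIFTI writer/reader built on xml2. One DataArray
# per map row; enough of the standard (intent, dims, encoding) to exchange
# vertex-wise data with surface tools that accept ASCII GIFTI.

.giftiDataArray <- function(root, values, intent, dataType) {
  da <- xml2::xml_add_child(root, "DataArray",
    Intent = intent, DataType = dataType,
    ArrayIndexingOrder = "RowMajorOrder", Dimensionality = "1",
    Dim0 = as.character(length(values)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "",
    ExternalFileOffset = "")
  txt <- if (dataType == "NIFTI_TYPE_INT32")
    paste(as.integer(values), collapse = " ")
  else paste(formatC(values, digits = 10, format = "g"), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

#' Write vertex data as an ASCII GIFTI file
#'
#' Each row of `x` becomes one DataArray of per-vertex float values.
#'
#' @param x numeric matrix (n_maps x V) or vector.
#' @param path output file path (conventionally `.func.gii` or
#'   `.shape.gii`).
#' @param intent NIFTI intent string stored on every array.
#' @return `path`, invisibly.
#' @export
writeGiftiData <- function(x, path, intent = "NIFTI_INTENT_NONE") {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  root <- xml2::xml_new_root("GIFTI", Version = "1.0",
                             NumberOfDataArrays = as.character(nrow(x)))
  for (i in seq_len(nrow(x)))
    .giftiDataArray(root, x[i, ], intent, "NIFTI_TYPE_FLOAT32")
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read vertex data from an ASCII GIFTI file
#'
#' @param path GIFTI file written with ASCII encoding.
#' @return numeric matrix (n_arrays x V).
#' @export
readGiftiData <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stop("no DataArray elements in ", path, call. = FALSE)
  enc <- xml2::xml_attr(arrays, "Encoding")
  if (!all(enc == "ASCII"))
    stop("only ASCII-encoded GIFTI is supported", call. = FALSE)
  rows <- lapply(arrays, function(a) {
    as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(a, "./Data"))), "\\s+")[[1]])
  })
  do.call(rbind, rows)
}

#' Write a parcellation as a GIFTI label file
#'
#' @param parcellation a [Parcellation].
#' @param path output path (conventionally `.label.gii`).
#' @return `path`, invisibly.
#' @export
writeGiftiLabel <- function(parcellation, path) {
  root <- xml2::xml_new_root("GIFTI", Version = "1.0",
                             NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(root, "LabelTable")
  xml2::xml_add_child(lt, "Label", "unassigned", Key = "0")
  nm <- networkNames(parcellation)
  for (i in seq_along(nm))
    xml2::xml_add_child(lt, "Label", nm[i], Key = as.character(i))
  .giftiDataArray(root, parcelLabels(parcellation), "NIFTI_INTENT_LABEL",
                  "NIFTI_TYPE_INT32")
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a GIFTI label file as a parcellation
#'
#' @param path GIFTI label file written by [writeGiftiLabel()].
#' @return a [Parcellation].
#' @export
readGiftiLabel <- function(path) {
  doc <- xml2::read_xml(path)
  labels <- as.integer(readGiftiData(path)[1, ])
  labs <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  keys <- as.integer(xml2::xml_attr(labs, "Key"))
  nm <- xml2::xml_text(labs)[order(keys)]
  nm <- nm[sort(keys) != 0L]
  new("Parcellation", labels = labels, networkNames = nm)
}

#' Motion parameter text files
#'
#' Six-column whitespace-delimited traces in FSL `.par` ordering: three
#' rotations (rad) then three translations (mm). [BoldRun] objects store
#' translations first, so writing reorders columns and reading restores
#' the internal order.
#'
#' @param motion numeric matrix (T x 6), translations then rotations.
#' @param path file path.
#' @return `writeMotionPar`: `path` invisibly; `readMotionPar`: T x 6
#'   matrix, translations first.
#' @name motionPar
#' @export
writeMotionPar <- function(motion, path) {
  stopifnot(ncol(motion) == 6L)
  utils::write.table(motion[, c(4:6, 1:3), drop = FALSE], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname motionPar
#' @export
readMotionPar <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("expected 6 motion columns", call. = FALSE)
  m <- m[, c(4:6, 1:3), drop = FALSE]
  colnames(m) <- c(paste0("trans_", c("x", "y", "z")),
                   paste0("rot_", c("x", "y", "z")))
  rownames(m) <- NULL
  m
}

#' Cohort CSV round trip
#'
#' @param cohort a [Cohort].
#' @param path CSV path (columns subject_id, age, sex).
#' @return `writeCohortCsv`: `path` invisibly; `readCohortCsv`: a [Cohort].
#' @name cohortCsv
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohortTable(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohortCsv
#' @export
readCohortCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("Cohort", table = tab)
}
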