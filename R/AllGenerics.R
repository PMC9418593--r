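#' @rdname TapCohort-accessors
#' @export
setGeneric("tapStreams", function(x) standardGeneric("tapStreams"))

#' @rdname TapCohort-accessors
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))

#' @rdname TapCohort-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname JIDGrid-accessors
#' @export
setGeneric("jidMass", function(x) standardGeneric("jidMass"))

#' @rdname JIDGrid-accessors
#' @export
setGeneric("gridCenters", function(x) standardGeneric("gridCenters"))

#' @rdname NormativeModel-accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))

#' @rdname NormativeModel-accessors
#' @export
setGeneric("foldModels", function(x) standardGeneric("foldModels"))

#' @rdname NormativeModel-accessors
#' @export
setGeneric("hyperParams", function(x) standardGeneric("hyperParams"))

#' @rdname NormativeModel-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname NormativeModel-accessors
#' @export
setGeneric("windowDays", function(x) standardGeneric("windowDays"))
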