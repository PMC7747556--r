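#' @rdname EpochSeries-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EpochSeries-class
#' @export
setGeneric("activityCounts", function(x) standardGeneric("activityCounts"))

#' @rdname EpochSeries-class
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname ActivityCohort-class
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname ActivityCohort-class
#' @export
setGeneric("series", function(x, id) standardGeneric("series"))

#' @rdname ActivityCohort-class
#' @export
setGeneric("diaries", function(x) standardGeneric("diaries"))

#' @rdname ActivityCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname FourierCurve-class
#' @export
setGeneric("evaluateCurve", function(x, minutes) standardGeneric("evaluateCurve"))

#' @rdname FLMResult-class
#' @export
setGeneric("observedF", function(x) standardGeneric("observedF"))

#' @rdname FLMResult-class
#' @export
setGeneric("criticalCurve", function(x) standardGeneric("criticalCurve"))

#' @rdname FLMResult-class
#' @export
setGeneric("pointwiseP", function(x) standardGeneric("pointwiseP"))

#' @rdname significantIntervals
#' @export
setGeneric("significantIntervals", function(x, ...) standardGeneric("significantIntervals"))

#' @rdname ModelAverageResult-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname ModelAverageResult-class
#' @export
setGeneric("candidateModels", function(x) standardGeneric("candidateModels"))
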