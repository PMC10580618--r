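#' @rdname ConditionRegistry-class
#' @param x,object a `ConditionRegistry` (or, where documented, another class).
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname ConditionRegistry-class
#' @export
setGeneric("nConditions", function(x) standardGeneric("nConditions"))

#' @rdname ConditionRegistry-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname BottleneckSurvey
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))

#' @rdname BottleneckSurvey
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @rdname BottleneckSurvey
#' @export
setGeneric("systemKeys", function(x) standardGeneric("systemKeys"))

#' @rdname BottleneckSurvey
#' @export
setGeneric("importanceSelections", function(x) standardGeneric("importanceSelections"))

#' @rdname buildFlagTable
#' @export
setGeneric("flags", function(x, which = "bottleneck") standardGeneric("flags"))

#' @rdname buildFlagTable
#' @export
setGeneric("hasFlags", function(x) standardGeneric("hasFlags"))

#' @rdname CongruenceMatrix-class
#' @export
setGeneric("congruenceLabels", function(x) standardGeneric("congruenceLabels"))

#' @rdname CongruenceMatrix-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
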