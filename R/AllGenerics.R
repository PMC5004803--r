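#' Accessors
#'
#' Small accessor generics for the package's S4 result classes.
#'
#' @param x an [OtuExperiment-class], [DoseResponseFit-class] or
#'   [BurrIII-class] object.
#' @return `otuStage()` the preprocessing stage; `otuCounts()` the abundance
#'   matrix; `doseDesign()` a data.frame with `sample_id`, `treatment`,
#'   `dose`; `fitParams()` the named parameter vector; `fitModel()` the model
#'   label; `fitCovariance()` the covariance matrix or `NULL`; `rSquared()`
#'   the coefficient of determination; `isAccepted()` the acceptance flag;
#'   `rejectionReasons()` the reason codes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuStage", function(x) standardGeneric("otuStage"))
#' @rdname accessors
#' @export
setMethod("otuStage", "OtuExperiment", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setMethod("otuCounts", "OtuExperiment", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("doseDesign", function(x) standardGeneric("doseDesign"))
#' @rdname accessors
#' @export
setMethod("doseDesign", "OtuExperiment", function(x) {
    cd <- colData(x)
    data.frame(sample_id = rownames(cd), treatment = cd$treatment,
               dose = cd$dose, row.names = NULL)
})

#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setMethod("fitParams", "DoseResponseFit", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("fitParams", "BurrIII",
    function(x) c(scale_b = x@scaleB, shape_c = x@shapeC, shape_k = x@shapeK))

#' @rdname accessors
#' @export
setGeneric("fitModel", function(x) standardGeneric("fitModel"))
#' @rdname accessors
#' @export
setMethod("fitModel", "DoseResponseFit", function(x) x@model)

#' @rdname accessors
#' @export
setGeneric("fitCovariance", function(x) standardGeneric("fitCovariance"))
#' @rdname accessors
#' @export
setMethod("fitCovariance", "DoseResponseFit", function(x) x@covariance)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "DoseResponseFit", function(x) x@rSquared)

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setMethod("isAccepted", "DoseResponseFit", function(x) x@accepted)

#' @rdname accessors
#' @export
setGeneric("rejectionReasons", function(x) standardGeneric("rejectionReasons"))
#' @rdname accessors
#' @export
setMethod("rejectionReasons", "DoseResponseFit", function(x) x@rejectionReasons)
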