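#' @import methods
NULL

#' Accessor generics for fcmsim classes
#'
#' Small accessor generics shared across the package's S4 classes.
#' Use these instead of reaching into slots with `@`.
#'
#' @param x,object an fcmsim S4 object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name fcmsim-generics
#' @keywords internal
NULL

#' @rdname fcmsim-generics
#' @export
setGeneric("concepts", function(x, ...) standardGeneric("concepts"))

#' @rdname fcmsim-generics
#' @export
setGeneric("relations", function(x, ...) standardGeneric("relations"))

#' @rdname fcmsim-generics
#' @export
setGeneric("weightMatrix", function(x, ...) standardGeneric("weightMatrix"))

#' @rdname fcmsim-generics
#' @export
setGeneric("conceptIds", function(x, ...) standardGeneric("conceptIds"))

#' @rdname fcmsim-generics
#' @export
setGeneric("nConcepts", function(x) standardGeneric("nConcepts"))

#' @rdname fcmsim-generics
#' @export
setGeneric("nRelations", function(x) standardGeneric("nRelations"))

#' @rdname fcmsim-generics
#' @export
setGeneric("states", function(x, ...) standardGeneric("states"))

#' @rdname fcmsim-generics
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname fcmsim-generics
#' @export
setGeneric("iterationsToConvergence",
           function(x) standardGeneric("iterationsToConvergence"))

#' @rdname fcmsim-generics
#' @export
setGeneric("attractorClass", function(x) standardGeneric("attractorClass"))

#' @rdname fcmsim-generics
#' @export
setGeneric("cyclePeriod", function(x) standardGeneric("cyclePeriod"))

#' @rdname fcmsim-generics
#' @export
setGeneric("terminalState", function(x, ...) standardGeneric("terminalState"))

#' @rdname fcmsim-generics
#' @export
setGeneric("terminalValues", function(x, ...) standardGeneric("terminalValues"))

#' @rdname fcmsim-generics
#' @export
setGeneric("profileSummary", function(x, ...) standardGeneric("profileSummary"))

#' @rdname fcmsim-generics
#' @export
setGeneric("profileMeans", function(x, ...) standardGeneric("profileMeans"))

#' @rdname fcmsim-generics
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname fcmsim-generics
#' @export
setGeneric("recipeClamps", function(x, ...) standardGeneric("recipeClamps"))
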