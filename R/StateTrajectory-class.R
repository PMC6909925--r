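#' StateTrajectory: the recorded run of a simulation
#'
#' Holds the per-iteration state matrix of a simulation run, its
#' convergence outcome and the terminal-behaviour classification.
#'
#' @slot states numeric matrix, one row per recorded iteration (row 1 is
#'   the initial state, iteration 0), columns named by concept; every
#'   entry lies in \[-1, 1\].
#' @slot converged logical.
#' @slot iterationsToConvergence iteration at which the convergence window
#'   was first satisfied (NA if not converged).
#' @slot attractorClass "fixed_point", "limit_cycle" or "non_convergent".
#' @slot cyclePeriod smallest period of a detected limit cycle (NA
#'   otherwise).
#' @seealso [runSimulation()], [assessConvergence()], [classifyAttractor()]
#' @export
setClass("StateTrajectory",
         representation(states = "matrix", converged = "logical",
                        iterationsToConvergence = "integer",
                        attractorClass = "character",
                        cyclePeriod = "integer"))

setValidity("StateTrajectory", function(object) {
  msgs <- character()
  if (any(!is.finite(object@states)) || any(abs(object@states) > 1))
    msgs <- c(msgs, "all recorded states must be finite and within [-1, 1]")
  if (!object@attractorClass %in%
        c("fixed_point", "limit_cycle", "non_convergent"))
    msgs <- c(msgs, "unknown attractor class")
  if (object@converged && is.na(object@iterationsToConvergence))
    msgs <- c(msgs, "converged trajectories must report the iteration")
  if (!object@converged && !is.na(object@iterationsToConvergence))
    msgs <- c(msgs, "iterationsToConvergence must be NA when not converged")
  if (object@attractorClass == "limit_cycle" && is.na(object@cyclePeriod))
    msgs <- c(msgs, "limit cycles must report a period")
  if (length(msgs)) msgs else TRUE
})

#' @rdname fcmsim-generics
#' @export
setMethod("states", "StateTrajectory", function(x, ...) x@states)

#' @rdname fcmsim-generics
#' @export
setMethod("isConverged", "StateTrajectory", function(x) x@converged)

#' @rdname fcmsim-generics
#' @export
setMethod("iterationsToConvergence", "StateTrajectory",
          function(x) x@iterationsToConvergence)

#' @rdname fcmsim-generics
#' @export
setMethod("attractorClass", "StateTrajectory", function(x) x@attractorClass)

#' @rdname fcmsim-generics
#' @export
setMethod("cyclePeriod", "StateTrajectory", function(x) x@cyclePeriod)

#' @rdname fcmsim-generics
#' @export
setMethod("terminalState", "StateTrajectory", function(x, ...) {
  x@states[nrow(x@states), ]
})

setMethod("show", "StateTrajectory", function(object) {
  n <- nrow(object@states)
  cat("StateTrajectory:", ncol(object@states), "concepts,", n - 1L,
      "iterations recorded\n")
  cat("  attractor:", object@attractorClass)
  if (!is.na(object@cyclePeriod))
    cat(" (period ", object@cyclePeriod, ")", sep = "")
  if (object@converged)
    cat("; converged at iteration", object@iterationsToConvergence)
  cat("\n")
})

#' Export a trajectory as a data.frame
#'
#' @param traj a [StateTrajectory-class].
#' @return data.frame with an `iteration` column followed by one column per
#'   concept.
#' @export
trajectoryTable <- function(traj) {
  stopifnot(is(traj, "StateTrajectory"))
  data.frame(iteration = seq_len(nrow(traj@states)) - 1L, traj@states,
             check.names = FALSE)
}
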