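#' SteadyStateProfile: terminal concept values across replicates
#'
#' Terminal state vectors of an ensemble of replicate simulations, with
#' per-concept mean, standard error and confidence-interval half-width.
#' Replicates differ only through the seeded noise model of the
#' configuration; with noise off they are identical and every SEM is 0.
#'
#' @slot values numeric matrix, replicates x concepts.
#' @slot convergedReplicates logical, per replicate; non-convergent
#'   replicates are flagged, never dropped.
#' @slot level confidence level of the interval half-width (default 0.99).
#' @seealso [runReplicates()], [replicateSummary()], [callExpression()]
#' @export
setClass("SteadyStateProfile",
         representation(values = "matrix", convergedReplicates = "logical",
                        level = "numeric"))

setValidity("SteadyStateProfile", function(object) {
  msgs <- character()
  if (nrow(object@values) < 1L) msgs <- c(msgs, "need >= 1 replicate")
  if (length(object@convergedReplicates) != nrow(object@values))
    msgs <- c(msgs, "one convergence flag per replicate required")
  if (object@level <= 0 || object@level >= 1)
    msgs <- c(msgs, "level must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname fcmsim-generics
#' @export
setMethod("terminalValues", "SteadyStateProfile", function(x, ...) x@values)

#' @rdname fcmsim-generics
#' @export
setMethod("nReplicates", "SteadyStateProfile", function(x) nrow(x@values))

#' @rdname fcmsim-generics
#' @export
setMethod("conceptIds", "SteadyStateProfile",
          function(x, ...) colnames(x@values))

#' @describeIn SteadyStateProfile-class named vector of per-concept means.
#' @param x,object a SteadyStateProfile.
#' @param ... unused.
#' @export
setMethod("profileMeans", "SteadyStateProfile",
          function(x, ...) colMeans(x@values))

#' @describeIn SteadyStateProfile-class data.frame with one row per concept:
#'   `concept`, `mean`, `sem`, `ci_low`, `ci_high`, `n`.
#' @export
setMethod("profileSummary", "SteadyStateProfile", function(x, ...) {
  v <- x@values
  n <- nrow(v)
  out <- do.call(rbind, lapply(colnames(v), function(id) {
    s <- replicateSummary(v[, id], level = x@level)
    data.frame(concept = id, mean = s$mean, sem = s$sem,
               ci_low = s$mean - s$ci_half, ci_high = s$mean + s$ci_half,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
})

setMethod("show", "SteadyStateProfile", function(object) {
  cat("SteadyStateProfile:", ncol(object@values), "concepts,",
      nrow(object@values), "replicate(s)\n")
  bad <- sum(!object@convergedReplicates)
  if (bad > 0L) cat("  WARNING:", bad, "non-convergent replicate(s)\n")
})

#' Replicate summary statistics
#'
#' Mean, standard error of the mean and a t-based confidence-interval
#' half-width for a set of replicate values.
#'
#' @param values numeric vector.
#' @param level confidence level (default 0.99).
#' @return list with `mean`, `sem`, `ci_half` (`sem` and `ci_half` are NA
#'   for a single value).
#' @examples
#' replicateSummary(c(0, 1))  # half-width = t(0.995, df = 1) * 0.5
#' @export
replicateSummary <- function(values, level = 0.99) {
  stopifnot(level > 0, level < 1, length(values) >= 1L)
  n <- length(values)
  m <- mean(values)
  if (n < 2L)
    return(list(mean = m, sem = NA_real_, ci_half = NA_real_))
  sem <- stats::sd(values) / sqrt(n)
  list(mean = m, sem = sem,
       ci_half = stats::qt(1 - (1 - level) / 2, df = n - 1L) * sem)
}
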