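#' Rank candidate biomarkers by genotype separation
#'
#' For each candidate concept, compares its values across the wild-type
#' and disease ensembles with the exact Mann-Whitney test and ranks by
#' p-value (mean difference magnitude breaks ties). Candidates whose exact
#' p falls below `flag_threshold` are flagged as significant.
#'
#' Simulated steady states are only resolved to the convergence tolerance
#' of the run that produced them: sub-tolerance residuals are numerical
#' stopping artifacts, not biology. Values are therefore snapped to a
#' `tol`-spaced grid before rank-testing, so a genotype-invariant concept
#' yields tied samples and p = 1 instead of spuriously perfect separation
#' at the 1e-7 level. Set `tol = 0` to rank raw values (appropriate for
#' measured, not simulated, profiles).
#'
#' @param wt,disease matrices or data.frames of profiles (rows =
#'   replicates/samples, columns = concepts), e.g.
#'   `terminalValues(profile)` of two [runReplicates()] ensembles, or the
#'   marker columns of a [generateProfileDataset()] split by label.
#' @param candidates candidate concept ids (must be columns of both).
#' @param flag_threshold significance flag cutoff (default 1e-4).
#' @param tol value-resolution grid (default 1e-4, the default convergence
#'   tolerance).
#' @return data.frame sorted by rank: `concept`, `mean_wt`,
#'   `mean_disease`, `delta`, `U`, `p_value`, `significant`.
#' @export
rankCandidateBiomarkers <- function(wt, disease, candidates,
                                    flag_threshold = 1e-4, tol = 1e-4) {
  wt <- as.data.frame(wt); disease <- as.data.frame(disease)
  if (nrow(wt) == 0L || nrow(disease) == 0L)
    stop("both ensembles must be non-empty", call. = FALSE)
  miss <- setdiff(candidates, intersect(names(wt), names(disease)))
  if (length(miss))
    stop("candidate(s) absent from profiles: ",
         paste(miss, collapse = ", "), call. = FALSE)
  snap <- function(x) if (tol > 0) round(x / tol) * tol else x
  rows <- lapply(candidates, function(id) {
    mwu <- exactMannWhitney(snap(disease[[id]]), snap(wt[[id]]))
    data.frame(concept = id, mean_wt = mean(wt[[id]]),
               mean_disease = mean(disease[[id]]),
               delta = mean(disease[[id]]) - mean(wt[[id]]),
               U = mwu$U, p_value = mwu$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -abs(out$delta), out$concept), ]
  out$significant <- out$p_value < flag_threshold
  rownames(out) <- NULL
  out
}

#' Fit a single-variable linear discriminant
#'
#' Fits a one-marker logistic discriminant for Normal vs disease: the
#' linear score is `a * x + b` (the logit of Normal), with the decision
#' rule *predict Normal iff `a * x + b >= 0`*. With a marker that is
#' higher in disease, the fitted slope `a` is negative.
#'
#' Perfectly separated classes are permitted (the score still orders and
#' classifies correctly; glm's separation warnings are suppressed on
#' purpose, and coefficient magnitudes are then arbitrary large numbers).
#'
#' @param data data.frame from [generateProfileDataset()] (or any frame
#'   with the marker column and a `label` column with levels "Normal" and
#'   one disease label).
#' @param marker marker column name.
#' @return list of class `fcmsim_discriminant`: `marker`, `a` (slope),
#'   `b` (intercept).
#' @export
fitLinearDiscriminant <- function(data, marker) {
  stopifnot(marker %in% names(data), "label" %in% names(data))
  y <- as.integer(data$label == "Normal")
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  x <- data[[marker]]
  if (stats::sd(x) == 0)
    stop("constant marker: ", marker, call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial()))
  co <- stats::coef(fit)
  structure(list(marker = marker, a = unname(co[2L]), b = unname(co[1L])),
            class = "fcmsim_discriminant")
}

#' @export
print.fcmsim_discriminant <- function(x, ...) {
  cat(sprintf("OUTCOME{Normal} = (%.4g * %s) + %.4g\n", x$a, x$marker, x$b))
  invisible(x)
}

#' Score and classify with a fitted discriminant
#'
#' @param object a `fcmsim_discriminant` from [fitLinearDiscriminant()].
#' @param newdata data.frame containing the marker column.
#' @param type "score" (linear score, the Normal logit) or "class".
#' @param ... unused.
#' @return numeric scores or a character vector of predicted labels.
#' @export
predict.fcmsim_discriminant <- function(object, newdata,
                                        type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- object$a * newdata[[object$marker]] + object$b
  if (type == "score") s else ifelse(s >= 0, "Normal", "IOPD")
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed by the rank (Mann-Whitney)
#' formulation: `U / (n1 * n0)` with midrank ties, where scores of the
#' positive class are compared against the negative class.
#'
#' @param scores numeric scores (higher = more positive-class).
#' @param positive logical or 0/1: which observations are positive-class.
#' @return AUC in \[0, 1\].
#' @export
aucFromScores <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
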