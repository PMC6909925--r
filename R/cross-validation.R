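#' Harmonic-mean F measure
#'
#' `F = 2PR / (P + R)`, 0 when both precision and recall are 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return F measure in \[0, 1\].
#' @examples
#' fMeasure(0.9459, 0.9722)  # 0.959 at printed precision
#' @export
fMeasure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Stratified k-fold cross-validation of a single-marker discriminant
#'
#' Assigns folds stratified by class (seed-deterministic), fits
#' [fitLinearDiscriminant()] on each training split and pools the held-out
#' predictions. Metrics take Normal as the positive class: precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`, the F measure, and AUC from
#' the pooled held-out scores via the rank formulation
#' ([aucFromScores()]).
#'
#' @param data data.frame from [generateProfileDataset()].
#' @param marker marker column to cross-validate.
#' @param folds number of folds (default 10); must not exceed the smaller
#'   class (every training split must contain both classes).
#' @param seed fold-assignment seed.
#' @return list: `precision`, `recall`, `f_measure`, `auc`, `folds`,
#'   `confusion` (pooled TP/FP/FN/TN), `fold_confusion` (per-fold counts).
#' @examples
#' cv <- crossValidate(generateProfileDataset(seed = 2), "calpain")
#' cv$f_measure
#' @export
crossValidate <- function(data, marker, folds = 10L, seed = 1L) {
  stopifnot("label" %in% names(data))
  n <- nrow(data)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  cls <- data$label
  if (min(table(cls)) < folds)
    stop("folds must not exceed the smaller class size for stratified ",
         "assignment", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  scores <- numeric(n)
  pred <- character(n)
  fold_conf <- matrix(0L, folds, 4L,
                      dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    model <- fitLinearDiscriminant(data[!test, , drop = FALSE], marker)
    scores[test] <- predict(model, data[test, , drop = FALSE])
    pred[test] <- ifelse(scores[test] >= 0, "Normal", "IOPD")
    is_pos <- cls[test] == "Normal"
    is_hat <- pred[test] == "Normal"
    fold_conf[k, ] <- c(sum(is_hat & is_pos), sum(is_hat & !is_pos),
                        sum(!is_hat & is_pos), sum(!is_hat & !is_pos))
  }
  conf <- colSums(fold_conf)
  precision <- if (conf["TP"] + conf["FP"] > 0)
    conf["TP"] / (conf["TP"] + conf["FP"]) else 0
  recall <- if (conf["TP"] + conf["FN"] > 0)
    conf["TP"] / (conf["TP"] + conf["FN"]) else 0
  list(precision = unname(precision), recall = unname(recall),
       f_measure = fMeasure(unname(precision), unname(recall)),
       auc = aucFromScores(scores, cls == "Normal"),
       folds = as.integer(folds),
       confusion = conf, fold_confusion = fold_conf)
}
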