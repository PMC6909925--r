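#' Threshold terminal values into expression calls
#'
#' Deterministic call rule: a terminal value >= 0 is `expressed_up`
#' (expressed / upregulated / present), a value < 0 is `repressed_absent`
#' (downregulated / not expressed / absent). Exactly 0 calls expressed.
#'
#' @param x a [SteadyStateProfile-class] (per-concept means are called) or
#'   a named numeric vector of terminal values.
#' @return data.frame with `concept`, `value`, `call`.
#' @examples
#' callExpression(c(lysosomal_glycogen = 0.585, GAA = -1))
#' @export
callExpression <- function(x) {
  if (is(x, "SteadyStateProfile")) x <- profileMeans(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  data.frame(concept = names(x), value = unname(x),
             call = ifelse(x >= 0, "expressed_up", "repressed_absent"),
             stringsAsFactors = FALSE)
}
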