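#' Summary statistics of a concept network
#'
#' Degree and sign statistics of the directed graph. The positive-edge
#' fraction doubles as the network's pretest probability of a positive
#' prediction: the chance-success probability used by
#' [biasedBinomialTest()] when validating simulation calls against
#' literature profiles.
#'
#' @param net a non-empty [ConceptNetwork-class].
#' @return A list with `n_concepts`, `n_relations`, `mean_in_degree`,
#'   `mean_out_degree`, `positive_fraction`, `pretest_positive` and
#'   `pretest_negative` (`= 1 - pretest_positive`).
#' @examples
#' net <- randomNetwork(50, mean_degree = 4, seed = 1)
#' networkStats(net)$positive_fraction
#' @export
networkStats <- function(net) {
  stopifnot(is(net, "ConceptNetwork"))
  if (nConcepts(net) == 0L)
    stop("empty network", call. = FALSE)
  re <- relations(net)
  n <- nConcepts(net)
  m <- nrow(re)
  pos <- if (m > 0L) sum(re$weight > 0) / m else NA_real_
  list(n_concepts = n,
       n_relations = m,
       mean_in_degree = m / n,
       mean_out_degree = m / n,
       positive_fraction = pos,
       pretest_positive = pos,
       pretest_negative = 1 - pos)
}
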