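#' Generate a random signed concept network
#'
#' Draws a directed graph with a fixed total edge count
#' `round(n_concepts * mean_degree)`, sampled uniformly without replacement
#' from all ordered pairs (self-loops excluded unless allowed). Edge signs
#' are i.i.d. positive with probability `positive_fraction`; magnitudes
#' default to 1 or are drawn uniformly from a range. The defaults emulate
#' the published statistics of the large curated database this package's
#' bundled network stands in for: roughly 8 inputs and 8 outputs per node
#' and a 0.66 positive-edge fraction.
#'
#' @param n_concepts number of concepts (>= 2).
#' @param mean_degree target mean in-degree (= mean out-degree); must be
#'   smaller than the number of admissible partners.
#' @param positive_fraction probability an edge is positive, in \[0, 1\].
#' @param weight_magnitude either a single magnitude in (0, 1\] (default 1)
#'   or a length-2 range to draw magnitudes uniformly from.
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @param allow_self_loops allow edges i -> i (default FALSE).
#' @return A [ConceptNetwork-class] with concepts `c1 ... cN`.
#' @examples
#' net <- randomNetwork(100, mean_degree = 8, positive_fraction = 0.66,
#'                      seed = 1)
#' nRelations(net)  # 800
#' @export
randomNetwork <- function(n_concepts, mean_degree = 8,
                          positive_fraction = 0.66,
                          weight_magnitude = 1, seed = 1L,
                          allow_self_loops = FALSE) {
  stopifnot(n_concepts >= 2, positive_fraction >= 0, positive_fraction <= 1,
            mean_degree >= 0)
  n <- as.integer(n_concepts)
  n_pairs <- if (allow_self_loops) n * n else n * (n - 1L)
  m <- as.integer(round(n * mean_degree))
  if (m > n_pairs)
    stop("infeasible degree request: ", m, " edges but only ", n_pairs,
         " ordered pairs available", call. = FALSE)
  ids <- paste0("c", seq_len(n))
  if (m == 0L)
    return(conceptNetwork(concepts = data.frame(id = ids)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pick <- sample.int(n_pairs, m)
  if (allow_self_loops) {
    src <- ((pick - 1L) %% n) + 1L
    tgt <- ((pick - 1L) %/% n) + 1L
  } else {
    # enumerate ordered pairs excluding the diagonal
    src <- ((pick - 1L) %% n) + 1L
    off <- ((pick - 1L) %/% n) + 1L     # 1 .. n-1, offset from source
    tgt <- ((src + off - 1L) %% n) + 1L
  }
  sign <- ifelse(stats::runif(m) < positive_fraction, 1, -1)
  mag <- if (length(weight_magnitude) == 2L)
    stats::runif(m, weight_magnitude[1L], weight_magnitude[2L])
  else rep(weight_magnitude, m)
  rel <- data.frame(source = ids[src], target = ids[tgt],
                    weight = sign * mag, stringsAsFactors = FALSE)
  conceptNetwork(rel, concepts = data.frame(id = ids))
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
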