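#' Run a replicate ensemble to steady state
#'
#' Runs `n` replicate simulations whose seeds are derived deterministically
#' from `config@seed`, collects the terminal states and summarises them per
#' concept. Replicate variability comes entirely from the configuration's
#' noise model (by default, seeded uniform jitter on the initial values of
#' unclamped concepts); with `noiseSigma = 0` all replicates are identical.
#'
#' @param net a [ConceptNetwork-class].
#' @param clamps clamp data.frame (see [clampSpec()]).
#' @param config a [SimulationConfig-class].
#' @param n number of replicates (default 3).
#' @param init optional initial state passed to every replicate (phase-2
#'   continuation); may be a matrix with one row per replicate.
#' @return A [SteadyStateProfile-class]. Non-convergent replicates are
#'   flagged in the profile (and trigger a warning), never dropped.
#' @examples
#' net <- iopdNetwork()
#' prof <- runReplicates(net, recipeClamps(iopdRecipes()[["aiSkMC_IOPD"]]),
#'                       simConfig(seed = 11), n = 3)
#' profileSummary(prof)[1:3, ]
#' @export
runReplicates <- function(net, clamps = emptyClamps(), config = simConfig(),
                          n = 3L, init = NULL) {
  stopifnot(n >= 1L)
  seeds <- deriveSeeds(config@seed, n)
  vals <- NULL
  conv <- logical(n)
  for (r in seq_len(n)) {
    cfg_r <- config
    cfg_r@seed <- seeds[r]
    init_r <- if (is.matrix(init)) init[r, ] else init
    tr <- runSimulation(net, clamps, cfg_r, init = init_r)
    if (is.null(vals))
      vals <- matrix(NA_real_, n, ncol(states(tr)),
                     dimnames = list(NULL, colnames(states(tr))))
    vals[r, ] <- terminalState(tr)
    conv[r] <- isConverged(tr)
  }
  if (any(!conv))
    warning(sum(!conv), " replicate(s) did not converge", call. = FALSE)
  new("SteadyStateProfile", values = vals, convergedReplicates = conv,
      level = 0.99)
}

#' Derive replicate seeds from a master seed
#'
#' Deterministic: the master seed fully determines the replicate seeds, and
#' replicate r always receives the r-th derived seed regardless of how many
#' replicates are requested.
#'
#' @param seed master integer seed.
#' @param n number of seeds.
#' @return integer vector of length `n`.
#' @export
deriveSeeds <- function(seed, n) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Export a profile summary as CSV
#'
#' @param profile a [SteadyStateProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  utils::write.csv(profileSummary(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a profile summary CSV back as a named mean vector
#'
#' @param path CSV written by [writeProfileCsv()] (columns `concept`,
#'   `mean`, ...).
#' @return named numeric vector of means.
#' @export
readProfileCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("concept", "mean") %in% names(df)))
  stats::setNames(df$mean, df$concept)
}
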