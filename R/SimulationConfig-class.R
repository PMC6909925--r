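#' Simulation configuration
#'
#' Free parameters of the iterated update rule
#' \deqn{x(t+1) = \tanh\!\big(g\,[W x(t) + \mu\, x(t)]\big)}
#' and of convergence detection and replicate noise.
#'
#' @slot maxIterations iteration budget (default 1000).
#' @slot tol convergence tolerance \eqn{\epsilon} on the max-norm of
#'   successive state differences (default 1e-4).
#' @slot window number of consecutive sub-tolerance differences required to
#'   declare convergence (default 5).
#' @slot memory state-memory coefficient \eqn{\mu \in [0, 1]}
#'   (default 1: each concept feeds its previous value back into its own
#'   update, alongside the network inflow).
#' @slot squashGain gain \eqn{g > 0} of the tanh squashing (default 1).
#' @slot noiseSigma magnitude of the uniform jitter applied to the initial
#'   values of unclamped concepts when simulating replicates (default 0.05;
#'   0 disables noise).
#' @slot noiseModel "initial" (jitter initial state; default) or "weights"
#'   (jitter edge weights instead).
#' @slot seed integer seed controlling all randomness.
#' @seealso [simConfig()], [runSimulation()], [runReplicates()]
#' @export
setClass("SimulationConfig",
         representation(maxIterations = "integer", tol = "numeric",
                        window = "integer", memory = "numeric",
                        squashGain = "numeric", noiseSigma = "numeric",
                        noiseModel = "character", seed = "integer"),
         prototype(maxIterations = 1000L, tol = 1e-4, window = 5L,
                   memory = 1.0, squashGain = 1.0, noiseSigma = 0.05,
                   noiseModel = "initial", seed = 1L))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@tol <= 0) msgs <- c(msgs, "tol must be > 0")
  if (object@window < 1L) msgs <- c(msgs, "window must be >= 1")
  if (object@maxIterations < object@window)
    msgs <- c(msgs, "maxIterations must be >= window")
  if (object@memory < 0 || object@memory > 1)
    msgs <- c(msgs, "memory must lie in [0, 1]")
  if (object@squashGain <= 0) msgs <- c(msgs, "squashGain must be > 0")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("initial", "weights"))
    msgs <- c(msgs, "noiseModel must be 'initial' or 'weights'")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulation configuration
#'
#' @param maxIterations,tol,window,memory,squashGain,noiseSigma,noiseModel,seed
#'   see [SimulationConfig-class] for meanings and defaults.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(noiseSigma = 0, seed = 7)
#' @export
simConfig <- function(maxIterations = 1000L, tol = 1e-4, window = 5L,
                      memory = 1.0, squashGain = 1.0, noiseSigma = 0.05,
                      noiseModel = "initial", seed = 1L) {
  new("SimulationConfig", maxIterations = as.integer(maxIterations),
      tol = tol, window = as.integer(window), memory = memory,
      squashGain = squashGain, noiseSigma = noiseSigma,
      noiseModel = noiseModel, seed = as.integer(seed))
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simConfig()] (snake_case accepted, e.g.
#' `max_iterations`); missing keys keep their defaults.
#'
#' @param path path to a YAML `key: value` file.
#' @return A [SimulationConfig-class] object.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  canon <- c(max_iterations = "maxIterations", tol = "tol",
             convergence_tol = "tol", window = "window",
             convergence_window = "window", memory = "memory",
             memory_coefficient = "memory", squash_gain = "squashGain",
             noise_sigma = "noiseSigma", noise_model = "noiseModel",
             seed = "seed")
  nm <- names(vals)
  hit <- nm %in% names(canon)
  nm[hit] <- canon[nm[hit]]
  names(vals) <- nm
  known <- names(formals(simConfig))
  unknown <- setdiff(nm, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(simConfig, vals)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: maxIterations=%d tol=%g window=%d ",
                     "memory=%g gain=%g noise=%g(%s) seed=%d\n"),
              object@maxIterations, object@tol, object@window,
              object@memory, object@squashGain, object@noiseSigma,
              object@noiseModel, object@seed))
})
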