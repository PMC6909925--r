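#' The squashing function
#'
#' Hyperbolic-tangent squashing with gain `g`: odd, strictly increasing,
#' bounded in (-1, 1), with `squash(0) == 0`. This keeps every concept
#' activation qualitative (a level between full repression -1 and full
#' activation +1) no matter how much signed input flows into it.
#'
#' @param v finite numeric vector.
#' @param gain positive gain (default 1).
#' @return `tanh(gain * v)`.
#' @examples
#' squash(c(-5, 0, 5))
#' @export
squash <- function(v, gain = 1) {
  if (any(!is.finite(v))) stop("non-finite input to squash", call. = FALSE)
  tanh(gain * v)
}

#' One synchronous update of the network map
#'
#' Computes \eqn{x' = \tanh(g [W x + \mu x])} and then overwrites the
#' entries of hold clamps active at iteration `iteration` with their clamp
#' values, so clamped concepts are exact. Deterministic.
#'
#' @param x named state vector matching the network's concepts.
#' @param net a [ConceptNetwork-class] (or a pre-computed weight matrix).
#' @param clamps clamp data.frame (see [clampSpec()]); only `hold` rows
#'   are applied here.
#' @param config a [SimulationConfig-class].
#' @param iteration the index of the state being produced (affects which
#'   `active_from` clamps apply; default 1).
#' @return The next state vector, all entries in \[-1, 1\].
#' @export
stepState <- function(x, net, clamps = emptyClamps(), config = simConfig(),
                      iteration = 1L) {
  W <- if (is.matrix(net)) net else weightMatrix(net)
  if (length(x) != ncol(W))
    stop("state dimension (", length(x), ") does not match network (",
         ncol(W), ")", call. = FALSE)
  if (!is.matrix(net)) clamps <- .check_clamps(clamps, net)
  x_new <- squash(drop(W %*% x) + config@memory * x, config@squashGain)
  hold <- clamps[clamps$mode == "hold" & clamps$active_from <= iteration, ,
                 drop = FALSE]
  if (nrow(hold) > 0L)
    x_new[match(hold$concept, colnames(W))] <- hold$value
  names(x_new) <- colnames(W)
  x_new
}

#' Run a clamped simulation to steady state
#'
#' Starts from the all-zero state vector, applies `initial_only` clamp
#' values and iteration-0 hold clamps, then iterates [stepState()] until
#' the convergence window is satisfied or the iteration budget is
#' exhausted. With `config@noiseSigma > 0`, unclamped concepts receive
#' i.i.d. uniform jitter on their initial values (seeded, so runs are
#' reproducible); this is the replicate-to-replicate variability model.
#'
#' @param net a [ConceptNetwork-class].
#' @param clamps clamp data.frame (see [clampSpec()]).
#' @param config a [SimulationConfig-class].
#' @param init optional named initial state (overrides the zero vector;
#'   used to continue a run, e.g. phase 2 of a treatment). Initial-only
#'   clamps are not re-applied when `init` is given.
#' @param overtrain if TRUE, keep iterating to `maxIterations` even after
#'   convergence, so [classifyAttractor()] can check that the steady state
#'   persists (no late drift or oscillation).
#' @return A [StateTrajectory-class] (full trajectory recorded).
#' @examples
#' net <- iopdNetwork()
#' cl <- recipeClamps(iopdRecipes()[["aiSkMC_IOPD"]])
#' tr <- runSimulation(net, cl, simConfig(noiseSigma = 0))
#' terminalState(tr)[["lysosomal_glycogen"]]
#' @export
runSimulation <- function(net, clamps = emptyClamps(), config = simConfig(),
                          init = NULL, overtrain = FALSE) {
  stopifnot(is(net, "ConceptNetwork"), is(config, "SimulationConfig"))
  clamps <- .check_clamps(clamps, net)
  W <- weightMatrix(net)
  ids <- colnames(W)
  n <- length(ids)

  if (config@noiseSigma > 0 && config@noiseModel == "weights") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(config@seed)
    jit <- matrix(stats::runif(n * n, -config@noiseSigma,
                               config@noiseSigma), n, n)
    W <- W + jit * (W != 0)
    W[W > 1] <- 1; W[W < -1] <- -1
  }

  if (is.null(init)) {
    x <- stats::setNames(numeric(n), ids)
    if (config@noiseSigma > 0 && config@noiseModel == "initial") {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(config@seed)
      x <- x + stats::runif(n, -config@noiseSigma, config@noiseSigma)
    }
    ini <- clamps[clamps$mode == "initial_only", , drop = FALSE]
    if (nrow(ini) > 0L) x[match(ini$concept, ids)] <- ini$value
  } else {
    stopifnot(length(init) == n)
    x <- stats::setNames(as.numeric(init[ids]), ids)
  }
  hold0 <- clamps[clamps$mode == "hold" & clamps$active_from == 0L, ,
                  drop = FALSE]
  if (nrow(hold0) > 0L) x[match(hold0$concept, ids)] <- hold0$value

  traj <- matrix(NA_real_, config@maxIterations + 1L, n,
                 dimnames = list(NULL, ids))
  traj[1L, ] <- x
  run <- 0L          # consecutive sub-tolerance steps
  conv_at <- NA_integer_
  t_final <- 0L
  for (t in seq_len(config@maxIterations)) {
    x_new <- stepState(x, W, clamps, config, iteration = t)
    traj[t + 1L, ] <- x_new
    if (max(abs(x_new - x)) < config@tol) run <- run + 1L else run <- 0L
    x <- x_new
    t_final <- t
    if (run >= config@window && is.na(conv_at)) {
      conv_at <- t
      if (!overtrain) break
    }
  }
  traj <- traj[seq_len(t_final + 1L), , drop = FALSE]
  out <- new("StateTrajectory", states = traj,
             converged = !is.na(conv_at),
             iterationsToConvergence = conv_at,
             attractorClass = "non_convergent",
             cyclePeriod = NA_integer_)
  cls <- classifyAttractor(out, config@tol)
  out@attractorClass <- cls$attractor_class
  out@cyclePeriod <- cls$cycle_period
  out
}

#' Convergence assessment on a recorded trajectory
#'
#' A trajectory has converged at the first iteration `t >= k` such that the
#' max-norm difference between successive states is below `tol` for the `k`
#' consecutive steps ending at `t`.
#'
#' @param traj a [StateTrajectory-class] or a state matrix (rows =
#'   iterations 0, 1, ...).
#' @param tol tolerance \eqn{\epsilon}.
#' @param window window length `k`.
#' @return list with `converged` (logical) and `iteration` (first
#'   qualifying t, NA if none).
#' @export
assessConvergence <- function(traj, tol = 1e-4, window = 5L) {
  m <- if (is(traj, "StateTrajectory")) states(traj) else as.matrix(traj)
  if (nrow(m) < 2L)
    return(list(converged = FALSE, iteration = NA_integer_))
  d <- apply(abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]),
             1L, max)                      # d[t] compares states t and t-1
  ok <- d < tol
  run <- 0L
  for (t in seq_along(ok)) {
    run <- if (ok[t]) run + 1L else 0L
    if (run >= window)
      return(list(converged = TRUE, iteration = t))
  }
  list(converged = FALSE, iteration = NA_integer_)
}

#' Classify the terminal behaviour of a trajectory
#'
#' `fixed_point` if the trajectory converged and every later recorded state
#' stays within `tol` (per concept) of the state at convergence — running
#' with `overtrain = TRUE` extends this check through the full iteration
#' budget, the guard against late "overtraining" drift. `limit_cycle` if
#' the terminal window repeats with some smallest period `p >= 2`.
#' `non_convergent` otherwise.
#'
#' @param traj a [StateTrajectory-class] or state matrix.
#' @param tol tolerance.
#' @param max_period largest cycle period searched (default 20).
#' @param window convergence window (used when `traj` is a bare matrix).
#' @return list with `attractor_class` and `cycle_period` (NA unless a
#'   limit cycle).
#' @export
classifyAttractor <- function(traj, tol = 1e-4, max_period = 20L,
                              window = 5L) {
  if (is(traj, "StateTrajectory")) {
    m <- states(traj)
    conv <- list(converged = isConverged(traj),
                 iteration = iterationsToConvergence(traj))
  } else {
    m <- as.matrix(traj)
    conv <- assessConvergence(m, tol, window)
  }
  T_last <- nrow(m)
  if (conv$converged) {
    ref <- m[conv$iteration + 1L, ]        # row index = iteration + 1
    later <- m[seq(conv$iteration + 1L, T_last), , drop = FALSE]
    if (max(abs(sweep(later, 2L, ref))) <= tol * max(1, window))
      return(list(attractor_class = "fixed_point",
                  cycle_period = NA_integer_))
  }
  # cycle search over the terminal window
  for (p in seq(2L, max_period)) {
    if (T_last <= 2L * p) break
    reps <- min(3L, (T_last - 1L) %/% p)   # require a few repeats
    hit <- TRUE
    for (r in seq_len(reps)) {
      if (max(abs(m[T_last, ] - m[T_last - r * p, ])) >= tol) {
        hit <- FALSE; break
      }
    }
    # reject periods that are really a fixed point in disguise
    if (hit && max(abs(m[T_last, ] - m[T_last - 1L, ])) >= tol)
      return(list(attractor_class = "limit_cycle",
                  cycle_period = as.integer(p)))
  }
  list(attractor_class = "non_convergent", cycle_period = NA_integer_)
}
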