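#' DoseResponseResult: an inhibition sweep over a target
#'
#' @slot table data.frame in tidy form: `fraction`, `readout`, `mean`,
#'   `sem` — terminal values of each readout concept at each inhibition
#'   fraction (phase-2 values under the two-phase schedule).
#' @slot established named logical: whether the disease phenotype was
#'   established at each fraction (see [phenotypeEstablished()]).
#' @slot target inhibited concept id.
#' @slot schedule "after_disease_steady_state" or "from_start".
#' @seealso [doseResponseSweep()]
#' @export
setClass("DoseResponseResult",
         representation(table = "data.frame", established = "logical",
                        target = "character", schedule = "character"))

setValidity("DoseResponseResult", function(object) {
  msgs <- character()
  if (!all(c("fraction", "readout", "mean", "sem") %in%
             names(object@table)))
    msgs <- c(msgs, "table needs columns fraction, readout, mean, sem")
  fr <- unique(object@table$fraction)
  if (is.unsorted(fr)) msgs <- c(msgs, "grid must be sorted ascending")
  if (nrow(object@table) == 0L) msgs <- c(msgs, "readout set must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DoseResponseResult-class tidy readout table.
#' @param x,object a DoseResponseResult.
#' @export
doseResponseTable <- function(x) x@table

setMethod("show", "DoseResponseResult", function(object) {
  fr <- unique(object@table$fraction)
  cat("DoseResponseResult:", object@target, "inhibition,",
      length(fr), "dose(s) [", object@schedule, "]\n")
  cat("  readouts:", paste(unique(object@table$readout), collapse = ", "),
      "\n")
  cat("  phenotype established at:",
      paste(fr[object@established], collapse = ", "), "\n")
})

# default phenotype set and readout set for the disease models
.default_readouts <- c("intracellular_calcium", "ROS",
                       "mitochondrial_dysfunction", "cell_death")
.default_phenotype <- c("lysosomal_glycogen", "mitochondrial_dysfunction",
                        "intracellular_calcium", "cell_death")

#' Is the disease phenotype established?
#'
#' The phenotype counts as established when every concept of the phenotype
#' set is simultaneously above a strict positive margin (default 0.05 —
#' the expression-call threshold of 0 would count the all-zero initial
#' state as "present", so establishment uses a margin).
#'
#' @param x a [SteadyStateProfile-class] (checked at its terminal means) or
#'   a [StateTrajectory-class] (checked at every recorded iteration:
#'   established if the condition ever holds).
#' @param phenotype concept ids defining the phenotype.
#' @param margin strict threshold (default 0.05).
#' @return logical.
#' @export
phenotypeEstablished <- function(x, phenotype = .default_phenotype,
                                 margin = 0.05) {
  if (is(x, "SteadyStateProfile"))
    return(all(profileMeans(x)[phenotype] > margin))
  if (is(x, "StateTrajectory")) {
    m <- states(x)[, phenotype, drop = FALSE]
    return(any(apply(m > margin, 1L, all)))
  }
  stop("x must be a SteadyStateProfile or StateTrajectory", call. = FALSE)
}

#' Dose-response sweep of fractional target inhibition
#'
#' Runs the disease recipe once per grid fraction with the target inhibited
#' at that fraction, and reports the terminal mean of each readout concept.
#' The 0 grid point is a no-treatment sentinel (no clamp at all), giving
#' the untreated disease baseline — a clamp at exactly 0 would instead
#' silence the target, which is not "no treatment".
#'
#' Schedules: `after_disease_steady_state` (default) runs disease to steady
#' state, then adds the inhibition (two-phase); `from_start` applies the
#' inhibition from iteration 0, and `phenotype_established` then records
#' whether the disease phenotype ever appears before reversal.
#'
#' @param net a [ConceptNetwork-class].
#' @param recipe disease [Recipe-class] or bundled recipe name.
#' @param target concept id to inhibit.
#' @param grid inhibition fractions in \[0, 1\] (sorted internally).
#' @param readouts readout concept ids (default: intracellular calcium,
#'   ROS, mitochondrial dysfunction, cell death).
#' @param config a [SimulationConfig-class].
#' @param n replicates per dose (default 3).
#' @param schedule see above.
#' @param phenotype phenotype concept set for establishment calls.
#' @return A [DoseResponseResult-class].
#' @examples
#' dr <- doseResponseSweep(iopdNetwork(), "aiSkMC_IOPD", "VDCC",
#'                         grid = c(0, 0.25, 1), n = 1,
#'                         config = simConfig(noiseSigma = 0))
#' doseResponseTable(dr)
#' @export
doseResponseSweep <- function(net, recipe, target, grid,
                              readouts = .default_readouts,
                              config = simConfig(), n = 3L,
                              schedule = c("after_disease_steady_state",
                                           "from_start"),
                              phenotype = .default_phenotype) {
  schedule <- match.arg(schedule)
  if (length(grid) == 0L) stop("empty dose grid", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 1))
    stop("grid fractions must lie in [0, 1]", call. = FALSE)
  recipe <- .resolve_recipe(recipe)
  readouts <- resolveConcepts(net, readouts)
  phenotype <- resolveConcepts(net, phenotype)
  grid <- sort(unique(grid))
  rows <- list()
  established <- logical(length(grid))
  for (i in seq_along(grid)) {
    f <- grid[i]
    if (schedule == "after_disease_steady_state") {
      tp <- runTwoPhase(net, recipe, target,
                        fraction = if (f == 0) NA_real_ else f,
                        config = config, n = n)
      established[i] <- phenotypeEstablished(tp$phase1, phenotype)
      prof <- tp$phase2
    } else {
      rec_f <- if (f == 0) recipe else applyInhibition(recipe, target, f)
      cl <- recipeClamps(rec_f, net)
      est <- logical(n)
      vals <- NULL
      seeds <- deriveSeeds(config@seed, n)
      conv <- logical(n)
      for (r in seq_len(n)) {
        cfg_r <- config; cfg_r@seed <- seeds[r]
        tr <- runSimulation(net, cl, cfg_r)
        est[r] <- phenotypeEstablished(tr, phenotype)
        if (is.null(vals))
          vals <- matrix(NA_real_, n, ncol(states(tr)),
                         dimnames = list(NULL, colnames(states(tr))))
        vals[r, ] <- terminalState(tr)
        conv[r] <- isConverged(tr)
      }
      established[i] <- all(est)
      prof <- new("SteadyStateProfile", values = vals,
                  convergedReplicates = conv, level = 0.99)
    }
    sm <- profileSummary(prof)
    sm <- sm[match(readouts, sm$concept), ]
    rows[[i]] <- data.frame(fraction = f, readout = sm$concept,
                            mean = sm$mean, sem = sm$sem,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  names(established) <- as.character(grid)
  new("DoseResponseResult", table = tab, established = established,
      target = target, schedule = schedule)
}
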