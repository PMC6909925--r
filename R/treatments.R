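#' Two-phase treatment simulation
#'
#' Phase 1 runs the disease recipe to steady state, establishing the
#' disease phenotype; phase 2 adds the treatment clamp (target held at
#' `-fraction`) and continues from the phase-1 terminal states to a new
#' steady state. This is the schedule for a drug given after disease onset.
#'
#' @param net a [ConceptNetwork-class].
#' @param recipe the disease [Recipe-class] (or bundled recipe name).
#' @param target concept id to inhibit in phase 2.
#' @param fraction inhibition fraction in \[0, 1\]; NA means no treatment
#'   (phase 2 simply continues phase 1 — the untreated sentinel).
#' @param config a [SimulationConfig-class].
#' @param n replicates per phase (default 3).
#' @param schedule must be "after_disease_steady_state"; requests for a
#'   from-start schedule belong in [doseResponseSweep()] and are an error
#'   here.
#' @return list with elements `phase1` and `phase2`, both
#'   [SteadyStateProfile-class] objects over the same replicates.
#' @examples
#' tp <- runTwoPhase(iopdNetwork(), "aiSkMC_IOPD", "calpain", 0.25,
#'                   simConfig(noiseSigma = 0), n = 1)
#' profileMeans(tp$phase2)[["cell_death"]] <
#'   profileMeans(tp$phase1)[["cell_death"]]
#' @export
runTwoPhase <- function(net, recipe, target, fraction,
                        config = simConfig(), n = 3L,
                        schedule = "after_disease_steady_state") {
  if (!identical(schedule, "after_disease_steady_state"))
    stop("runTwoPhase only implements the 'after_disease_steady_state' ",
         "schedule; use doseResponseSweep(schedule = 'from_start') ",
         "for treatment from iteration 0", call. = FALSE)
  recipe <- .resolve_recipe(recipe)
  clamps1 <- recipeClamps(recipe, net)
  phase1 <- runReplicates(net, clamps1, config, n = n)
  if (any(!phase1@convergedReplicates))
    stop("phase 1 did not converge in ",
         sum(!phase1@convergedReplicates), " replicate(s); ",
         "cannot establish the disease steady state", call. = FALSE)
  clamps2 <- clamps1
  if (!is.na(fraction)) {
    treated <- applyInhibition(recipe, target, fraction)
    clamps2 <- recipeClamps(treated, net)
  }
  phase2 <- runReplicates(net, clamps2, config, n = n,
                          init = terminalValues(phase1))
  list(phase1 = phase1, phase2 = phase2)
}

#' Compare genotype steady-state profiles
#'
#' Per-concept difference between a disease and a wild-type profile with a
#' three-way direction call: "up" / "down" when the difference exceeds a
#' dead-band `delta`, "unchanged" within it (the operational reading of
#' "not different from WT", which the narrative results never quantify).
#'
#' @param profile_wt,profile_disease [SteadyStateProfile-class] objects
#'   over the same concept universe.
#' @param delta dead-band half-width (default 0.05).
#' @return data.frame with `concept`, `mean_wt`, `mean_disease`, `delta`
#'   (disease minus WT) and `direction`.
#' @export
compareGenotypes <- function(profile_wt, profile_disease, delta = 0.05) {
  ids <- conceptIds(profile_wt)
  if (!identical(sort(ids), sort(conceptIds(profile_disease))))
    stop("profiles cover different concept universes", call. = FALSE)
  mw <- profileMeans(profile_wt)[ids]
  md <- profileMeans(profile_disease)[ids]
  d <- md - mw
  direction <- ifelse(d > delta, "up", ifelse(d < -delta, "down",
                                              "unchanged"))
  data.frame(concept = ids, mean_wt = unname(mw),
             mean_disease = unname(md), delta = unname(d),
             direction = unname(direction), stringsAsFactors = FALSE)
}
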