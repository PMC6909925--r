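#' Recipe: a declarative simulation experiment
#'
#' A recipe bundles the interventions defining one study model: the cell
#' context held on throughout, transient reprogramming-factor pulses,
#' continuously present drugs/transgenes, and gene deletions.
#'
#' @slot name unique token naming the model (e.g. "aiSkMC_IOPD").
#' @slot baseContext concept ids held at +1 for the whole run (the cell
#'   identity context, e.g. "Fibroblast").
#' @slot factors clamp data.frame of the recipe's factors: transient
#'   (`initial_only`) pulses and held (`hold`) drugs/transgenes.
#' @slot deletions concept ids locked off (held at -1).
#' @slot label "WT" or "disease".
#' @seealso [makeRecipe()], [iopdRecipes()], [applyKnockout()],
#'   [applyInhibition()]
#' @export
setClass("Recipe",
         representation(name = "character", baseContext = "character",
                        factors = "data.frame", deletions = "character",
                        label = "character"))

setValidity("Recipe", function(object) {
  msgs <- character()
  if (!object@label %in% c("WT", "disease"))
    msgs <- c(msgs, "label must be 'WT' or 'disease'")
  if (length(intersect(object@deletions, object@factors$concept)))
    msgs <- c(msgs, "deletions must be disjoint from factor concepts")
  if (length(intersect(object@deletions, object@baseContext)))
    msgs <- c(msgs, "deletions must be disjoint from the base context")
  if (length(msgs)) msgs else TRUE
})

#' Build a recipe from a Table-1-style declaration
#'
#' Transient factors (reprogramming pulses) become `initial_only` clamps at
#' +1; held factors (drugs and transgenes continuously present) become
#' `hold` clamps at +1; deletions become `hold` clamps at -1.
#'
#' @param name recipe name.
#' @param transient concept ids turned on at iteration 0 only (e.g. the
#'   OSKM factors).
#' @param held concept ids held on for the run (e.g. Doxycycline, an
#'   exogenous MyoD1 transgene).
#' @param deletions concept ids locked off.
#' @param base_context cell-identity concepts held on (default
#'   "Fibroblast").
#' @param label "WT" or "disease".
#' @param net optional [ConceptNetwork-class]; when given, all referenced
#'   concepts are resolved against it and unknown names are an error.
#' @return A [Recipe-class].
#' @examples
#' makeRecipe("aiSkMC_WT", held = c("MyoD1_exo", "Doxycycline"),
#'            net = iopdNetwork())
#' @export
makeRecipe <- function(name, transient = character(), held = character(),
                       deletions = character(),
                       base_context = "Fibroblast", label = "WT",
                       net = NULL) {
  if (!is.null(net)) {
    transient <- resolveConcepts(net, transient)
    held <- resolveConcepts(net, held)
    deletions <- resolveConcepts(net, deletions)
    base_context <- resolveConcepts(net, base_context)
  }
  factors <- rbind(
    if (length(transient))
      do.call(rbind, lapply(transient, clampSpec, mode = "initial_only",
                            value = 1)),
    if (length(held))
      do.call(rbind, lapply(held, clampSpec, mode = "hold", value = 1)))
  if (is.null(factors)) factors <- emptyClamps()
  new("Recipe", name = name, baseContext = as.character(base_context),
      factors = factors, deletions = as.character(deletions), label = label)
}

#' @describeIn Recipe-class expand a recipe into the full clamp set:
#'   base-context hold clamps at +1, the factor clamps, and deletion hold
#'   clamps at -1.
#' @param x,object a Recipe.
#' @param net optional network to validate concept ids against.
#' @param ... unused.
#' @export
setMethod("recipeClamps", "Recipe", function(x, net = NULL, ...) {
  cl <- x@factors
  if (length(x@baseContext))
    cl <- rbind(do.call(rbind, lapply(x@baseContext, clampSpec,
                                      mode = "hold", value = 1)), cl)
  if (length(x@deletions))
    cl <- rbind(cl, do.call(rbind, lapply(x@deletions, clampSpec,
                                          mode = "hold", value = -1)))
  if (!is.null(net)) cl <- .check_clamps(cl, net)
  rownames(cl) <- NULL
  cl
})

setMethod("show", "Recipe", function(object) {
  cat("Recipe", object@name, sprintf("[%s]\n", object@label))
  f <- object@factors
  tr <- f$concept[f$mode == "initial_only"]
  hd <- f$concept[f$mode == "hold"]
  cat("  context:", paste(object@baseContext, collapse = ", "), "\n")
  if (length(tr)) cat("  transient:", paste(tr, collapse = ", "), "\n")
  if (length(hd)) cat("  held:", paste(hd, collapse = ", "), "\n")
  if (length(object@deletions))
    cat("  locked off:", paste(object@deletions, collapse = ", "), "\n")
})

#' The four bundled IOPD study recipes
#'
#' The models evaluated on the bundled network: reprogramming to
#' pluripotency (aiPSC) uses a transient OSKM pulse plus held Doxycycline
#' and exogenous MyoD1; direct transdifferentiation to skeletal muscle
#' (aiSkMC) uses held exogenous MyoD1 plus Doxycycline without OSKM.
#' The IOPD variants lock the GAA gene off.
#'
#' @return Named list of [Recipe-class] objects: `aiPSC_WT`, `aiPSC_IOPD`,
#'   `aiSkMC_WT`, `aiSkMC_IOPD`.
#' @export
iopdRecipes <- function() {
  oskm <- c("OCT4", "SOX2", "KLF4", "cMYC")
  held <- c("Doxycycline", "MyoD1_exo")
  list(
    aiPSC_WT = makeRecipe("aiPSC_WT", transient = oskm, held = held),
    aiPSC_IOPD = makeRecipe("aiPSC_IOPD", transient = oskm, held = held,
                            deletions = "GAA", label = "disease"),
    aiSkMC_WT = makeRecipe("aiSkMC_WT", held = held),
    aiSkMC_IOPD = makeRecipe("aiSkMC_IOPD", held = held,
                             deletions = "GAA", label = "disease"))
}

#' Lock a gene off in a recipe
#'
#' Adds the concept to the recipe's deletions (a hold clamp at -1).
#' Idempotent: knocking out an already-deleted concept returns the recipe
#' unchanged. Knocking out a held-on factor is a contradictory clamp and an
#' error.
#'
#' @param recipe a [Recipe-class].
#' @param concept concept id to lock off.
#' @return The modified [Recipe-class].
#' @export
applyKnockout <- function(recipe, concept) {
  stopifnot(is(recipe, "Recipe"), length(concept) == 1L)
  if (concept %in% recipe@deletions) return(recipe)
  if (concept %in% recipe@factors$concept[recipe@factors$mode == "hold"] ||
      concept %in% recipe@baseContext)
    stop("contradictory clamp: ", concept,
         " is held on by the recipe", call. = FALSE)
  recipe@deletions <- c(recipe@deletions, concept)
  recipe@label <- "disease"
  validObject(recipe)
  recipe
}

#' Add fractional inhibition of a target to a recipe
#'
#' Models a dose of an inhibitor as a hold clamp at `-f`: `f = 1`
#' reproduces a full knockout; `f = 0` clamps the target to neutral 0,
#' which silences it — distinct from leaving it unclamped (an untreated
#' baseline is expressed by *omitting* the clamp; see
#' [doseResponseSweep()], which uses a no-treatment sentinel for the 0%
#' grid point).
#'
#' @param recipe a [Recipe-class].
#' @param target concept id to inhibit.
#' @param fraction inhibition fraction `f` in \[0, 1\].
#' @param active_from first iteration the inhibition applies (default 0).
#' @return The modified [Recipe-class].
#' @export
applyInhibition <- function(recipe, target, fraction, active_from = 0L) {
  stopifnot(is(recipe, "Recipe"), length(target) == 1L)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("inhibition fraction must lie in [0, 1]", call. = FALSE)
  if (target %in% recipe@factors$concept[recipe@factors$mode == "hold"] ||
      target %in% recipe@baseContext)
    stop("contradictory clamp: ", target, " is held on by the recipe",
         call. = FALSE)
  if (fraction == 1) {
    if (target %in% recipe@deletions) return(recipe)
    recipe@deletions <- c(recipe@deletions, target)
  } else {
    recipe@factors <- rbind(
      recipe@factors,
      clampSpec(target, "hold", -fraction, active_from = active_from))
  }
  validObject(recipe)
  recipe
}
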