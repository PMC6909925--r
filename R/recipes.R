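#' Run a recipe on a network
#'
#' Convenience wrapper: expands the recipe into clamps and runs a replicate
#' ensemble to steady state.
#'
#' @param net a [ConceptNetwork-class].
#' @param recipe a [Recipe-class] or the name of a bundled recipe from
#'   [iopdRecipes()].
#' @param config a [SimulationConfig-class].
#' @param n number of replicates (default 3).
#' @return A [SteadyStateProfile-class].
#' @examples
#' prof <- runRecipe(iopdNetwork(), "aiSkMC_WT", simConfig(noiseSigma = 0))
#' profileMeans(prof)[["lysosomal_glycogen"]] < 0
#' @export
runRecipe <- function(net, recipe, config = simConfig(), n = 3L) {
  recipe <- .resolve_recipe(recipe)
  runReplicates(net, recipeClamps(recipe, net), config, n = n)
}

.resolve_recipe <- function(recipe) {
  if (is(recipe, "Recipe")) return(recipe)
  all <- iopdRecipes()
  if (is.character(recipe) && length(recipe) == 1L) {
    if (!recipe %in% names(all))
      stop("unknown recipe '", recipe, "'; available: ",
           paste(names(all), collapse = ", "), call. = FALSE)
    return(all[[recipe]])
  }
  stop("recipe must be a Recipe object or a bundled recipe name",
       call. = FALSE)
}
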