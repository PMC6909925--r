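#' Clamping interventions
#'
#' A clamp forces a concept's activation. Two modes:
#' \describe{
#'   \item{`initial_only`}{the concept is set to `value` in the initial
#'     state only and then evolves freely — e.g. a transient reprogramming
#'     factor pulse ("turned on, not locked on").}
#'   \item{`hold`}{the concept is overwritten with `value` at every
#'     iteration from `active_from` onwards — e.g. a gene deletion held at
#'     -1 ("locked off"), a drug held at +1, or fractional inhibition held
#'     at `-f`.}
#' }
#'
#' Clamp sets are plain data.frames with columns `concept`, `mode`,
#' `value`, `active_from`; combine them with `rbind()`.
#'
#' @param concept concept id (character).
#' @param mode "initial_only" or "hold".
#' @param value clamp value in \[-1, 1\].
#' @param active_from first iteration at which a hold clamp applies
#'   (default 0). Ignored, with a warning, for `initial_only` clamps.
#' @return A one-row clamp data.frame.
#' @examples
#' rbind(clampSpec("OCT4", "initial_only", 1),
#'       clampSpec("GAA", "hold", -1))
#' @export
clampSpec <- function(concept, mode = c("hold", "initial_only"), value,
                      active_from = 0L) {
  mode <- match.arg(mode)
  stopifnot(length(concept) == 1L, length(value) == 1L)
  if (!is.finite(value) || abs(value) > 1)
    stop("clamp value must lie in [-1, 1]", call. = FALSE)
  if (active_from < 0) stop("active_from must be >= 0", call. = FALSE)
  if (mode == "initial_only" && active_from > 0) {
    warning("initial_only clamps ignore active_from > 0", call. = FALSE)
    active_from <- 0L
  }
  data.frame(concept = as.character(concept), mode = mode,
             value = as.numeric(value),
             active_from = as.integer(active_from),
             stringsAsFactors = FALSE)
}

#' @rdname clampSpec
#' @export
emptyClamps <- function() {
  data.frame(concept = character(), mode = character(), value = numeric(),
             active_from = integer(), stringsAsFactors = FALSE)
}

# validate a clamp set against a network; returns the clamp df with
# concepts resolved to canonical ids
.check_clamps <- function(clamps, net) {
  if (is.null(clamps)) clamps <- emptyClamps()
  stopifnot(all(c("concept", "mode", "value", "active_from") %in%
                  names(clamps)))
  if (nrow(clamps) == 0L) return(clamps)
  clamps$concept <- resolveConcepts(net, clamps$concept)
  if (anyDuplicated(clamps$concept[clamps$mode == "hold"]))
    stop("conflicting hold clamps on the same concept", call. = FALSE)
  if (any(!is.finite(clamps$value)) || any(abs(clamps$value) > 1))
    stop("clamp values must lie in [-1, 1]", call. = FALSE)
  clamps
}
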