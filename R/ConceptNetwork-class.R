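#' ConceptNetwork: a signed, weighted concept graph
#'
#' The simulator's substrate: a directed graph whose nodes ("concepts") are
#' genes, proteins, phenotypes or compounds and whose edges carry signed
#' weights in \eqn{[-1, 1] \setminus \{0\}}. A positive weight means the
#' source activates/increases the target; a negative weight means it
#' inhibits/decreases it. The implied weight matrix \eqn{W} has
#' \eqn{W[t, s]} equal to the weight of the relation \eqn{s \to t} and 0
#' where no relation exists.
#'
#' @slot concepts data.frame with columns `id` (unique token), `label`,
#'   `kind` (one of gene, protein, phenotype, compound) and `aliases`
#'   (";"-separated alternates, possibly empty).
#' @slot relations data.frame with columns `source`, `target`, `weight`
#'   and optional `provenance`.
#'
#' @seealso [conceptNetwork()], [readEdgeList()], [iopdNetwork()],
#'   [randomNetwork()]
#' @export
setClass("ConceptNetwork",
         representation(concepts = "data.frame", relations = "data.frame"))

.concept_kinds <- c("gene", "protein", "phenotype", "compound")

setValidity("ConceptNetwork", function(object) {
  co <- object@concepts
  re <- object@relations
  msgs <- character()
  need_c <- c("id", "label", "kind", "aliases")
  need_r <- c("source", "target", "weight")
  if (!all(need_c %in% names(co)))
    msgs <- c(msgs, "concepts must have columns id, label, kind, aliases")
  if (!all(need_r %in% names(re)))
    msgs <- c(msgs, "relations must have columns source, target, weight")
  if (length(msgs) == 0L) {
    if (anyDuplicated(co$id))
      msgs <- c(msgs, "concept ids must be unique")
    if (nrow(co) > 0L && !all(co$kind %in% .concept_kinds))
      msgs <- c(msgs, paste("concept kind must be one of:",
                            paste(.concept_kinds, collapse = ", ")))
    if (nrow(re) > 0L) {
      if (!all(re$source %in% co$id) || !all(re$target %in% co$id))
        msgs <- c(msgs, "relation endpoints must be registered concepts")
      if (any(!is.finite(re$weight)) || any(re$weight == 0) ||
          any(abs(re$weight) > 1))
        msgs <- c(msgs, "weights must be non-zero, finite and within [-1, 1]")
      if (anyDuplicated(paste(re$source, re$target, sep = "\r")))
        msgs <- c(msgs, "at most one relation per ordered (source, target) pair")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConceptNetwork
#'
#' @param relations data.frame with columns `source`, `target`, `weight` and
#'   optionally `provenance`. May have zero rows.
#' @param concepts optional data.frame with columns `id` and any of `label`,
#'   `kind`, `aliases`. Concepts appearing only as relation endpoints are
#'   auto-registered with `kind = "gene"` and an empty alias list.
#' @return A [ConceptNetwork-class] object.
#' @examples
#' net <- conceptNetwork(data.frame(source = "GAA",
#'                                  target = "lysosomal_glycogen",
#'                                  weight = -1))
#' nConcepts(net)
#' @export
conceptNetwork <- function(relations = data.frame(source = character(),
                                                  target = character(),
                                                  weight = numeric()),
                           concepts = NULL) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(relations))
    relations$provenance <- rep(NA_character_, nrow(relations))
  relations <- relations[, c("source", "target", "weight", "provenance")]
  relations$source <- as.character(relations$source)
  relations$target <- as.character(relations$target)
  relations$weight <- as.numeric(relations$weight)

  ids <- unique(c(if (!is.null(concepts)) as.character(concepts$id),
                  relations$source, relations$target))
  co <- data.frame(id = ids,
                   label = ids,
                   kind = rep("gene", length(ids)),
                   aliases = rep("", length(ids)),
                   stringsAsFactors = FALSE)
  if (!is.null(concepts)) {
    concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
    m <- match(co$id, as.character(concepts$id))
    for (col in c("label", "kind", "aliases")) {
      if (col %in% names(concepts)) {
        v <- as.character(concepts[[col]])[m]
        keep <- !is.na(v) & v != ""
        co[[col]][keep] <- v[keep]
      }
    }
  }
  rownames(co) <- NULL
  rownames(relations) <- NULL
  new("ConceptNetwork", concepts = co, relations = relations)
}

#' @rdname fcmsim-generics
#' @export
setMethod("concepts", "ConceptNetwork", function(x, ...) x@concepts)

#' @rdname fcmsim-generics
#' @export
setMethod("relations", "ConceptNetwork", function(x, ...) x@relations)

#' @rdname fcmsim-generics
#' @export
setMethod("conceptIds", "ConceptNetwork", function(x, ...) x@concepts$id)

#' @rdname fcmsim-generics
#' @export
setMethod("nConcepts", "ConceptNetwork", function(x) nrow(x@concepts))

#' @rdname fcmsim-generics
#' @export
setMethod("nRelations", "ConceptNetwork", function(x) nrow(x@relations))

#' @describeIn ConceptNetwork-class the N x N weight matrix, rows indexed by
#'   target and columns by source, so that one synchronous update reads
#'   `W %*% x`.
#' @param x,object a ConceptNetwork.
#' @param ... unused.
#' @export
setMethod("weightMatrix", "ConceptNetwork", function(x, ...) {
  ids <- x@concepts$id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  re <- x@relations
  if (nrow(re) > 0L)
    W[cbind(match(re$target, ids), match(re$source, ids))] <- re$weight
  W
})

#' Resolve concept names against a network
#'
#' Matches tokens to canonical concept ids, case-insensitively, also
#' searching the ";"-separated alias lists.
#'
#' @param net a [ConceptNetwork-class].
#' @param x character vector of names to resolve.
#' @param error if TRUE (default) unknown names raise an error.
#' @return Character vector of canonical ids (NA for unresolved when
#'   `error = FALSE`).
#' @export
resolveConcepts <- function(net, x, error = TRUE) {
  ids <- concepts(net)$id
  lut <- tolower(ids)
  ali <- strsplit(concepts(net)$aliases, ";", fixed = TRUE)
  out <- character(length(x))
  for (i in seq_along(x)) {
    hit <- match(tolower(x[i]), lut)
    if (is.na(hit)) {
      ahit <- which(vapply(ali, function(a) tolower(x[i]) %in% tolower(a),
                           logical(1)))
      hit <- if (length(ahit)) ahit[1L] else NA_integer_
    }
    out[i] <- if (is.na(hit)) NA_character_ else ids[hit]
  }
  if (error && anyNA(out))
    stop("unknown concept(s): ", paste(x[is.na(out)], collapse = ", "),
         call. = FALSE)
  out
}

setMethod("show", "ConceptNetwork", function(object) {
  cat("ConceptNetwork with", nConcepts(object), "concepts and",
      nRelations(object), "relations\n")
  if (nRelations(object) > 0L) {
    pos <- mean(object@relations$weight > 0)
    cat(sprintf("  positive-edge fraction: %.3f\n", pos))
  }
  kinds <- table(object@concepts$kind)
  if (length(kinds))
    cat("  kinds:", paste(names(kinds), kinds, sep = ":", collapse = " "), "\n")
})
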