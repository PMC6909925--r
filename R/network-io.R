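#' Read a signed edge list into a ConceptNetwork
#'
#' Reads CSV or TSV rows `source, target, weight` (header optional,
#' auto-detected; the separator is auto-detected from the first line unless
#' given). A companion concept table may supply labels, kinds and aliases.
#'
#' @param path path to the edge-list file.
#' @param concept_table optional path to a concept table CSV with columns
#'   `id,label,kind,aliases` (aliases ";"-separated).
#' @param strict if TRUE a duplicate (source, target) pair is an error; if
#'   FALSE the last occurrence wins with a warning.
#' @param sep field separator; NULL (default) auto-detects "," vs tab.
#' @return A [ConceptNetwork-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("source,target,weight", "GAA,lysosomal_glycogen,-1.0"), f)
#' net <- readEdgeList(f)
#' nRelations(net)
#' @export
readEdgeList <- function(path, concept_table = NULL, strict = FALSE,
                         sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(conceptNetwork())
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(
    as.numeric(trimws(first[3L]))))
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = has_header, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3L)
    stop("edge list needs at least 3 columns: source, target, weight",
         call. = FALSE)
  names(df)[1:3] <- c("source", "target", "weight")
  df$weight <- suppressWarnings(as.numeric(df$weight))
  bad <- is.na(df$weight) | df$weight == 0 | abs(df$weight) > 1
  if (any(bad))
    stop("rejected edge row(s) with weight zero, non-numeric or outside ",
         "[-1, 1]: ", paste(which(bad), collapse = ", "), call. = FALSE)
  key <- paste(df$source, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    pairs <- paste(gsub("\r", " -> ", dup, fixed = TRUE), collapse = "; ")
    if (strict)
      stop("duplicate edge(s) in strict mode: ", pairs, call. = FALSE)
    warning("duplicate edge(s), last occurrence wins: ", pairs, call. = FALSE)
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  co <- NULL
  if (!is.null(concept_table)) {
    co <- utils::read.csv(concept_table, stringsAsFactors = FALSE)
    if (!"id" %in% names(co))
      stop("concept table must have an 'id' column", call. = FALSE)
    missing <- setdiff(unique(c(df$source, df$target)), co$id)
    if (length(missing))
      stop("dangling concept reference(s) not in concept table: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  conceptNetwork(df, concepts = co)
}

#' Write a ConceptNetwork as an edge list (and optional concept table)
#'
#' `readEdgeList(writeEdgeList(net, path))` reproduces the network exactly:
#' same concepts, relations and weights.
#'
#' @param net a [ConceptNetwork-class].
#' @param path output path for the edge list CSV.
#' @param concept_table optional output path for the companion concept table.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path, concept_table = NULL) {
  stopifnot(is(net, "ConceptNetwork"))
  re <- relations(net)
  cols <- c("source", "target", "weight")
  if (any(!is.na(re$provenance))) cols <- c(cols, "provenance")
  utils::write.csv(re[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = which(cols == "provenance"))
  if (!is.null(concept_table))
    utils::write.csv(concepts(net), concept_table, row.names = FALSE)
  invisible(path)
}

#' Read a SIF interaction file
#'
#' Simple interaction format: `source<TAB>sign<TAB>target` with sign
#' `activates` (weight +1) or `inhibits` (weight -1).
#'
#' @param path path to the SIF file.
#' @return A [ConceptNetwork-class].
#' @export
readSIF <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("source", "sign", "target"))
  w <- c(activates = 1, inhibits = -1)[df$sign]
  if (anyNA(w))
    stop("SIF sign must be 'activates' or 'inhibits'; got: ",
         paste(unique(df$sign[is.na(w)]), collapse = ", "), call. = FALSE)
  conceptNetwork(data.frame(source = df$source, target = df$target,
                            weight = unname(w), stringsAsFactors = FALSE))
}
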