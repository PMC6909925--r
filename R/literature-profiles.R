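#' Read a literature expectation profile
#'
#' A literature profile lists, per concept, the direction reported in the
#' wet-lab literature for a given cellular state: "up" (expressed /
#' upregulated / present) or "down" (repressed / not expressed / absent),
#' with a free-text provenance note.
#'
#' @param path CSV with columns `concept`, `expected` and optionally
#'   `provenance`.
#' @return data.frame with unique concepts.
#' @export
readLiteratureProfile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concept", "expected") %in% names(df)))
    stop("literature profile needs columns concept, expected",
         call. = FALSE)
  if (anyDuplicated(df$concept))
    stop("duplicate concepts in literature profile", call. = FALSE)
  ok <- df$expected %in% c("up", "present", "up/present",
                           "down", "absent", "down/absent")
  if (any(!ok))
    stop("expected direction must be up/present or down/absent; got: ",
         paste(unique(df$expected[!ok]), collapse = ", "), call. = FALSE)
  df
}

#' Bundled literature expectation profiles for the IOPD study models
#'
#' The feature sets the bundled network is validated against, one per
#' result suite:
#' \describe{
#'   \item{aipsc_wt_pluripotency}{17 features of the wild-type pluripotent
#'     model: the ESC marker panel up, GAA just above baseline, endogenous
#'     MyoD1 not sustained.}
#'   \item{aipsc_iopd}{7 features of the GAA-deleted pluripotent model:
#'     retained pluripotency markers, modest lysosomal glycogen
#'     accumulation, GAA off.}
#'   \item{aiskmc_differentiation}{9 transdifferentiation features (muscle
#'     markers up, Pax7 and the pluripotency markers down) shared by the WT
#'     and disease muscle models.}
#'   \item{aiskmc_iopd_disease}{9 disease features of the GAA-deleted
#'     muscle model: glycogen/LAMP2/glucose-deprivation up, GAA off,
#'     mTORC1-p and its substrates p70S6K-p/p4EBP1-p suppressed,
#'     mitochondrial dysfunction and impaired energy metabolism up.}
#'   \item{calcium_homeostasis}{directional calcium features (intracellular
#'     calcium, VDCC influx, calpain); lysosomal calcium is expected
#'     *unchanged* and is therefore checked with [compareGenotypes()]
#'     rather than a direction call.}
#'   \item{autophagy_mitophagy}{LC3, p62, Pink2, autophagy, mitophagy up.}
#'   \item{mitochondrial_function}{CytC, AIF, ROS, Caspase3, apoptosis up.}
#'   \item{bioenergetics}{ADP up, ATP down, impaired energy metabolism up.}
#'   \item{mitochondrial_morphology}{DNM1L and MFN2 up.}
#' }
#'
#' @param name optional single profile name; omit for the full named list.
#' @return A data.frame (single profile) or named list of data.frames.
#' @examples
#' nrow(iopdLiteratureProfiles("aipsc_wt_pluripotency"))  # 17
#' @export
iopdLiteratureProfiles <- function(name = NULL) {
  dir <- system.file("extdata", "profiles", package = "fcmsim",
                     mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  profs <- lapply(files, readLiteratureProfile)
  names(profs) <- sub("\\.csv$", "", basename(files))
  if (is.null(name)) return(profs)
  if (!name %in% names(profs))
    stop("unknown profile '", name, "'; available: ",
         paste(names(profs), collapse = ", "), call. = FALSE)
  profs[[name]]
}
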