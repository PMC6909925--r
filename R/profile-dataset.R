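#' Generate a labelled expression-profile dataset
#'
#' Synthetic stand-in for a simulation-derived dataset of wild-type and
#' disease steady-state profiles: each row is one profile, each marker is
#' drawn from a class-specific Gaussian truncated to \[-1, 1\]. The default
#' effect table emulates the bundled disease network's calcium-axis
#' steady-state separation, with calpain the strongest and most reliable
#' discriminator (largest mean shift, smallest dispersion) and lysosomal
#' calcium a genotype-invariant null marker.
#'
#' The default size is 75 rows, 36 Normal and 39 IOPD.
#'
#' @param n_rows total rows (>= 4).
#' @param class_fractions named fractions for Normal and IOPD (must sum
#'   to 1); counts are `round(n_rows * fraction)`, adjusted on Normal to
#'   hit `n_rows`.
#' @param marker_effects data.frame with columns `concept`, `mean_wt`,
#'   `mean_disease`, `sd` (sd >= 0); default [defaultMarkerEffects()].
#' @param seed integer seed; generation is reproducible.
#' @return data.frame with one column per marker plus a `label` column
#'   ("Normal" / "IOPD").
#' @examples
#' d <- generateProfileDataset(seed = 1)
#' table(d$label)
#' @export
generateProfileDataset <- function(n_rows = 75L,
                                   class_fractions = c(Normal = 36 / 75,
                                                       IOPD = 39 / 75),
                                   marker_effects = defaultMarkerEffects(),
                                   seed = 1L) {
  stopifnot(n_rows >= 4L,
            abs(sum(class_fractions) - 1) < 1e-8,
            all(c("Normal", "IOPD") %in% names(class_fractions)))
  if (any(marker_effects$sd < 0))
    stop("degenerate marker effect: sd < 0", call. = FALSE)
  n_dis <- round(n_rows * class_fractions[["IOPD"]])
  n_wt <- n_rows - n_dis
  if (n_wt < 1L || n_dis < 1L)
    stop("both classes must be represented", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lab <- c(rep("Normal", n_wt), rep("IOPD", n_dis))
  out <- data.frame(row.names = seq_len(n_rows))
  for (i in seq_len(nrow(marker_effects))) {
    mu <- ifelse(lab == "Normal", marker_effects$mean_wt[i],
                 marker_effects$mean_disease[i])
    out[[marker_effects$concept[i]]] <-
      .rtruncnorm(n_rows, mu, marker_effects$sd[i])
  }
  out$label <- lab
  out
}

# truncated-normal sampling on [-1, 1] by inverse-CDF (exact, no rejection)
.rtruncnorm <- function(n, mean, sd) {
  if (all(sd == 0)) return(pmin(1, pmax(-1, mean + numeric(n))))
  lo <- stats::pnorm(-1, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Default marker effect table for dataset generation
#'
#' Class means and dispersions for the calcium-homeostasis candidate set.
#' Means follow the sign and rough magnitude of the bundled network's
#' wild-type vs disease steady states; dispersions encode how reliably
#' each marker separates in repeated simulation (calpain tightest).
#'
#' @return data.frame with columns `concept`, `mean_wt`, `mean_disease`,
#'   `sd`.
#' @export
defaultMarkerEffects <- function() {
  data.frame(
    concept = c("calpain", "intracellular_calcium", "VDCC", "ROS",
                "cell_death", "lysosomal_calcium"),
    mean_wt      = c(-0.80, -0.75, -0.70, -0.50, -0.55, 0.30),
    mean_disease = c( 0.85,  0.80,  0.75,  0.60,  0.65, 0.30),
    sd           = c( 0.15,  0.35,  0.40,  0.45,  0.50, 0.25),
    stringsAsFactors = FALSE)
}
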