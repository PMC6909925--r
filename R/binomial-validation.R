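#' Bias-adjusted exact binomial validation
#'
#' Tests whether the number of simulation calls agreeing with a literature
#' expectation profile exceeds what the network's prediction bias alone
#' would produce. The chance-success probability is the network's pretest
#' probability of a positive prediction, `p0` (0.66 for the system this
#' package emulates), rather than 0.5.
#'
#' Two null models:
#' \describe{
#'   \item{`uniform`}{(default) every feature has chance-success
#'     probability `p0`, a plain binomial null — the mode reproducing the
#'     printed validation p-values, where all-correct agreement at N
#'     features gives a one-sided p of exactly `p0^N`.}
#'   \item{`per_direction`}{expected-up features have chance probability
#'     `p0`, expected-down features `1 - p0`; the agreement count is then
#'     Poisson-binomial (computed by exact convolution).}
#' }
#' One-sided p is `P(X >= agreements)`; two-sided p uses the method of
#' small likelihoods (total probability of outcomes no more likely than
#' the observed count). Both are exact; no normal approximation.
#'
#' @param agreements number of agreeing features.
#' @param n total number of features N.
#' @param p0 pretest probability of a positive prediction (default 0.66).
#' @param expected character vector of expected directions ("up"/"down"),
#'   length `n`; required for `mode = "per_direction"`.
#' @param mode "uniform" or "per_direction".
#' @return list with `N`, `agreements`, `p0`, `mode`, `p_one_sided`,
#'   `p_two_sided`.
#' @examples
#' biasedBinomialTest(17, 17)$p_one_sided  # 0.66^17, prints as 0.0009
#' @export
biasedBinomialTest <- function(agreements, n, p0 = 0.66, expected = NULL,
                               mode = c("uniform", "per_direction")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L, p0 > 0, p0 < 1)
  if (agreements < 0 || agreements > n)
    stop("agreements must lie in 0..N", call. = FALSE)
  if (mode == "uniform") {
    pmf <- stats::dbinom(0:n, n, p0)
  } else {
    if (is.null(expected) || length(expected) != n)
      stop("per_direction mode needs one expected direction per feature",
           call. = FALSE)
    pr <- ifelse(expected %in% c("up", "present", "up/present"), p0, 1 - p0)
    pmf <- .poisson_binomial_pmf(pr)
  }
  p_one <- sum(pmf[(agreements + 1L):(n + 1L)])
  p_obs <- pmf[agreements + 1L]
  p_two <- sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  list(N = as.integer(n), agreements = as.integer(agreements), p0 = p0,
       mode = mode, p_one_sided = min(p_one, 1), p_two_sided = min(p_two, 1))
}

# exact Poisson-binomial pmf by sequential convolution
.poisson_binomial_pmf <- function(pr) {
  pmf <- 1
  for (p in pr)
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Validate simulation calls against a literature profile
#'
#' Joins expression calls (from [callExpression()]) with a literature
#' expectation profile, counts agreements (an `expressed_up` call agrees
#' with an expected "up", a `repressed_absent` call with an expected
#' "down") and runs [biasedBinomialTest()].
#'
#' @param calls data.frame from [callExpression()], or a
#'   [SteadyStateProfile-class] to call first.
#' @param profile a literature profile data.frame with columns `concept`
#'   and `expected` ("up"/"down"), e.g. from [iopdLiteratureProfiles()].
#' @param p0,mode passed to [biasedBinomialTest()].
#' @return list with `N`, `agreements`, `p0`, `mode`, `p_one_sided`,
#'   `p_two_sided` and a per-feature `table` (concept, expected, value,
#'   call, agree).
#' @export
validateCalls <- function(calls, profile, p0 = 0.66,
                          mode = c("uniform", "per_direction")) {
  mode <- match.arg(mode)
  if (is(calls, "SteadyStateProfile")) calls <- callExpression(calls)
  stopifnot(all(c("concept", "expected") %in% names(profile)))
  miss <- setdiff(profile$concept, calls$concept)
  if (length(miss) == nrow(profile))
    stop("no overlap between called concepts and the literature profile",
         call. = FALSE)
  if (length(miss))
    stop("profile concept(s) missing from calls: ",
         paste(miss, collapse = ", "), call. = FALSE)
  m <- match(profile$concept, calls$concept)
  tab <- data.frame(concept = profile$concept,
                    expected = profile$expected,
                    value = calls$value[m],
                    call = calls$call[m],
                    stringsAsFactors = FALSE)
  up <- tab$expected %in% c("up", "present", "up/present")
  tab$agree <- ifelse(up, tab$call == "expressed_up",
                      tab$call == "repressed_absent")
  res <- biasedBinomialTest(sum(tab$agree), nrow(tab), p0 = p0,
                            expected = tab$expected, mode = mode)
  c(res, list(table = tab))
}
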