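# Exact 2x2 cohort statistics: the Peto one-step odds ratio (usable with a
# zero cell) and Fisher's exact test, plus printed-precision proportion
# summaries.

#' Construct a 2x2 table
#'
#' @param a,b Events / non-events in group 1.
#' @param c,d Events / non-events in group 2.
#' @return A list of class `two_by_two` with the counts and margins.
#' @export
twoByTwo <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  t <- as.list(counts)
  t$n1 <- a + b; t$n2 <- c + d
  t$m1 <- a + c; t$m2 <- b + d
  t$N <- t$n1 + t$n2
  class(t) <- "two_by_two"
  t
}

asTwoByTwo <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  if (length(t) == 4L) return(twoByTwo(t[[1]], t[[2]], t[[3]], t[[4]]))
  stop("expected a two_by_two or 4 counts (a, b, c, d)")
}

#' Peto one-step odds ratio with confidence interval
#'
#' One-step estimator `exp((O - E) / V)` with hypergeometric expectation
#' `E = n1 * m1 / N` and variance
#' `V = n1 * n2 * m1 * m2 / (N^2 * (N - 1))`; the z-level confidence
#' interval is `exp((O - E)/V +/- z / sqrt(V))`.  Designed for tables with
#' a zero cell, where the sample odds ratio is undefined.
#'
#' @param t A [twoByTwo()] table (or 4 counts a, b, c, d).
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return A list of class `peto_result` with `O`, `E`, `V`, `ln_or`,
#'   `or_hat`, `ci`, `z`, `undefined`.
#' @export
petoOddsRatio <- function(t, z = 1.96) {
  t <- asTwoByTwo(t)
  out <- list(table = t, z = z, undefined = FALSE)
  if (t$m1 == 0 || t$m1 == t$N || t$n1 == 0 || t$n2 == 0) {
    out$undefined <- TRUE
    out$O <- t$a; out$E <- NA_real_; out$V <- NA_real_
    out$ln_or <- NA_real_; out$or_hat <- NA_real_
    out$ci <- c(NA_real_, NA_real_)
    class(out) <- "peto_result"
    return(out)
  }
  O <- t$a
  E <- t$n1 * t$m1 / t$N
  V <- t$n1 * t$n2 * t$m1 * t$m2 / (t$N^2 * (t$N - 1))
  lnOr <- (O - E) / V
  out$O <- O; out$E <- E; out$V <- V
  out$ln_or <- lnOr
  out$or_hat <- exp(lnOr)
  out$ci <- exp(lnOr + c(-1, 1) * z / sqrt(V))
  class(out) <- "peto_result"
  out
}

#' @export
print.peto_result <- function(x, ...) {
  if (x$undefined) {
    cat("Peto odds ratio: undefined (no events, or all margins degenerate)\n")
    return(invisible(x))
  }
  cat(sprintf("Peto odds ratio: %.2f (O = %d, E = %.3f, V = %.3f)\n",
              x$or_hat, x$O, x$E, x$V))
  cat(sprintf("  %g%% CI: %.2f - %.2f\n",
              round(200 * stats::pnorm(x$z) - 100, 1), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail computation.  The two-sided p-value follows
#' the point-probability rule: the sum of the probabilities of all tables
#' (with the observed margins) whose point probability does not exceed the
#' observed table's.
#'
#' @param t A [twoByTwo()] table (or 4 counts).
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (tail of the
#'   group-1 event count `a`).
#' @return The p-value.
#' @export
fisherExact <- function(t, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  t <- asTwoByTwo(t)
  lo <- max(0, t$m1 - t$n2)
  hi <- min(t$m1, t$n1)
  support <- lo:hi
  probs <- stats::dhyper(support, t$n1, t$n2, t$m1)
  pObs <- stats::dhyper(t$a, t$n1, t$n2, t$m1)
  p <- switch(alternative,
    two_sided = sum(probs[probs <= pObs * (1 + 1e-7)]),
    greater = sum(probs[support >= t$a]),
    less = sum(probs[support <= t$a]))
  min(1, p)
}

#' Percentage rounded half-up to a printed precision
#'
#' @param k,n Numerator and denominator (`0 <= k <= n`, `n > 0`).
#' @param decimals Decimal places of the printed percentage.
#' @return `100 * k / n`, rounded half-up.
#' @export
proportionPct <- function(k, n, decimals = 1L) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  roundHalfUp(100 * k / n, decimals)
}

roundHalfUp <- function(x, decimals = 0L) {
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Compare event frequency between two classified cohorts
#'
#' Builds the 2x2 table of isolates with at least one filtered event versus
#' isolates without (the isolate, not the event, is the counting unit) and
#' attaches the Peto odds ratio and Fisher's exact p-value.
#'
#' @param ampIsolates,ctrlIsolates Lists of per-isolate classifications
#'   from [classifyEvents()] (as returned by [callCohort()]), for the
#'   amplified and control cohorts.
#' @param eventFilter Either a predicate `function(classification)` or one
#'   of `"any_extra"` (any structural event beyond the plain amplification:
#'   the all-extra-events comparison) and `"secondary"` (events unlinked to
#'   the amplification only).
#' @return A list with `table` ([twoByTwo()]), `peto` ([petoOddsRatio()])
#'   and `fisher_p`.
#' @export
cohortCompare <- function(ampIsolates, ctrlIsolates,
                          eventFilter = "any_extra") {
  if (!length(ampIsolates) || !length(ctrlIsolates))
    stop("both cohorts must be non-empty")
  pred <- eventPredicate(eventFilter)
  a <- sum(vapply(ampIsolates, pred, logical(1)))
  c <- sum(vapply(ctrlIsolates, pred, logical(1)))
  t <- twoByTwo(a, length(ampIsolates) - a, c, length(ctrlIsolates) - c)
  peto <- petoOddsRatio(t)
  list(table = t, peto = peto,
       fisher_p = fisherExact(t, "two_sided"),
       undefined = peto$undefined)
}

eventPredicate <- function(eventFilter) {
  if (is.function(eventFilter)) return(eventFilter)
  # a PCR-detected inversion counts as secondary only when the aCGH class
  # does not already explain it as amplification-linked (shared junction
  # with the amplification => related, not secondary)
  switch(eventFilter,
    any_extra = function(cl) {
      extra <- setdiff(unique(cl$events$event_class), c("AMP"))
      length(extra) > 0L ||
        (isTRUE(cl$pcr_inversion) && cl$primary %in% c("AMP", "NONE"))
    },
    secondary = function(cl) {
      length(cl$secondary) > 0L ||
        (isTRUE(cl$pcr_inversion) && cl$primary %in% c("AMP", "NONE"))
    },
    stop("unknown event filter: ", eventFilter))
}
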