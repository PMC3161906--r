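# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's internal helpers: they work on plain strings with their own
# complement/reverse code.

smallRefConfig <- function(...) {
  referenceConfig(
    chromLength = 30000L, episomeLength = 20000L,
    sharedBlock = c(15001L, 21000L), sharedImageStart = 5001L,
    markerLocus = c(8001L, 9000L),
    mask = data.frame(replicon = "chromosome", start = 2001L, end = 3000L),
    nRepChrom = 2L, nRepEpisome = 1L, ...)
}

# memoized fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

smallRef <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- buildReference(smallRefConfig(), seed = 42)
  .fixtures$small
}

defaultRef <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- buildReference(referenceConfig(), seed = 1)
  .fixtures$default
}

oracleRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Brute-force microhomology oracle: builds the donor template window D, the
# acceptor template window A, and the realized junction window W, then
# slides the breakpoint across every position of W and counts consistent
# placements.  Positions must be at least K+1 away from the sequence ends.
oracleMicrohomology <- function(refStr, p, pStrand, q, qStrand, K = 60) {
  D <- if (pStrand == "+") substr(refStr, p - K + 1, p + K)
       else oracleRevcomp(substr(refStr, p - K, p + K - 1))
  A <- if (qStrand == "+") substr(refStr, q - K, q + K - 1)
       else oracleRevcomp(substr(refStr, q - K + 1, q + K))
  W <- paste0(substr(D, 1, K), substr(A, K + 1, 2 * K))
  consistent <- vapply(0:(2 * K), function(t) {
    substr(W, 1, t) == substr(D, 1, t) &&
      substr(W, t + 1, 2 * K) == substr(A, t + 1, 2 * K)
  }, logical(1))
  sum(consistent) - 1L
}

# Fisher two-sided oracle by direct enumeration of all tables with the
# observed margins (binomial coefficients, no distribution functions)
oracleFisherTwoSided <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m1 <- a + c; N <- n1 + n2
  if (m1 == 0 || m1 == N) return(1)
  xs <- max(0, m1 - n2):min(m1, n1)
  p <- choose(n1, xs) * choose(n2, m1 - xs) / choose(N, m1)
  pObs <- choose(n1, a) * choose(n2, m1 - a) / choose(N, m1)
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# per-base counting-loop coverage oracle
oracleProfile <- function(segments, L) {
  prof <- integer(L)
  for (i in seq_len(nrow(segments))) {
    for (b in segments$start[i]:segments$end[i]) prof[b] <- prof[b] + 1L
  }
  prof
}

makePlan <- function(replicon, start, end, strand) {
  new("SegmentPlan", repliconId = replicon,
      segments = data.frame(start = as.integer(start), end = as.integer(end),
                            strand = strand, stringsAsFactors = FALSE),
      events = list(), junctionInfo = ampshower:::emptyJunctionInfo())
}

episomeSeq <- function(ref) as.character(refSequences(ref)[["episome"]])
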