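# Junction measurement: microhomology, REP overlap, in-silico
# unidirectional PCR, and inversion endpoint micro-indel recovery.

# Microhomology by breakpoint-placement ambiguity (the standard SV
# convention): the junction point can be slid left while the last donor
# base keeps matching the acceptor's upstream template, and right while the
# next acceptor base keeps matching the donor's downstream template.  The
# total number of equivalent placements is mh_len + 1.
measureMicrohomologyChars <- function(chars, p, sigma, q, tau, L,
                                      maxK = 200L) {
  dIn  <- rev(donorIn(chars, p, sigma, maxK, L))      # [1] = closest to junction
  aOut <- rev(acceptorOut(chars, q, tau, maxK, L))
  mL <- 0L
  while (mL < maxK && dIn[mL + 1L] == aOut[mL + 1L]) mL <- mL + 1L
  aIn  <- acceptorIn(chars, q, tau, maxK, L)
  dOut <- donorOut(chars, p, sigma, maxK, L)
  mR <- 0L
  while (mR < maxK && aIn[mR + 1L] == dOut[mR + 1L]) mR <- mR + 1L
  mhSeq <- charsToSeq(c(rev(dIn[seq_len(mL)]), aIn[seq_len(mR)]))
  list(mh_len = mL + mR, mh_seq = mhSeq, m_left = mL, m_right = mR)
}

#' Measure junction microhomology
#'
#' Measures the breakpoint-placement ambiguity of a junction joining a
#' donor end (`donorPos` read on `donorStrand`) to an acceptor start
#' (`acceptorPos` on `acceptorStrand`) on one replicon: the maximal k such
#' that the junction point can be placed at k+1 equivalent positions
#' because the two parental strands share an identical k-mer spanning the
#' join.  The leftmost placement is reported: `donor_left`/`acceptor_left`
#' are the junction coordinates after sliding maximally left.
#'
#' @param ref A [ReferenceModel-class], or a plain DNA string (then treated
#'   as one circular replicon).
#' @param donorPos,donorStrand Last parental coordinate before the join and
#'   the strand it is read on.
#' @param acceptorPos,acceptorStrand First parental coordinate after the
#'   join and its strand.
#' @param replicon Replicon name when `ref` is a `ReferenceModel`.
#' @param context Optional realized junction context to cross-check: must
#'   contain the regenerated join (error if it is too short to span the
#'   shared tract).
#' @param maxK Search bound for the shared tract.
#' @return `list(mh_len, mh_seq, m_left, m_right, donor_left,
#'   acceptor_left)`.
#' @export
measureMicrohomology <- function(ref, donorPos, donorStrand,
                                 acceptorPos, acceptorStrand,
                                 replicon = "episome", context = NULL,
                                 maxK = 200L) {
  chars <- if (is(ref, "ReferenceModel")) repliconChars(ref, replicon)
           else seqToChars(toupper(as.character(ref)))
  L <- length(chars)
  m <- measureMicrohomologyChars(chars, donorPos, donorStrand,
                                 acceptorPos, acceptorStrand, L, maxK)
  if (!is.null(context)) {
    k <- m$mh_len
    if (nchar(context) < 2L * (k + 1L))
      stop("context shorter than twice the shared-tract window")
    w <- min((nchar(context)) %/% 2L, maxK)
    expect <- charsToSeq(c(donorIn(chars, donorPos, donorStrand, w, L),
                           acceptorIn(chars, acceptorPos, acceptorStrand, w, L)))
    if (!grepl(expect, context, fixed = TRUE) &&
        !grepl(context, expect, fixed = TRUE))
      stop("supplied context does not match the junction regenerated from ",
           "the reference")
  }
  step <- function(pos, strand, d) {
    if (strand == "+") wrapPos(pos - d, L) else wrapPos(pos + d, L)
  }
  m$donor_left <- step(donorPos, donorStrand, m$m_left)
  m$acceptor_left <- step(acceptorPos, acceptorStrand, m$m_left)
  m
}

#' Annotate junctions with REP-element overlap
#'
#' A junction is "at REP" iff either parental breakpoint coordinate lies
#' within a REP cassette cluster interval (half-open boundary semantics:
#' one base outside the interval does not count).
#'
#' @param junctions Data frame from [junctionsOf()] (needs `replicon`,
#'   `donor_pos`, `acceptor_pos`).
#' @param ref A [ReferenceModel-class] (its `repSites` are used).
#' @return `junctions` with a logical `at_rep` column appended.
#' @export
annotateRep <- function(junctions, ref) {
  rs <- ref@repSites
  inRep <- function(replicon, pos) {
    hit <- rs[as.character(seqnames(rs)) == replicon]
    any(pos >= start(hit) & pos <= end(hit))
  }
  junctions$at_rep <- vapply(seq_len(nrow(junctions)), function(i) {
    inRep(junctions$replicon[i], junctions$donor_pos[i]) ||
      inRep(junctions$replicon[i], junctions$acceptor_pos[i])
  }, logical(1))
  junctions
}

#' In-silico unidirectional PCR
#'
#' Finds all exact binding sites of two primers on both strands of a sample
#' sequence and reports a product for every convergent (facing) site pair
#' within `maxProduct` nt.  Two primers designed in the same orientation on
#' the reference give no product on the reference; an inversion spanning
#' one primer site makes the pair convergent and yields a product -- the
#' inversion screen logic.
#'
#' @param sampleSeq DNA string (character or `DNAString`), treated as
#'   linear.
#' @param primer1,primer2 Primer sequences (>= 15 nt), written 5'->3'.
#' @param maxProduct Maximal product size in nt.
#' @return Data frame with one row per product: `start`, `end`, `size`,
#'   `fwd_primer`, `rev_primer`, `product_seq`.
#' @export
unidirectionalPcr <- function(sampleSeq, primer1, primer2,
                              maxProduct = 20000L) {
  s <- toupper(as.character(sampleSeq))
  primers <- c(p1 = toupper(as.character(primer1)),
               p2 = toupper(as.character(primer2)))
  if (any(nchar(primers) < 15L)) stop("primers must be at least 15 nt")
  subject <- Biostrings::DNAString(s)
  sites <- list()
  for (nm in names(primers)) {
    pr <- primers[[nm]]
    fwdHits <- Biostrings::matchPattern(pr, subject)             # extends rightward
    revHits <- Biostrings::matchPattern(revcompChr(pr), subject) # extends leftward
    nHits <- length(fwdHits) + length(revHits)
    if (nHits > 1L)
      warning("primer ", nm, " has ", nHits,
              " binding sites; assay is ambiguous")
    if (length(fwdHits))
      sites[[length(sites) + 1L]] <- data.frame(
        primer = nm, dir = "fwd",
        start = IRanges::start(fwdHits), end = IRanges::end(fwdHits))
    if (length(revHits))
      sites[[length(sites) + 1L]] <- data.frame(
        primer = nm, dir = "rev",
        start = IRanges::start(revHits), end = IRanges::end(revHits))
  }
  empty <- data.frame(start = integer(), end = integer(), size = integer(),
                      fwd_primer = character(), rev_primer = character(),
                      product_seq = character(), stringsAsFactors = FALSE)
  if (!length(sites)) return(empty)
  sites <- do.call(rbind, sites)
  fs <- sites[sites$dir == "fwd", , drop = FALSE]
  rs <- sites[sites$dir == "rev", , drop = FALSE]
  out <- empty
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    if (rs$start[j] <= fs$end[i]) next      # not facing
    size <- rs$end[j] - fs$start[i] + 1L
    if (size > maxProduct) next
    out <- rbind(out, data.frame(
      start = fs$start[i], end = rs$end[j], size = size,
      fwd_primer = fs$primer[i], rev_primer = rs$primer[j],
      product_seq = substr(s, fs$start[i], rs$end[j]),
      stringsAsFactors = FALSE))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Unidirectional-PCR inversion screen around the marker
#'
#' Designs same-orientation primers on the reference episome at regular
#' steps within `flank` nt on both sides of the marker locus and runs
#' [unidirectionalPcr()] with every adjacent primer pair against a sample
#' sequence.  On the unrearranged reference no pair yields a product; an
#' inversion that flips one primer site makes a pair convergent.  Most
#' inversions are copy-neutral and invisible to aCGH, so this screen is the
#' only detection route for them.
#'
#' @param sampleSeq Realized episome sequence of the isolate.
#' @param ref A [ReferenceModel-class] (primers are taken from its episome).
#' @param flank Screened distance either side of the marker (nt).
#' @param step Primer spacing (nt).
#' @param primerLen Primer length (nt).
#' @param maxProduct Maximal product size passed to [unidirectionalPcr()].
#' @return `list(detected, products)`.
#' @export
inversionScreen <- function(sampleSeq, ref, flank = 20000L, step = 2000L,
                            primerLen = 20L, maxProduct = 30000L) {
  m <- ref@markerLocus
  epi <- as.character(ref@sequences[["episome"]])
  L <- nchar(epi)
  anchors <- c(seq.int(max(1L, start(m) - flank), start(m) - 500L, by = step),
               seq.int(end(m) + 500L, min(L - primerLen, end(m) + flank),
                       by = step))
  primers <- vapply(anchors, function(a)
    substr(epi, a, a + primerLen - 1L), character(1))
  s <- as.character(sampleSeq)
  products <- NULL
  for (i in seq_len(length(primers) - 1L)) {
    pr <- suppressWarnings(
      unidirectionalPcr(s, primers[i], primers[i + 1L], maxProduct))
    if (nrow(pr)) products <- rbind(products, pr)
  }
  list(detected = !is.null(products) && nrow(products) > 0L,
       products = products)
}

#' Recover inversion endpoint micro-indel offsets
#'
#' Aligns the realized sequence of an inversion plan to the reference from
#' both molecule ends and recovers the two signed endpoint offsets (positive
#' = micro-duplication, negative = micro-deletion).  Exact by construction:
#' the builder's zero-microhomology junction caps terminate both alignments
#' at the designed breakpoints.
#'
#' @param plan A plan built by [buildInversionWithIndels()].
#' @param ref The [ReferenceModel-class] returned alongside the plan.
#' @return `c(left = lo, right = ro)`, or `NULL` (with a message) for a
#'   plan that contains no inversion event.
#' @export
junctionMicroindels <- function(plan, ref) {
  ev <- Filter(function(e) identical(e$class, "INV"), plan@events)
  if (!length(ev)) {
    message("plan contains no inversion event; micro-indel recovery not applicable")
    return(NULL)
  }
  ev <- ev[[1]]
  s <- ev$inv[1]; e <- ev$inv[2]
  refChars <- repliconChars(ref, plan@repliconId)
  L <- length(refChars)
  realized <- seqToChars(as.character(realizeSequence(plan, ref)))
  n <- min(length(realized), L)
  eq <- realized[seq_len(n)] == refChars[seq_len(n)]
  P <- if (all(eq)) n else which(!eq)[1] - 1L
  eqR <- rev(realized)[seq_len(n)] == rev(refChars)[seq_len(n)]
  Q <- if (all(eqR)) n else which(!eqR)[1] - 1L
  c(left = P - (s - 1L), right = Q - (L - e))
}
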