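# Rearranged replicons as oriented segment lists.  Every structure class is
# built by an explicit template-switch construction: the plan records the
# oriented reference intervals, the designed junctions, and the event
# regions used for composition; realization and the copy-number profile
# follow mechanically from the segment list.

newPlan <- function(replicon, segments, events = list(),
                    junctionInfo = emptyJunctionInfo()) {
  rownames(segments) <- NULL
  new("SegmentPlan", repliconId = replicon, segments = segments,
      events = events, junctionInfo = junctionInfo)
}

emptyJunctionInfo <- function() {
  data.frame(donor_pos = integer(), donor_strand = character(),
             acceptor_pos = integer(), acceptor_strand = character(),
             mh_len = integer(), side = character(), label = character(),
             stringsAsFactors = FALSE)
}

junctionRow <- function(p, sigma, q, tau, mh, side, label) {
  data.frame(donor_pos = as.integer(p), donor_strand = sigma,
             acceptor_pos = as.integer(q), acceptor_strand = tau,
             mh_len = as.integer(mh), side = side, label = label,
             stringsAsFactors = FALSE)
}

seg <- function(start, end, strand = "+", label = "backbone") {
  data.frame(start = as.integer(start), end = as.integer(end),
             strand = strand, event_label = label, stringsAsFactors = FALSE)
}

# vectorized segment-table assembly: each argument is a list(start, end,
# strand, label) block, recycled to equal length, concatenated in order
segBlocks <- function(...) {
  blocks <- list(...)
  n <- vapply(blocks, function(b) length(b[[1]]), integer(1))
  data.frame(
    start = as.integer(unlist(lapply(blocks, `[[`, 1L))),
    end = as.integer(unlist(lapply(blocks, `[[`, 2L))),
    strand = unlist(mapply(function(b, k) rep_len(b[[3]], k), blocks, n,
                           SIMPLIFY = FALSE)),
    event_label = unlist(mapply(function(b, k) rep_len(b[[4]], k), blocks, n,
                                SIMPLIFY = FALSE)),
    stringsAsFactors = FALSE)
}

#' Identity plan for a replicon
#'
#' @param ref A [ReferenceModel-class].
#' @param replicon `"chromosome"` or `"episome"`.
#' @return A [SegmentPlan-class] whose realization is the reference itself.
#' @export
identityPlan <- function(ref, replicon = "episome") {
  L <- repliconLengths(ref)[[replicon]]
  newPlan(replicon, seg(1L, L))
}

validatePlan <- function(plan, ref) {
  L <- repliconLengths(ref)[[plan@repliconId]]
  s <- plan@segments
  if (any(s$end > L)) stop("segment out of reference bounds")
  invisible(TRUE)
}

#' Realize the DNA sequence of a segment plan
#'
#' Concatenates the oriented reference substrings of the plan (`-` segments
#' as reverse complements).  The identity plan realizes the reference
#' sequence exactly; the realized length is the sum of segment lengths.
#'
#' @param plan A [SegmentPlan-class].
#' @param ref The [ReferenceModel-class] the plan refers to.
#' @return A [Biostrings::DNAString].
#' @export
realizeSequence <- function(plan, ref) {
  validatePlan(plan, ref)
  full <- ref@sequences[[plan@repliconId]]
  parts <- lapply(seq_len(nrow(plan@segments)), function(i) {
    s <- plan@segments[i, ]
    x <- Biostrings::subseq(full, s$start, s$end)
    if (s$strand == "-") x <- Biostrings::reverseComplement(x)
    as.character(x)
  })
  Biostrings::DNAString(paste(unlist(parts), collapse = ""))
}

#' Per-base copy-number profile of a plan over reference coordinates
#'
#' `profile[base]` is the number of plan segments covering that reference
#' base, orientation-agnostic.  The sum of the profile equals the sum of
#' segment lengths (conservation) -- this is the exact expectation behind
#' every simulated aCGH scan.
#'
#' @param plan A [SegmentPlan-class].
#' @param ref The [ReferenceModel-class] the plan refers to.
#' @return Integer vector of length equal to the replicon length.
#' @export
copyNumberProfile <- function(plan, ref) {
  validatePlan(plan, ref)
  L <- repliconLengths(ref)[[plan@repliconId]]
  prof <- integer(L)
  s <- plan@segments
  for (i in seq_len(nrow(s)))
    prof[s$start[i]:s$end[i]] <- prof[s$start[i]:s$end[i]] + 1L
  prof
}

# coverage of a plan evaluated only at given positions (fast path used by
# the cohort simulator); equivalent to copyNumberProfile(plan, ref)[pos].
# plans repeat a handful of distinct intervals many times, so aggregate by
# interval first
coverageAt <- function(plan, pos) {
  s <- plan@segments
  key <- s$start * 1e9 + s$end
  uk <- unique(key)
  idx <- match(key, uk)
  uw <- tabulate(idx, nbins = length(uk))
  first <- match(uk, key)
  us <- s$start[first]; ue <- s$end[first]
  cn <- integer(length(pos))
  for (i in seq_along(us))
    cn <- cn + uw[i] * (pos >= us[i] & pos <= ue[i])
  cn
}

# ---- junction design ------------------------------------------------------

# Apply the designed junctions of a plan to the replicon sequence: plant
# each junction's homology tract and disambiguation caps, iterating to a
# fixed point so that nearby junctions cannot silently extend each other's
# measured microhomology.
designJunctionHomologies <- function(ref, plan) {
  ji <- plan@junctionInfo
  if (!nrow(ji)) return(ref)
  replicon <- plan@repliconId
  chars <- repliconChars(ref, replicon)
  L <- length(chars)
  for (pass in 1:10) {
    before <- chars
    for (i in seq_len(nrow(ji))) {
      chars <- plantJunctionHomologySided(
        chars, ji$donor_pos[i], ji$donor_strand[i],
        ji$acceptor_pos[i], ji$acceptor_strand[i],
        ji$mh_len[i], L, ji$side[i])
    }
    ok <- all(vapply(seq_len(nrow(ji)), function(i) {
      m <- measureMicrohomologyChars(chars, ji$donor_pos[i], ji$donor_strand[i],
                                     ji$acceptor_pos[i], ji$acceptor_strand[i], L)
      m$mh_len == ji$mh_len[i]
    }, logical(1)))
    if (ok && identical(before, chars)) break
    if (pass == 10L) stop("junction homology design did not converge; ",
                          "events are probably placed too close together")
  }
  updateSequence(ref, replicon, chars)
}

# side = "left": the k-base tract ends at the junction (planted into the
# acceptor's upstream template); side = "right": the tract starts at the
# junction (planted into the donor's downstream template).  One capping base
# immediately outside the tract is forced to differ so the measured
# breakpoint ambiguity equals k exactly; the opposite flank is checked and
# disambiguated only if it happens to match.
plantJunctionHomologySided <- function(chars, p, sigma, q, tau, k, L,
                                       side = "left") {
  if (side == "left") return(plantJunctionHomology(chars, p, sigma, q, tau, k, L))
  if (k > 0L) {
    tract <- acceptorIn(chars, q, tau, k, L)
    for (j in seq_len(k)) {
      pos <- donorOutPos(p, sigma, j, L)
      chars[pos] <- if (sigma == "+") tract[j] else compBase(tract[j])
    }
  }
  ak1 <- acceptorIn(chars, q, tau, k + 1L, L)[k + 1L]
  capPos <- donorOutPos(p, sigma, k + 1L, L)
  capOriented <- pickOtherBase(ak1)
  chars[capPos] <- if (sigma == "+") capOriented else compBase(capOriented)
  d1 <- donorIn(chars, p, sigma, 1L, L)
  a0pos <- acceptorOutPos(q, tau, 1L, L)
  a0cur <- if (tau == "+") chars[a0pos] else compBase(chars[a0pos])
  if (identical(a0cur, d1)) {
    newOriented <- pickOtherBase(d1)
    chars[a0pos] <- if (tau == "+") newOriented else compBase(newOriented)
  }
  chars
}

finishBuild <- function(ref, plan, designHomology) {
  if (designHomology) ref <- designJunctionHomologies(ref, plan)
  list(plan = plan, ref = ref)
}

checkInterval <- function(iv, L, what) {
  if (length(iv) != 2L || iv[1] > iv[2]) stop(what, ": invalid interval")
  if (iv[1] <= 200L || iv[2] >= L - 200L)
    stop(what, " must keep >200 nt clear of the replication origin at position 1")
  as.integer(iv)
}

markerInside <- function(ref, replicon, iv) {
  m <- ref@markerLocus
  replicon == as.character(seqnames(m)) && iv[1] <= start(m) && iv[2] >= end(m)
}

# ---- builders -------------------------------------------------------------

#' Tandem amplification (the selected event)
#'
#' Head-to-tail tandem array of the amplicon at the requested copy number
#' with one novel junction type (amplicon end joined to amplicon start)
#' whose flanks share exactly `mhLen` designed bases.  Expansion by unequal
#' crossing-over is modelled as direct repetition of the unit.
#'
#' @param ref A [ReferenceModel-class].
#' @param amplicon Length-2 integer interval on the replicon; should contain
#'   the marker locus (a warning is given otherwise: the event would not be
#'   selectable).
#' @param copies Total copy number of the amplicon (>= 2).
#' @param mhLen Designed junction microhomology in nt.
#' @param seed Integer seed (reserved for stochastic placement options).
#' @param replicon Replicon the event sits on.
#' @param designHomology If `FALSE`, skip sequence-level homology planting
#'   (copy-number-only simulations).
#' @return `list(plan = SegmentPlan, ref = ReferenceModel)`; the returned
#'   reference carries the planted junction homology.
#' @export
buildAmplification <- function(ref, amplicon, copies = 70L, mhLen = 5L,
                               seed = 1L, replicon = "episome",
                               designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  amplicon <- checkInterval(amplicon, L, "amplicon")
  if (copies < 2L) stop("copies must be >= 2")
  if (!markerInside(ref, replicon, amplicon))
    warning("amplicon does not contain the marker locus; ",
            "the event would not be selectable")
  s <- amplicon[1]; e <- amplicon[2]
  segs <- segBlocks(
    list(1L, s - 1L, "+", "backbone"),
    list(rep(s, copies), rep(e, copies), "+", "amplification"),
    list(e + 1L, L, "+", "backbone"))
  ji <- junctionRow(e, "+", s, "+", mhLen, "left", "amp")
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "amplification", class = "AMP",
                                     region = c(s, e))),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

#' Embedded inverted duplication (EID) amplicon
#'
#' Amplification whose repeating unit carries an inner region twice, once
#' inverted: unit = \[left-flank(+), inner(+), inner(-), right-flank(+)\],
#' produced by two inverted template switches and expanded by unequal
#' crossing-over.  The inner region sits at twice the amplicon copy number.
#' With `triplication = TRUE` the unit is \[inner(+), inner(-), inner(+)\]
#' within the amplicon (inner at three times the flank copy), the
#' pre-crossover inverted-triplication structure.
#'
#' The two inverted-switch junctions carry the designed microhomologies
#' `mhLens`; with `copies >= 2` the tandem unit boundary additionally forms
#' the amplification junction (`ampMhLen`), reported separately, as
#' amplification junctions are in the source data.
#'
#' @inheritParams buildAmplification
#' @param amplicon Outer amplified interval.
#' @param inner Inverted-duplication interval; must contain the marker
#'   unless `requireMarker = FALSE` (in every observed case the marker lay
#'   inside the embedded duplication).
#' @param mhLens Length-2 integer: designed microhomology of the two
#'   inverted-switch junctions.
#' @param ampMhLen Designed microhomology of the tandem amplification
#'   junction.
#' @param triplication Use the inverted-triplication unit layout.
#' @param requireMarker Enforce marker inside `inner`.
#' @export
buildEmbeddedInvertedDuplication <- function(ref, amplicon, inner,
                                             copies = 70L, mhLens = c(5L, 5L),
                                             ampMhLen = 5L, seed = 1L,
                                             triplication = FALSE,
                                             requireMarker = TRUE,
                                             replicon = "episome",
                                             designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  amplicon <- checkInterval(amplicon, L, "amplicon")
  inner <- checkInterval(inner, L, "inner")
  if (inner[1] <= amplicon[1] || inner[2] >= amplicon[2])
    stop("inner must lie strictly inside the amplicon")
  if (requireMarker && !markerInside(ref, replicon, inner))
    stop("configuration error: inner region must contain the marker locus ",
         "(override with requireMarker = FALSE)")
  s <- amplicon[1]; e <- amplicon[2]; is <- inner[1]; ie <- inner[2]
  if (ie - is < max(mhLens) + 10L) stop("inner too short for designed microhomology")
  if (triplication) {
    unit <- rbind(seg(s, ie, "+", "eid"),
                  seg(is, ie + 1L, "-", "eid"),
                  seg(is + 1L, e, "+", "eid"))
    j2 <- junctionRow(is, "-", is + 1L, "+", mhLens[2], "right", "eid_inv2")
  } else {
    unit <- rbind(seg(s, ie, "+", "eid"),
                  seg(is, ie + 1L, "-", "eid"),
                  seg(ie + 2L, e, "+", "eid"))
    j2 <- junctionRow(is, "-", ie + 2L, "+", mhLens[2], "right", "eid_inv2")
  }
  j1 <- junctionRow(ie, "+", ie + 1L, "-", mhLens[1], "left", "eid_inv1")
  ji <- rbind(j1, j2)
  segs <- segBlocks(
    list(1L, s - 1L, "+", "backbone"),
    list(rep(unit$start, copies), rep(unit$end, copies),
         rep(unit$strand, copies), "eid"),
    list(e + 1L, L, "+", "backbone"))
  if (copies >= 2L)
    ji <- rbind(ji, junctionRow(e, "+", s, "+", ampMhLen, "left", "amp"))
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "embedded_inverted_duplication",
                                     class = "EID", region = c(s, e),
                                     inner = c(is, ie))),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

#' Partially inverted (split) amplification
#'
#' Two inverted template switches generate an inverted copy of a `right`
#' block fused to a direct copy of a `left` block; unequal crossing-over
#' between the direct `left` repeats expands the structure.  On the
#' reference map the gained sequence appears as two blocks separated by an
#' unchanged gap.  Plan: \[1..le\](+) then (copies-1) x \{right(-),
#' left(+)\} then \[le+1..L\](+), giving both blocks at `copies` and the gap
#' at 1, with exactly two novel junction types.
#'
#' @inheritParams buildAmplification
#' @param left,right Disjoint intervals, `left` upstream of `right`,
#'   separated by a gap on the reference.
#' @param mhLens Designed microhomology of the two junction types.
#' @export
buildPartiallyInvertedAmplification <- function(ref, left, right,
                                                copies = 70L, mhLens = c(5L, 5L),
                                                seed = 1L, replicon = "episome",
                                                designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  left <- checkInterval(left, L, "left")
  right <- checkInterval(right, L, "right")
  if (left[2] >= right[1]) stop("left and right must be disjoint, left first")
  if (right[1] - left[2] < 3L) stop("left and right must be separated by a gap")
  if (copies < 2L) stop("copies must be >= 2")
  ls <- left[1]; le <- left[2]; rs <- right[1]; re <- right[2]
  nu <- copies - 1L
  segs <- segBlocks(
    list(1L, le, "+", "backbone"),
    list(rep(c(rs, ls), nu), rep(c(re, le), nu),
         rep(c("-", "+"), nu), "pia"),
    list(le + 1L, L, "+", "backbone"))
  ji <- rbind(junctionRow(le, "+", re, "-", mhLens[1], "left", "pia_inv"),
              junctionRow(rs, "-", ls, "+", mhLens[2], "left", "pia_direct"))
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "partially_inverted_amplification",
                                     class = "SPLIT_AMPLICON",
                                     region = c(ls, re),
                                     left = left, right = right)),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

#' Amplicon with an embedded deletion
#'
#' Two direct template switches give a unit pair of one full amplicon copy
#' plus one copy lacking the `deleted` interval; the deleted region is
#' present at half the copy number of the rest of the amplicon.  `copies`
#' is the total amplicon copy number and must be even (unit pairs).
#'
#' @inheritParams buildAmplification
#' @param deleted Interval inside the amplicon, disjoint from the marker.
#' @param mhLens Length-2: microhomology of the amplification junction and
#'   of the internal deletion junction.
#' @export
buildEmbeddedDeletionAmplicon <- function(ref, amplicon, deleted,
                                          copies = 70L, mhLens = c(5L, 5L),
                                          seed = 1L, replicon = "episome",
                                          designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  amplicon <- checkInterval(amplicon, L, "amplicon")
  s <- amplicon[1]; e <- amplicon[2]
  noDeletion <- length(deleted) == 2L && deleted[1] > deleted[2]
  if (noDeletion)
    return(buildAmplification(ref, amplicon, copies, mhLens[1], seed,
                              replicon, designHomology))
  deleted <- checkInterval(deleted, L, "deleted")
  if (deleted[1] <= s || deleted[2] >= e)
    stop("deleted interval must lie strictly inside the amplicon")
  m <- ref@markerLocus
  if (replicon == as.character(seqnames(m)) &&
      deleted[1] <= end(m) && deleted[2] >= start(m))
    stop("deleted interval covers the marker locus; selection would be lost")
  if (copies < 2L || copies %% 2L != 0L)
    stop("copies must be an even number >= 2 (full + deleted unit pairs)")
  ds <- deleted[1]; de <- deleted[2]
  k <- copies %/% 2L
  segs <- segBlocks(
    list(1L, s - 1L, "+", "backbone"),
    list(rep(c(s, s, de + 1L), k), rep(c(e, ds - 1L, e), k),
         "+", "embedded_del"),
    list(e + 1L, L, "+", "backbone"))
  ji <- rbind(junctionRow(e, "+", s, "+", mhLens[1], "left", "amp"),
              junctionRow(ds - 1L, "+", de + 1L, "+", mhLens[2], "left",
                          "embedded_del"))
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "embedded_deletion_amplicon",
                                     class = "EMBEDDED_DEL", region = c(s, e),
                                     deleted = c(ds, de))),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

#' Inversion with endpoint micro-indels
#'
#' Inverts `inv` with its endpoints displaced by signed offsets: a positive
#' offset leaves a micro-duplication (covered twice), a negative one a
#' micro-deletion (covered zero times) at that end, emulating the
#' near-reciprocal template-switch inversions whose junctions are displaced
#' by a few tens of base pairs.  Realized length = reference length +
#' `leftOffset` + `rightOffset`.  Both junctions are designed with zero
#' microhomology so endpoint offsets are recoverable exactly by alignment.
#'
#' @inheritParams buildAmplification
#' @param inv Interval to invert.
#' @param leftOffset,rightOffset Signed endpoint displacements in nt
#'   (|offset| <= 100).
#' @export
buildInversionWithIndels <- function(ref, inv, leftOffset = 0L,
                                     rightOffset = 0L, seed = 1L,
                                     replicon = "episome",
                                     designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  inv <- checkInterval(inv, L, "inv")
  lo <- as.integer(leftOffset); ro <- as.integer(rightOffset)
  if (abs(lo) > 100L || abs(ro) > 100L)
    stop("offsets must be at most a few tens of base pairs (|offset| <= 100)")
  s <- inv[1]; e <- inv[2]
  if (abs(lo) >= e - s || abs(ro) >= e - s)
    stop("offsets larger than the inverted interval")
  segs <- rbind(seg(1L, s - 1L + lo),
                seg(s, e, "-", "inversion"),
                seg(e + 1L - ro, L))
  ji <- rbind(junctionRow(s - 1L + lo, "+", e, "-", 0L, "left", "inv_left"),
              junctionRow(s, "-", e + 1L - ro, "+", 0L, "left", "inv_right"))
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "inversion", class = "INV",
                                     region = c(min(s + lo, s), max(e, e - ro)),
                                     inv = c(s, e), offsets = c(lo, ro))),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

#' Deletion unlinked to the amplification
#'
#' Removes `delInterval` with a single novel direct junction carrying the
#' designed microhomology (1-4 nt in the observed secondary deletions).
#'
#' @inheritParams buildAmplification
#' @param delInterval Interval to delete; must not cover the marker.
#' @param mhLen Designed junction microhomology.
#' @export
buildSecondaryDeletion <- function(ref, delInterval, mhLen = 2L, seed = 1L,
                                   replicon = "chromosome",
                                   designHomology = TRUE) {
  L <- repliconLengths(ref)[[replicon]]
  delInterval <- checkInterval(delInterval, L, "delInterval")
  m <- ref@markerLocus
  if (replicon == as.character(seqnames(m)) &&
      delInterval[1] <= end(m) && delInterval[2] >= start(m))
    stop("deletion overlaps the marker locus")
  s <- delInterval[1]; e <- delInterval[2]
  segs <- rbind(seg(1L, s - 1L), seg(e + 1L, L))
  ji <- junctionRow(s - 1L, "+", e + 1L, "+", mhLen, "left", "secondary_del")
  plan <- newPlan(replicon, segs,
                  events = list(list(label = "secondary_deletion",
                                     class = "SECONDARY_DEL",
                                     region = c(s, e))),
                  junctionInfo = ji)
  finishBuild(ref, plan, designHomology)
}

# ---- composition and junction enumeration ---------------------------------

#' Compose independent events on one replicon
#'
#' Splices the event cores of several single-event plans (all on the same
#' replicon, built against the same reference lineage) into one plan.
#' Event regions must be pairwise disjoint.
#'
#' @param ref A [ReferenceModel-class] (the reference carrying all the
#'   events' planted junction homologies, i.e. the `ref` returned by the
#'   last chained builder call).
#' @param ... Two or more [SegmentPlan-class] objects.
#' @return A composite [SegmentPlan-class].
#' @export
composePlans <- function(ref, ...) {
  plans <- list(...)
  if (length(plans) == 1L && is.list(plans[[1]]) && !is(plans[[1]], "SegmentPlan"))
    plans <- plans[[1]]
  replicon <- unique(vapply(plans, planReplicon, character(1)))
  if (length(replicon) != 1L)
    stop("all plans must be on the same replicon")
  L <- repliconLengths(ref)[[replicon]]
  cores <- lapply(plans, extractCore, L = L)
  ord <- order(vapply(cores, function(x) x$region[1], numeric(1)))
  cores <- cores[ord]
  regions <- t(vapply(cores, function(x) x$region, numeric(2)))
  if (nrow(regions) > 1L &&
      any(regions[-1, 1] <= regions[-nrow(regions), 2]))
    stop("composition error: event regions overlap")
  segs <- NULL
  cursor <- 1L
  for (x in cores) {
    if (x$region[1] > cursor)
      segs <- rbind(segs, seg(cursor, x$region[1] - 1L))
    segs <- rbind(segs, x$core)
    cursor <- x$region[2] + 1L
  }
  if (cursor <= L) segs <- rbind(segs, seg(cursor, L))
  newPlan(replicon, segs,
          events = unlist(lapply(plans[ord], planEvents), recursive = FALSE),
          junctionInfo = do.call(rbind, lapply(plans[ord], planJunctionInfo)))
}

# split a single-event builder plan into prefix / core / suffix; region is
# the reference interval replaced by the core
extractCore <- function(plan, L) {
  s <- plan@segments
  n <- nrow(s)
  if (n < 2L) stop("plan has no event core")
  if (s$strand[1] != "+" || s$start[1] != 1L)
    stop("plan does not start with a reference prefix")
  if (s$strand[n] != "+" || s$end[n] != L)
    stop("plan does not end with a reference suffix")
  list(region = c(s$end[1] + 1L, s$start[n] - 1L),
       core = s[-c(1L, n), , drop = FALSE])
}

#' Enumerate the novel junctions of a plan
#'
#' Walks every adjacent segment pair (including the circular wrap from last
#' to first segment); pairs whose reference adjacency is intact are skipped,
#' every other pair is a novel junction.  Each junction is reported with its
#' parental coordinates/strands, measured microhomology, and +/-50 nt of
#' realized context.
#'
#' @param plan A [SegmentPlan-class].
#' @param ref The [ReferenceModel-class] carrying the planted junction
#'   sequences.
#' @param contextWidth Realized context to report on each side of the join.
#' @return A data frame with one row per junction instance: `donor_pos`,
#'   `donor_strand`, `acceptor_pos`, `acceptor_strand`, `mh_len`, `mh_seq`,
#'   `label`, `context`.
#' @export
junctionsOf <- function(plan, ref, contextWidth = 50L) {
  validatePlan(plan, ref)
  s <- plan@segments
  n <- nrow(s)
  L <- repliconLengths(ref)[[plan@repliconId]]
  chars <- repliconChars(ref, plan@repliconId)
  ji <- plan@junctionInfo
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- if (s$strand[i] == "+") s$end[i] else s$start[i]
    sigma <- s$strand[i]
    q <- if (s$strand[j] == "+") s$start[j] else s$end[j]
    tau <- s$strand[j]
    refAdjacent <- sigma == tau &&
      ((sigma == "+" && q == wrapPos(p + 1L, L)) ||
       (sigma == "-" && q == wrapPos(p - 1L, L)))
    if (refAdjacent) next
    m <- measureMicrohomologyChars(chars, p, sigma, q, tau, L)
    ctx <- charsToSeq(c(donorIn(chars, p, sigma, contextWidth, L),
                        acceptorIn(chars, q, tau, contextWidth, L)))
    lab <- ji$label[ji$donor_pos == p & ji$donor_strand == sigma &
                    ji$acceptor_pos == q & ji$acceptor_strand == tau]
    out[[length(out) + 1L]] <- data.frame(
      replicon = plan@repliconId,
      donor_pos = p, donor_strand = sigma,
      acceptor_pos = q, acceptor_strand = tau,
      mh_len = m$mh_len, mh_seq = m$mh_seq,
      label = if (length(lab)) lab[1] else "unlabelled",
      context = ctx, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(replicon = character(), donor_pos = integer(),
                      donor_strand = character(), acceptor_pos = integer(),
                      acceptor_strand = character(), mh_len = integer(),
                      mh_seq = character(), label = character(),
                      context = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
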