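# Array-CGH simulation, the adjacent-probe calling rule, and the structure
# classifier.

#' Simulate per-probe log2 ratios from copy-number profiles
#'
#' `log2_ratio(p) = log2(cn_sample(p) / cn_ref(p)) + eps`, with
#' `eps ~ Normal(0, sigma^2)` i.i.d.  `sigma = 0` gives exact ratios.  A
#' sample copy number of zero over a positive reference uses a floor
#' pseudo-count of 0.01 (flagged in the `floored` column); probes with zero
#' reference copy are dropped with a warning.
#'
#' @param profileSample Named list of full-length per-base integer profiles
#'   (`chromosome`, `episome`), or a numeric vector with one value per probe
#'   row of the manifest.
#' @param ref A [ReferenceModel-class] supplying the probe array.
#' @param profileReference Like `profileSample`; default all-1.
#' @param sigma Noise standard deviation in log2 units.
#' @param seed Integer seed.
#' @return A probe table: data frame with `replicon`, `pos`, `probe_id`,
#'   `log2_ratio`, `floored`.
#' @export
simulateRatios <- function(profileSample, ref, profileReference = NULL,
                           sigma = 0, seed = 1L) {
  probes <- ref@probes
  cnAt <- function(profile) {
    if (is.list(profile)) {
      vapply(seq_len(nrow(probes)), function(i)
        profile[[probes$replicon[i]]][probes$pos[i]], numeric(1))
    } else {
      if (length(profile) != nrow(probes))
        stop("per-probe profile must have one value per probe")
      as.numeric(profile)
    }
  }
  cnS <- cnAt(profileSample)
  cnR <- if (is.null(profileReference)) rep(1, nrow(probes))
         else cnAt(profileReference)
  if (any(is.na(cnS)) || any(is.na(cnR)))
    stop("profiles must be defined at every probe position")
  keep <- cnR > 0
  if (!all(keep)) {
    warning(sum(!keep), " probe(s) with zero reference copy dropped")
    probes <- probes[keep, , drop = FALSE]
    cnS <- cnS[keep]; cnR <- cnR[keep]
  }
  floored <- cnS == 0
  cnS[floored] <- 0.01
  eps <- if (sigma > 0) withSeed(seed, stats::rnorm(length(cnS), 0, sigma))
         else numeric(length(cnS))
  out <- probes
  out$log2_ratio <- log2(cnS / cnR) + eps
  out$floored <- floored
  rownames(out) <- NULL
  out
}

#' Simulate the probe table of one rearranged isolate
#'
#' Convenience fast path: evaluates the plan's copy-number coverage directly
#' at the probe positions of the plan's replicon (all other probes are at
#' reference copy) and simulates ratios.
#'
#' @param plans A [SegmentPlan-class], a list of them (at most one per
#'   replicon), or `NULL` for a no-event isolate.
#' @inheritParams simulateRatios
#' @export
simulateIsolateRatios <- function(plans, ref, sigma = 0, seed = 1L) {
  probes <- ref@probes
  cn <- rep(1, nrow(probes))
  if (is(plans, "SegmentPlan")) plans <- list(plans)
  for (plan in plans) {
    i <- probes$replicon == planReplicon(plan)
    cn[i] <- coverageAt(plan, probes$pos[i])
  }
  simulateRatios(cn, ref, sigma = sigma, seed = seed)
}

#' Call copy-number segments with the adjacent-probe threshold rule
#'
#' Implements the calling rule used on the scans: every maximal run of at
#' least `minProbes` adjacent probes whose log2 ratio is `>= thresholdLog2`
#' (gain) or `<= -thresholdLog2` (loss) becomes a call ("two or more
#' adjacent probes showing 2-fold or more increase or decrease",
#' boundary-inclusive).  Probes are adjacent only when separated by exactly
#' one probe spacing, so runs break across masked gaps; the first and last
#' probes of a circular replicon are adjacent and a run may wrap (flagged
#' `wraps`, with `end` past the replicon length).  Call boundaries are the
#' outermost qualifying probe positions extended by half a spacing;
#' `est_copy = ref_copy * 2^mean_log2` with ref_copy = 1.
#'
#' @param table Probe table from [simulateRatios()]; must be sorted by
#'   replicon and position (error otherwise).
#' @param ref A [ReferenceModel-class] (spacing and replicon lengths).
#' @param thresholdLog2 Inclusive |log2| threshold (1 = 2-fold).
#' @param minProbes Minimal run length.
#' @return Data frame of calls: `replicon`, `start`, `end`, `direction`,
#'   `mean_log2`, `est_copy`, `n_probes`, `wraps`.
#' @export
callSegments <- function(table, ref, thresholdLog2 = 1, minProbes = 2L) {
  if (!nrow(table)) return(.emptyCalls)
  lens <- repliconLengths(ref)
  sp <- ref@spacing
  half <- sp / 2
  out <- list()
  for (rep in unique(table$replicon)) {
    idx <- table$replicon == rep
    pos <- table$pos[idx]
    ratio <- table$log2_ratio[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("probe table not sorted by position within replicon ", rep)
    L <- lens[[rep]]
    n <- length(pos)
    adj <- diff(pos) == sp                         # i linked to i+1
    wrapAdj <- n > 1L && (L - pos[n] + pos[1]) == sp
    for (dir in c("gain", "loss")) {
      q <- if (dir == "gain") ratio >= thresholdLog2
           else ratio <= -thresholdLog2
      if (!any(q)) next
      linked <- q[-n] & q[-1] & adj
      grp <- cumsum(c(TRUE, !linked))
      grp[!q] <- NA
      runs <- split(which(q), grp[q])
      # circular wrap: merge a run ending at the last probe with a run
      # starting at the first probe
      if (wrapAdj && length(runs) > 1L) {
        first <- runs[[1]]; last <- runs[[length(runs)]]
        if (first[1] == 1L && last[length(last)] == n) {
          runs[[1]] <- c(last, first)
          runs[[length(runs)]] <- NULL
        }
      }
      for (r in runs) {
        if (length(r) < minProbes) next
        wraps <- any(diff(r) < 0L)
        startPos <- pos[r[1]]
        endPos <- if (wraps) pos[r[length(r)]] + L else pos[r[length(r)]]
        m <- mean(ratio[r])
        out[[length(out) + 1L]] <- list(rep, startPos - half, endPos + half,
                                        dir, m, 2 ^ m, length(r), wraps)
      }
    }
  }
  if (!length(out)) return(.emptyCalls)
  calls <- data.frame(
    replicon = vapply(out, `[[`, character(1), 1L),
    start = vapply(out, `[[`, numeric(1), 2L),
    end = vapply(out, `[[`, numeric(1), 3L),
    direction = vapply(out, `[[`, character(1), 4L),
    mean_log2 = vapply(out, `[[`, numeric(1), 5L),
    est_copy = vapply(out, `[[`, numeric(1), 6L),
    n_probes = vapply(out, function(x) as.integer(x[[7L]]), integer(1)),
    wraps = vapply(out, `[[`, logical(1), 8L),
    stringsAsFactors = FALSE)
  calls[order(calls$replicon, calls$start), , drop = FALSE]
}

.emptyCalls <- data.frame(replicon = character(), start = numeric(),
                          end = numeric(), direction = character(),
                          mean_log2 = numeric(), est_copy = numeric(),
                          n_probes = integer(), wraps = logical(),
                          stringsAsFactors = FALSE)

#' Classify the structure of a called isolate
#'
#' Applies the structure catalogue rules to a call set (linear copy units
#' throughout):
#' \itemize{
#'   \item \strong{AMP}: a gain overlapping the marker locus.
#'   \item \strong{EID}: an AMP whose interior contains a run of >= 2 probes
#'     with estimated copy >= 1.4x the flanking amplicon copy (embedded
#'     inverted duplication).
#'   \item \strong{EMBEDDED_DEL}: interior run at <= 0.6x the flanking copy.
#'   \item \strong{SPLIT_AMPLICON}: two gains separated by a normal gap with
#'     estimated copies agreeing within 25% (candidate partially inverted
#'     amplification, flagged for PCR confirmation).
#'   \item \strong{SECONDARY_DEL}: a loss neither overlapping nor adjacent
#'     (> 1 probe spacing) to any AMP gain.
#'   \item \strong{UNCLASSIFIED} otherwise, with a reason.
#' }
#'
#' @param calls Call set from [callSegments()].
#' @param ref A [ReferenceModel-class].
#' @param table The probe table the calls came from (needed for interior
#'   sub-segment analysis).
#' @param junctions Optional junction data frame, recorded in the result.
#' @return `list(primary, secondary, events)` where `events` is a data
#'   frame of per-event classifications.
#' @export
classifyEvents <- function(calls, ref, table, junctions = NULL) {
  sp <- ref@spacing
  m <- ref@markerLocus
  mRep <- as.character(seqnames(m))
  # calls separated by a probe-free gap (an excluded mask) are one event
  # split by the exclusion, not two events: merge them before classifying
  calls <- mergeAcrossProbeFreeGaps(calls, table)
  ev <- list()
  addEv <- function(class, call, note = "") {
    ev[[length(ev) + 1L]] <<- data.frame(
      event_class = class, replicon = call$replicon, start = call$start,
      end = call$end, est_copy = call$est_copy, note = note,
      stringsAsFactors = FALSE)
  }
  gains <- calls[calls$direction == "gain", , drop = FALSE]
  losses <- calls[calls$direction == "loss", , drop = FALSE]

  overlapsMarker <- gains$replicon == mRep &
    gains$start <= end(m) & gains$end >= start(m)
  ampCalls <- gains[overlapsMarker, , drop = FALSE]

  # split amplicon: two gains on one replicon, separated by a normal gap,
  # with agreeing copy estimates, one of them covering the marker
  splitFound <- FALSE
  if (any(overlapsMarker) && nrow(gains) >= 2L) {
    for (i in seq_len(nrow(gains) - 1L)) {
      for (j in seq.int(i + 1L, nrow(gains))) {
        if (gains$replicon[i] != gains$replicon[j]) next
        gap <- gains$start[j] - gains$end[i]
        agree <- max(gains$est_copy[c(i, j)]) /
                 min(gains$est_copy[c(i, j)]) <= 1.25
        touchesMarker <- overlapsMarker[i] || overlapsMarker[j]
        if (gap > sp && agree && touchesMarker) {
          splitFound <- TRUE
          addEv("SPLIT_AMPLICON", gains[i, ], "flagged for PCR confirmation")
          addEv("SPLIT_AMPLICON", gains[j, ], "flagged for PCR confirmation")
        }
      }
    }
  }

  ampSubtype <- character(0)
  if (nrow(ampCalls)) {
    for (i in seq_len(nrow(ampCalls))) {
      call <- ampCalls[i, ]
      sub <- interiorSubsegments(call, table, sp)
      if (!is.null(sub$eid)) {
        ampSubtype <- c(ampSubtype, "EID")
        addEv("EID", call, sprintf("inner %d-%d at %.1fx flank",
                                   sub$eid$start, sub$eid$end, sub$eid$fold))
      } else if (!is.null(sub$del)) {
        ampSubtype <- c(ampSubtype, "EMBEDDED_DEL")
        addEv("EMBEDDED_DEL", call, sprintf("inner %d-%d at %.1fx flank",
                                            sub$del$start, sub$del$end,
                                            sub$del$fold))
      } else {
        ampSubtype <- c(ampSubtype, "AMP")
        addEv("AMP", call)
      }
    }
  }

  secondary <- character(0)
  if (nrow(losses)) {
    for (i in seq_len(nrow(losses))) {
      l <- losses[i, ]
      near <- gains$replicon == l$replicon &
        l$start <= gains$end + sp & l$end >= gains$start - sp
      if (any(near & overlapsMarker)) {
        addEv("UNCLASSIFIED", l, "loss adjacent to amplification (related)")
      } else {
        secondary <- c(secondary, "SECONDARY_DEL")
        addEv("SECONDARY_DEL", l)
      }
    }
  }

  primary <- if (splitFound) "SPLIT_AMPLICON"
    else if ("EID" %in% ampSubtype) "EID"
    else if ("EMBEDDED_DEL" %in% ampSubtype) "EMBEDDED_DEL"
    else if ("AMP" %in% ampSubtype) "AMP"
    else if (length(secondary)) "SECONDARY_DEL"
    else if (nrow(calls)) "UNCLASSIFIED"
    else "NONE"

  events <- if (length(ev)) do.call(rbind, ev)
    else data.frame(event_class = character(), replicon = character(),
                    start = numeric(), end = numeric(), est_copy = numeric(),
                    note = character(), stringsAsFactors = FALSE)
  list(primary = primary, secondary = unique(secondary), events = events,
       junctions = junctions)
}

# merge consecutive same-direction calls on one replicon when no probe
# exists strictly between them (the gap is masked, not normal-copy)
mergeAcrossProbeFreeGaps <- function(calls, table) {
  if (nrow(calls) < 2L) return(calls)
  calls <- calls[order(calls$replicon, calls$direction, calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(calls) - 1L)) {
      j <- i + 1L
      if (calls$replicon[i] != calls$replicon[j] ||
          calls$direction[i] != calls$direction[j]) next
      gapProbes <- sum(table$replicon == calls$replicon[i] &
                       table$pos > calls$end[i] & table$pos < calls$start[j])
      if (gapProbes > 0L) next
      inCall <- table$replicon == calls$replicon[i] &
        table$pos >= calls$start[i] & table$pos <= calls$end[j]
      calls$end[i] <- calls$end[j]
      calls$mean_log2[i] <- mean(table$log2_ratio[inCall])
      calls$est_copy[i] <- 2 ^ calls$mean_log2[i]
      calls$n_probes[i] <- sum(inCall)
      calls <- calls[-j, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  rownames(calls) <- NULL
  calls
}

# interior runs of an amplification call at >= 1.4x (eid) or <= 0.6x (del)
# of the flanking amplicon copy.  The flank copy is the smaller (for eid)
# or larger (for del) of the two edge medians, so one contaminated edge
# cannot hide an inner segment; interior runs need >= 5 probes and must
# pass the fold threshold on their run median as well as per probe.
interiorSubsegments <- function(call, table, sp) {
  idx <- which(table$replicon == call$replicon &
               table$pos >= call$start & table$pos <= call$end)
  tpos <- table$pos[idx]
  n <- length(idx)
  if (n < 8L) return(list(eid = NULL, del = NULL))
  cn <- 2 ^ table$log2_ratio[idx]
  nEdge <- max(3L, min(10L, n %/% 6L))
  edgeL <- stats::median(cn[seq_len(nEdge)])
  edgeR <- stats::median(cn[seq.int(n - nEdge + 1L, n)])
  # runs are assembled with a looser per-probe gate so single noisy probes
  # do not fragment them; the decision fold (1.4x / 0.6x) applies to the
  # run's median copy
  findRun <- function(flank, fold, gate, lower) {
    qual <- if (lower) cn <= gate * flank else cn >= gate * flank
    qual[c(seq_len(nEdge), seq.int(n - nEdge + 1L, n))] <- FALSE
    if (!any(qual)) return(NULL)
    adj <- diff(tpos) == sp
    linked <- qual[-n] & qual[-1] & adj
    grp <- cumsum(c(TRUE, !linked))
    runs <- split(which(qual), grp[qual])
    runs <- runs[vapply(runs, length, integer(1)) >= 5L]
    if (!length(runs)) return(NULL)
    r <- runs[[which.max(vapply(runs, length, integer(1)))]]
    med <- stats::median(cn[r])
    ok <- if (lower) med <= fold * flank else med >= fold * flank
    if (!ok) return(NULL)
    list(start = tpos[r[1]] - sp / 2, end = tpos[r[length(r)]] + sp / 2,
         fold = med / flank)
  }
  list(eid = findRun(min(edgeL, edgeR), 1.4, 1.2, lower = FALSE),
       del = findRun(max(edgeL, edgeR), 0.6, 0.75, lower = TRUE))
}

#' Plot one isolate's aCGH scan
#'
#' Position vs log2 ratio per replicon, with call boundaries marked;
#' mirrors the published scan panels.
#'
#' @param table Probe table.
#' @param calls Optional call set to mark.
#' @param main Plot title.
#' @export
plotIsolate <- function(table, calls = NULL, main = "aCGH scan") {
  reps <- unique(table$replicon)
  oldPar <- graphics::par(mfrow = c(length(reps), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldPar))
  for (rep in reps) {
    t <- table[table$replicon == rep, ]
    graphics::plot(t$pos, t$log2_ratio, pch = 16, cex = 0.3,
                   xlab = paste(rep, "position (nt)"),
                   ylab = "log2 ratio", main = if (rep == reps[1]) main else "")
    graphics::abline(h = c(-1, 1), lty = 3, col = "grey40")
    if (!is.null(calls)) {
      c0 <- calls[calls$replicon == rep, ]
      if (nrow(c0))
        graphics::rect(c0$start, -0.2, c0$end, 0.2,
                       border = NA, col = grDevices::adjustcolor(
                         ifelse(c0$direction == "gain", "red", "blue"), 0.3))
    }
  }
  invisible(NULL)
}
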