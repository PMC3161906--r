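# Cohort simulation and end-to-end orchestration: simulate -> hybridize ->
# call -> classify -> junction/structure analysis -> statistics -> report.

#' Cohort simulation configuration
#'
#' Defaults are the study conditions: 300 amplified isolates versus 240
#' stressed controls; every amplified isolate carries a tandem
#' amplification covering the marker (copy number lognormal with mean ~70
#' and SD ~23, amplicon length normal with mean 22.7 kb); additional
#' structural events are drawn at the observed per-isolate frequencies
#' (embedded inverted duplication 16/300, partially inverted amplification
#' 2/300, embedded deletion 1/300, unlinked deletion 4/300, inversion
#' 2/300, at most one per isolate); control isolates carry no events.
#'
#' @param nAmplified,nControl Cohort sizes.
#' @param pEid,pSplit,pEmbeddedDel,pSecondaryDel,pSecondaryInv Per-isolate
#'   event probabilities for amplified isolates.
#' @param copyMean,copySd Amplification copy-number mean and SD (lognormal;
#'   values rounded, clipped to \[10, 200\]).
#' @param ampLenMean,ampLenSd Amplicon length distribution (nt; clipped to
#'   \[6000, 60000\] and to fit the replicon).
#' @param mhRange Designed junction microhomology range (nt) for
#'   amplification-linked junctions.
#' @param delMhRange Microhomology range for unlinked deletions.
#' @param delLenRange Unlinked deletion length range (nt).
#' @param repSnapProb Probability that an amplification junction endpoint
#'   is snapped into a REP cassette cluster (junction hotspot emulation).
#' @param sigma Probe noise SD in log2 units.
#' @param sequences Realize per-isolate genome edits (junction homology
#'   planting)?  Needed for junction/PCR analyses; the copy-number path
#'   does not use them.
#' @return A list of class `cohort_config`.
#' @export
cohortConfig <- function(nAmplified = 300L, nControl = 240L,
                         pEid = 16 / 300, pSplit = 2 / 300,
                         pEmbeddedDel = 1 / 300,
                         pSecondaryDel = 4 / 300,
                         pSecondaryInv = 2 / 300,
                         copyMean = 70, copySd = 23,
                         ampLenMean = 22700, ampLenSd = 4000,
                         mhRange = c(3L, 30L),
                         delMhRange = c(1L, 4L),
                         delLenRange = c(200L, 7500L),
                         repSnapProb = 0.24,
                         sigma = 0.2,
                         sequences = FALSE) {
  cfg <- as.list(environment())
  probs <- c(pEid, pSplit, pEmbeddedDel, pSecondaryDel, pSecondaryInv)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1)
    stop("config error: event probabilities must be in [0,1] and sum to <= 1")
  class(cfg) <- "cohort_config"
  cfg
}

# master seed fans out to per-isolate seeds by a fixed counter scheme so
# any isolate is reproducible in isolation
isolateSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a cohort of isolates
#'
#' Amplified isolates all receive a tandem amplification covering the
#' marker; a fraction additionally carries one extra structural event per
#' the configured mixture.  Controls carry no events.  Deterministic for a
#' fixed master seed (per-isolate seeds are derived by a counter scheme).
#'
#' @param cfg A [cohortConfig()].
#' @param ref A [ReferenceModel-class]; default [buildReference()].
#' @param seed Master seed.
#' @return A list with `isolates` (per-isolate records: `id`, `group`,
#'   `truth`, `plan`, `ref`, `seed`) and `truth` (the cohort truth table,
#'   written before any calling).
#' @export
simulateCohort <- function(cfg = cohortConfig(), ref = buildReference(),
                           seed = 1L) {
  n <- cfg$nAmplified + cfg$nControl
  seeds <- isolateSeeds(seed, n)
  # cache plain-integer geometry used in the per-isolate hot loop
  rs <- ref@repSites
  epi <- as.character(seqnames(rs)) == "episome"
  cfg$.epiRepStarts <- start(rs)[epi]
  cfg$.epiRepEnds <- end(rs)[epi]
  m <- ref@markerLocus
  cfg$.marker <- c(start(m), end(m))
  isolates <- vector("list", n)
  for (i in seq_len(n)) {
    amplified <- i <= cfg$nAmplified
    id <- sprintf("%s%03d", if (amplified) "AMP" else "CTL",
                  if (amplified) i else i - cfg$nAmplified)
    isolates[[i]] <- if (amplified)
      simulateAmplifiedIsolate(id, cfg, ref, seeds[i])
    else
      list(id = id, group = "control", truth = "NONE", plans = NULL,
           ref = ref, seed = seeds[i])
  }
  truth <- data.frame(
    id = vapply(isolates, `[[`, character(1), "id"),
    group = vapply(isolates, `[[`, character(1), "group"),
    truth = vapply(isolates, `[[`, character(1), "truth"))
  list(isolates = isolates, truth = truth)
}

simulateAmplifiedIsolate <- function(id, cfg, ref, seed) {
  withSeed(seed, {
    if (is.null(cfg$.marker)) {
      m <- ref@markerLocus
      cfg$.marker <- c(start(m), end(m))
      rs <- ref@repSites
      epi <- as.character(seqnames(rs)) == "episome"
      cfg$.epiRepStarts <- start(rs)[epi]
      cfg$.epiRepEnds <- end(rs)[epi]
    }
    L <- repliconLengths(ref)[["episome"]]
    copies <- max(10L, min(200L, round(stats::rlnorm(1,
      meanlog = log(cfg$copyMean) - 0.5 * log(1 + (cfg$copySd / cfg$copyMean)^2),
      sdlog = sqrt(log(1 + (cfg$copySd / cfg$copyMean)^2))))))
    ampLen <- round(max(6000, min(60000,
      stats::rnorm(1, cfg$ampLenMean, cfg$ampLenSd))))
    amplicon <- placeContaining(ampLen, cfg$.marker[1], cfg$.marker[2], L, cfg)
    mh <- function() sample(cfg$mhRange[1]:cfg$mhRange[2], 1L)
    extra <- sample(c("EID", "SPLIT", "EMB_DEL", "SEC_DEL", "SEC_INV", "NONE"),
                    1L, prob = c(cfg$pEid, cfg$pSplit, cfg$pEmbeddedDel,
                                 cfg$pSecondaryDel, cfg$pSecondaryInv,
                                 1 - cfg$pEid - cfg$pSplit - cfg$pEmbeddedDel -
                                   cfg$pSecondaryDel - cfg$pSecondaryInv))
    innerSeed <- sample.int(.Machine$integer.max - 1L, 1L)
    buildIsolate(id, extra, ref, amplicon, copies, mh, innerSeed, cfg)
  })
}

# choose an interval of the given length containing [ms, me], clear of the
# origin; optionally snap the right boundary into a REP cluster
placeContaining <- function(len, ms, me, L, cfg) {
  # keep >= 800 nt of amplicon on both sides of the marker so embedded
  # events can sit strictly interior with clear flanks
  len <- max(len, me - ms + 1700L)
  lo <- max(300L, me + 800L - len)
  hi <- min(L - 300L - len, ms - 800L)
  s <- if (hi <= lo) lo else sample(lo:hi, 1L)
  e <- s + len - 1L
  if (stats::runif(1) < cfg$repSnapProb) {
    keep <- cfg$.epiRepStarts > me + 900L & cfg$.epiRepEnds < L - 300L
    rs <- cfg$.epiRepStarts[keep]
    if (length(rs)) e <- min(L - 300L, rs[which.min(abs(rs - e))] + 10L)
  }
  c(as.integer(s), as.integer(e))
}

buildIsolate <- function(id, extra, ref, amplicon, copies, mh, seed, cfg) {
  m <- ref@markerLocus
  Le <- repliconLengths(ref)[["episome"]]
  design <- cfg$sequences
  truth <- switch(extra, EID = "EID", SPLIT = "SPLIT_AMPLICON",
                  EMB_DEL = "EMBEDDED_DEL", SEC_DEL = "AMP+SECONDARY_DEL",
                  SEC_INV = "AMP+SECONDARY_INV", NONE = "AMP")
  res <- withSeed(seed, switch(extra,
    EID = {
      span <- max(2000L, min(amplicon[2] - amplicon[1] - 1200L,
                             round(stats::runif(1, 5200, 42600))))
      is <- max(amplicon[1] + 600L, min(start(m) - 100L,
                                        end(m) + 600L - span))
      ie <- min(amplicon[2] - 600L, is + span - 1L)
      if (ie < end(m) + 50L) ie <- min(amplicon[2] - 600L, end(m) + 50L)
      buildEmbeddedInvertedDuplication(ref, amplicon, c(is, ie), copies,
                                       mhLens = c(mh(), mh()), ampMhLen = mh(),
                                       seed = seed, designHomology = design)
    },
    SPLIT = {
      gap <- round(stats::runif(1, 1500, 4000))
      rlen <- round(stats::runif(1, 4000, 9000))
      re <- min(Le - 300L, amplicon[2] + gap + rlen)
      buildPartiallyInvertedAmplification(ref, amplicon,
        c(amplicon[2] + gap, re), copies, mhLens = c(mh(), mh()),
        seed = seed, designHomology = design)
    },
    EMB_DEL = {
      if (copies %% 2L) copies <- copies + 1L
      dlen <- round(stats::runif(1, 800, 3000))
      ds <- end(m) + 600L
      de <- ds + dlen - 1L
      if (amplicon[2] < de + 600L)
        amplicon[2] <- min(Le - 300L, de + 600L)
      buildEmbeddedDeletionAmplicon(ref, amplicon, c(ds, de), copies,
                                    mhLens = c(mh(), mh()), seed = seed,
                                    designHomology = design)
    },
    {
      buildAmplification(ref, amplicon, copies, mhLen = mh(), seed = seed,
                         designHomology = design)
    }))
  plans <- list(res$plan); ref2 <- res$ref
  pcrInv <- FALSE
  if (extra == "SEC_DEL") {
    res2 <- withSeed(seed + 1L,
                             placeSecondaryDeletion(ref2, res$plan, cfg, seed, design))
    plans <- res2$plans; ref2 <- res2$ref
  } else if (extra == "SEC_INV") {
    res2 <- withSeed(seed + 1L,
                             placeSecondaryInversion(ref2, res$plan, cfg, seed, design))
    plans <- res2$plans; ref2 <- res2$ref
    pcrInv <- TRUE
  }
  list(id = id, group = "amplified", truth = truth, plans = plans, ref = ref2,
       seed = seed, pcr_inversion_truth = pcrInv)
}

placeSecondaryDeletion <- function(ref, ampPlan, cfg, seed, design) {
  replicon <- if (stats::runif(1) < 0.5) "chromosome" else "episome"
  len <- round(stats::runif(1, cfg$delLenRange[1], cfg$delLenRange[2]))
  tryPlace <- function(replicon) {
    L <- repliconLengths(ref)[[replicon]]
    avoid <- avoidIntervals(ref, replicon, ampPlan)
    for (try in 1:200) {
      s <- sample(300:(L - 300L - len), 1L)
      cand <- c(s, s + len - 1L)
      if (!overlapsAny(cand, avoid, pad = 2L * ref@spacing)) return(cand)
    }
    NULL
  }
  iv <- tryPlace(replicon)
  if (is.null(iv)) {
    # the chosen replicon has no room (e.g. a long deletion on a small,
    # largely amplified episome): place on the other replicon instead
    replicon <- if (replicon == "episome") "chromosome" else "episome"
    iv <- tryPlace(replicon)
  }
  if (is.null(iv)) stop("could not place a secondary deletion")
  mhLen <- sample(cfg$delMhRange[1]:cfg$delMhRange[2], 1L)
  res <- buildSecondaryDeletion(ref, iv, mhLen, seed = seed,
                                replicon = replicon, designHomology = design)
  plans <- if (replicon == planReplicon(ampPlan))
    list(composePlans(res$ref, ampPlan, res$plan))
  else
    list(ampPlan, res$plan)
  list(plans = plans, ref = res$ref)
}

placeSecondaryInversion <- function(ref, ampPlan, cfg, seed, design) {
  m <- ref@markerLocus
  L <- repliconLengths(ref)[["episome"]]
  amp <- planEvents(ampPlan)[[1]]$region
  # within 20 kb of the marker but clear of the amplicon
  lo <- amp[2] + 2L * ref@spacing
  hi <- min(L - 400L, end(m) + 20000L)
  len <- round(stats::runif(1, 2000, 5000))
  if (hi - lo < len + 200L) {
    # no room right of the amplicon: fall back to the left side, still
    # within the screened window
    lo <- max(400L, start(m) - 20000L + 200L)
    hi <- amp[1] - 2L * ref@spacing
  }
  if (hi - lo < len + 200L) {
    # amplicon fills the screened window; place beyond it (such an
    # inversion escapes the PCR screen, as distant inversions do)
    lo <- amp[2] + 2L * ref@spacing
    hi <- L - 400L
  }
  if (hi - lo < len + 200L) len <- max(1000L, hi - lo - 200L)
  s <- sample(lo:(hi - len), 1L)
  offs <- sample(c(-50:-5, 5:50), 2L, replace = TRUE)
  res <- buildInversionWithIndels(ref, c(s, s + len - 1L), offs[1], offs[2],
                                  seed = seed, replicon = "episome",
                                  designHomology = design)
  list(plans = list(composePlans(res$ref, ampPlan, res$plan)), ref = res$ref)
}

avoidIntervals <- function(ref, replicon, ampPlan) {
  out <- list()
  mk <- ref@mask[as.character(seqnames(ref@mask)) == replicon]
  for (i in seq_along(mk)) out <- c(out, list(c(start(mk)[i], end(mk)[i])))
  m <- ref@markerLocus
  if (as.character(seqnames(m)) == replicon)
    out <- c(out, list(c(start(m), end(m))))
  if (replicon == planReplicon(ampPlan))
    for (e in planEvents(ampPlan)) out <- c(out, list(e$region))
  rs <- ref@repSites[as.character(seqnames(ref@repSites)) == replicon]
  for (i in seq_along(rs)) out <- c(out, list(c(start(rs)[i], end(rs)[i])))
  out
}

overlapsAny <- function(iv, intervals, pad = 0L) {
  any(vapply(intervals, function(o)
    iv[1] <= o[2] + pad && o[1] <= iv[2] + pad, logical(1)))
}

#' Hybridize, call and classify every isolate of a simulated cohort
#'
#' @param cohort Result of [simulateCohort()].
#' @param ref The cohort's reference model.
#' @param sigma Probe noise SD (log2 units).
#' @param seed Master seed for the noise draws.
#' @param pcrScreen Also run the unidirectional-PCR inversion screen on
#'   each isolate's realized episome (requires the cohort to have been
#'   simulated with `sequences = TRUE`); the result is recorded separately
#'   from the aCGH classes as `pcr_inversion`.
#' @return List of per-isolate classifications (as from
#'   [classifyEvents()]), named by isolate id, each with the isolate's
#'   `group` and `pcr_inversion` flag attached.
#' @export
callCohort <- function(cohort, ref, sigma = 0.2, seed = 1L,
                       pcrScreen = FALSE) {
  n <- length(cohort$isolates)
  seeds <- isolateSeeds(seed + 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    iso <- cohort$isolates[[i]]
    tab <- simulateIsolateRatios(iso$plans, ref, sigma = sigma, seed = seeds[i])
    calls <- callSegments(tab, ref)
    cl <- classifyEvents(calls, ref, tab)
    cl$id <- iso$id
    cl$group <- iso$group
    cl$pcr_inversion <- FALSE
    if (pcrScreen) {
      epiPlans <- Filter(function(p) planReplicon(p) == "episome",
                         if (is.null(iso$plans)) list() else iso$plans)
      sampleSeq <- if (length(epiPlans))
        realizeSequence(epiPlans[[1]], iso$ref)
      else iso$ref@sequences[["episome"]]
      cl$pcr_inversion <- inversionScreen(sampleSeq, ref)$detected
    }
    out[[i]] <- cl
  }
  names(out) <- vapply(cohort$isolates, `[[`, character(1), "id")
  out
}

#' Run the whole analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, hybridizes and calls every isolate, classifies
#' structures, runs the two cohort comparisons (any extra event; secondary
#' events only), and writes reference files, the truth table, per-isolate
#' classifications, statistics JSON and a Markdown report under `outdir`.
#'
#' @param cfg A [cohortConfig()].
#' @param outdir Output directory; refuses to reuse an existing one unless
#'   `force = TRUE`.
#' @param seed Master seed.
#' @param ref Optional pre-built [ReferenceModel-class].
#' @param force Overwrite an existing `outdir`.
#' @return Invisibly, the cohort report list.
#' @export
runPipeline <- function(cfg = cohortConfig(), outdir, seed = 1L,
                        ref = NULL, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory ", outdir, " exists; use force = TRUE to overwrite")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ref)) ref <- buildReference(seed = seed)
  writeReference(ref, file.path(outdir, "reference"))
  cohort <- simulateCohort(cfg, ref, seed = seed)
  writeTsv(cohort$truth, file.path(outdir, "truth.tsv"))

  classified <- callCohort(cohort, ref, sigma = cfg$sigma, seed = seed,
                           pcrScreen = cfg$sequences)
  called <- data.frame(
    id = vapply(classified, `[[`, character(1), "id"),
    group = vapply(classified, `[[`, character(1), "group"),
    primary = vapply(classified, `[[`, character(1), "primary"),
    secondary = vapply(classified, function(x)
      paste(x$secondary, collapse = ","), character(1)))
  writeTsv(called, file.path(outdir, "classifications.tsv"))

  amp <- classified[called$group == "amplified"]
  ctl <- classified[called$group == "control"]
  cmpAny <- cohortCompare(amp, ctl, "any_extra")
  cmpSec <- cohortCompare(amp, ctl, "secondary")

  confusion <- table(truth = cohort$truth$truth,
                     called = called$primary[match(cohort$truth$id, called$id)])

  stats <- list(
    any_extra = statsBlock(cmpAny),
    secondary = statsBlock(cmpSec),
    n_amplified = cfg$nAmplified, n_control = cfg$nControl, sigma = cfg$sigma)
  jsonlite::write_json(stats, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- list(truth = cohort$truth, called = called,
                 confusion = confusion, any_extra = cmpAny,
                 secondary = cmpSec)
  writeReportMd(report, file.path(outdir, "report.md"))
  invisible(report)
}

statsBlock <- function(cmp) {
  t <- cmp$table
  list(table = list(a = t$a, b = t$b, c = t$c, d = t$d),
       O = cmp$peto$O, E = cmp$peto$E, V = cmp$peto$V,
       or = cmp$peto$or_hat, ci = cmp$peto$ci, fisher_p = cmp$fisher_p)
}

writeReportMd <- function(report, path) {
  fmtCmp <- function(cmp, label) {
    t <- cmp$table
    or <- if (cmp$undefined) "undefined"
          else sprintf("%.1f (95%% CI %.1f-%.1f)",
                       roundHalfUp(cmp$peto$or_hat, 1),
                       roundHalfUp(cmp$peto$ci[1], 1),
                       roundHalfUp(cmp$peto$ci[2], 1))
    c(sprintf("## %s", label),
      sprintf("- table: %d/%d amplified vs %d/%d control",
              t$a, t$n1, t$c, t$n2),
      sprintf("- Peto odds ratio: %s", or),
      sprintf("- Fisher exact p: %.3g", cmp$fisher_p), "")
  }
  lines <- c("# Cohort report", "",
             sprintf("- isolates: %d amplified, %d control",
                     sum(report$truth$group == "amplified"),
                     sum(report$truth$group == "control")), "",
             fmtCmp(report$any_extra, "Any extra structural event"),
             fmtCmp(report$secondary, "Amplification-independent (secondary) events"))
  writeLines(lines, path)
}
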