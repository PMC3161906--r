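#' Configuration for the synthetic reference
#'
#' Returns the default study-system geometry: a 200 kb circular chromosome
#' and a 100 kb circular F'-like episome carrying a 40 kb block of
#' chromosomal sequence that includes a 3 kb selectable marker locus (the
#' \emph{lac} analogue).  The scale is a desk-scale stand-in for the 4.6 Mb
#' chromosome + ~100 kb F' of the real system; every size is configurable.
#'
#' @param chromLength,episomeLength Replicon lengths in nt.
#' @param spacing Probe spacing in nt (tiling array, ~100 bp resolution).
#' @param episomeSpacing Probe spacing on the episome; defaults to `spacing`
#'   (the real array's relative coverage of F' vs chromosome is unknown, so
#'   episome probe density is exposed as a knob).
#' @param sharedBlock Length-2 integer: the chromosomal interval copied
#'   verbatim onto the episome.
#' @param sharedImageStart Start of the image interval on the episome.
#' @param markerLocus Length-2 integer: marker interval on the episome; must
#'   lie inside the shared-block image.
#' @param mask Data frame (`replicon`, `start`, `end`) of intervals excluded
#'   from probing/calling (repeat/prophage analogue).  Intervals are aligned
#'   to the probe grid so that masked length divided by spacing equals the
#'   number of excluded probes.
#' @param nRepChrom,nRepEpisome Number of REP cassette clusters planted on
#'   each replicon (in addition to one cluster planted next to the marker,
#'   mirroring the junction-hotspot REP cluster near \emph{lac}).
#' @param repStem,repLoop,repMaxMismatch Stem length range, loop length
#'   range and maximal stem mismatches of each planted ~38 nt
#'   pseudopalindromic cassette.
#' @return A list of class `reference_config`.
#' @export
referenceConfig <- function(chromLength = 200000L,
                            episomeLength = 100000L,
                            spacing = 100L,
                            episomeSpacing = spacing,
                            sharedBlock = c(120001L, 160000L),
                            sharedImageStart = 30001L,
                            markerLocus = c(48001L, 51000L),
                            mask = data.frame(
                              replicon = c("chromosome", "chromosome", "episome"),
                              start = c(20001L, 90001L, 80001L),
                              end   = c(24000L, 92000L, 81000L)),
                            nRepChrom = 8L,
                            nRepEpisome = 5L,
                            repStem = c(12L, 16L),
                            repLoop = c(4L, 8L),
                            repMaxMismatch = 2L) {
  cfg <- list(chromLength = as.integer(chromLength),
              episomeLength = as.integer(episomeLength),
              spacing = as.integer(spacing),
              episomeSpacing = as.integer(episomeSpacing),
              sharedBlock = as.integer(sharedBlock),
              sharedImageStart = as.integer(sharedImageStart),
              markerLocus = as.integer(markerLocus),
              mask = mask,
              nRepChrom = as.integer(nRepChrom),
              nRepEpisome = as.integer(nRepEpisome),
              repStem = as.integer(repStem),
              repLoop = as.integer(repLoop),
              repMaxMismatch = as.integer(repMaxMismatch))
  class(cfg) <- "reference_config"
  validateReferenceConfig(cfg)
  cfg
}

validateReferenceConfig <- function(cfg) {
  if (cfg$chromLength <= 0L || cfg$episomeLength <= 0L)
    stop("replicon lengths must be positive")
  if (cfg$spacing < 1L || cfg$episomeSpacing < 1L)
    stop("probe spacing must be >= 1")
  sb <- cfg$sharedBlock
  if (diff(sb) + 1L >= cfg$chromLength)
    stop("shared block must be shorter than the chromosome")
  imgStart <- cfg$sharedImageStart
  imgEnd <- imgStart + diff(sb)
  if (imgEnd > cfg$episomeLength)
    stop("shared-block image exceeds episome length")
  m <- cfg$markerLocus
  if (m[1] < imgStart || m[2] > imgEnd)
    stop("configuration error: marker locus outside the shared-block image")
  invisible(cfg)
}

# one ~38 nt pseudopalindromic cassette: stem-loop-stem' with <= maxMismatch
# substitutions in the right arm, padded to 38 nt
repCassette <- function(stemRange, loopRange, maxMismatch) {
  stem <- sample(stemRange[1]:stemRange[2], 1L)
  loop <- sample(loopRange[1]:loopRange[2], 1L)
  arm <- sample(DNA_BASES, stem, replace = TRUE)
  arm2 <- rev(compBase(arm))
  nmm <- sample(0:maxMismatch, 1L)
  if (nmm > 0L) {
    at <- sample(seq_len(stem), nmm)
    for (i in at) arm2[i] <- pickOtherBase(c(arm2[i], compBase(arm[stem + 1L - i])))
  }
  core <- c(arm, sample(DNA_BASES, loop, replace = TRUE), arm2)
  pad <- 38L - length(core)
  if (pad > 0L) core <- c(core, sample(DNA_BASES, pad, replace = TRUE))
  charsToSeq(core)
}

# plant a cluster of 2-4 cassettes starting at `at`; returns list(chars, end)
plantRepCluster <- function(chars, at, cfg) {
  n <- sample(2:4, 1L)
  pos <- at
  for (i in seq_len(n)) {
    cas <- seqToChars(repCassette(cfg$repStem, cfg$repLoop, cfg$repMaxMismatch))
    if (pos + length(cas) - 1L > length(chars))
      stop("REP cassette cluster would extend past the replicon end; ",
           "reduce cluster count or enlarge the replicon")
    chars[pos:(pos + length(cas) - 1L)] <- cas
    pos <- pos + length(cas) + sample(5:15, 1L)
  }
  list(chars = chars, end = pos - 1L)
}

#' Build the synthetic chromosome + episome reference
#'
#' Generates i.i.d. uniform random sequence for both circular replicons,
#' copies the shared block from the chromosome onto the episome, plants
#' pseudopalindromic REP cassette clusters (one of them immediately
#' downstream of the marker's chromosomal source, emulating the REP cluster
#' near \emph{lac}), and lays out the tiling probe array over all unmasked
#' positions.  Deterministic for a fixed seed.
#'
#' @param config A [referenceConfig()] list.
#' @param seed Integer seed.
#' @return A [ReferenceModel-class].
#' @examples
#' ref <- buildReference(referenceConfig(), seed = 1)
#' ref
#' @export
buildReference <- function(config = referenceConfig(), seed = 1L) {
  validateReferenceConfig(config)
  withSeed(seed, buildReferenceImpl(config))
}

buildReferenceImpl <- function(cfg) {
  Lc <- cfg$chromLength; Le <- cfg$episomeLength
  chrom <- seqToChars(randomDna(Lc))
  sb <- cfg$sharedBlock
  imgStart <- cfg$sharedImageStart
  imgEnd <- imgStart + diff(sb)

  maskGr <- GRanges(cfg$mask$replicon, IRanges(cfg$mask$start, cfg$mask$end))

  # marker source position on the chromosome
  mSrcStart <- sb[1] + (cfg$markerLocus[1] - imgStart)
  mSrcEnd   <- sb[1] + (cfg$markerLocus[2] - imgStart)

  repRows <- list()
  occupied <- list(c(mSrcStart, mSrcEnd))   # keep clusters off the marker
  for (m in which(cfg$mask$replicon == "chromosome"))
    occupied <- c(occupied, list(c(cfg$mask$start[m], cfg$mask$end[m])))

  placeCluster <- function(chars, L, at) {
    res <- plantRepCluster(chars, at, cfg)
    list(chars = res$chars, iv = c(at, res$end))
  }
  clashes <- function(iv, occ) {
    any(vapply(occ, function(o) iv[1] <= o[2] + 50L && o[1] <= iv[2] + 50L,
               logical(1)))
  }

  # hotspot cluster just downstream of the marker source (inside the shared
  # block, so it is mirrored onto the episome next to the marker)
  res <- placeCluster(chrom, Lc, mSrcEnd + 300L)
  chrom <- res$chars
  occupied <- c(occupied, list(res$iv))
  repRows[[length(repRows) + 1L]] <- c("chromosome", res$iv)
  # its image on the episome
  repRows[[length(repRows) + 1L]] <-
    c("episome", res$iv - sb[1] + imgStart)

  for (i in seq_len(cfg$nRepChrom)) {
    for (try in 1:50) {
      at <- sample(500:(Lc - 800L), 1L)
      iv <- c(at, at + 200L)
      if (!clashes(iv, occupied)) break
    }
    res <- placeCluster(chrom, Lc, at)
    chrom <- res$chars
    occupied <- c(occupied, list(res$iv))
    repRows[[length(repRows) + 1L]] <- c("chromosome", res$iv)
    if (res$iv[1] >= sb[1] && res$iv[2] <= sb[2])
      repRows[[length(repRows) + 1L]] <-
        c("episome", res$iv - sb[1] + imgStart)
  }

  episome <- seqToChars(randomDna(Le))
  episome[imgStart:imgEnd] <- chrom[sb[1]:sb[2]]

  occE <- list(c(imgStart, imgEnd))
  for (m in which(cfg$mask$replicon == "episome"))
    occE <- c(occE, list(c(cfg$mask$start[m], cfg$mask$end[m])))
  for (i in seq_len(cfg$nRepEpisome)) {
    for (try in 1:50) {
      at <- sample(500:(Le - 800L), 1L)
      iv <- c(at, at + 200L)
      if (!clashes(iv, occE)) break
    }
    res <- placeCluster(episome, Le, at)
    episome <- res$chars
    occE <- c(occE, list(res$iv))
    repRows[[length(repRows) + 1L]] <- c("episome", res$iv)
  }

  repDf <- do.call(rbind, lapply(repRows, function(r)
    data.frame(replicon = r[1], start = as.integer(r[2]), end = as.integer(r[3]))))
  repGr <- GRanges(repDf$replicon, IRanges(repDf$start, repDf$end))
  repGr <- sort(repGr)

  seqs <- Biostrings::DNAStringSet(c(chromosome = charsToSeq(chrom),
                                     episome = charsToSeq(episome)))

  probes <- layoutProbes(c(chromosome = Lc, episome = Le),
                         c(chromosome = cfg$spacing, episome = cfg$episomeSpacing),
                         cfg$mask)

  new("ReferenceModel",
      sequences = seqs,
      sharedBlock = GRanges(c("chromosome", "episome"),
                            IRanges(c(sb[1], imgStart), c(sb[2], imgEnd))),
      markerLocus = GRanges("episome",
                            IRanges(cfg$markerLocus[1], cfg$markerLocus[2])),
      repSites = repGr,
      mask = maskGr,
      probes = probes,
      spacing = cfg$spacing)
}

# probe positions start at 1 and advance by the per-replicon spacing; probes
# falling inside a mask interval are dropped
layoutProbes <- function(lens, spacings, mask) {
  out <- lapply(names(lens), function(rep) {
    sp <- spacings[[rep]]
    pos <- seq.int(1L, lens[[rep]], by = sp)
    mk <- mask[mask$replicon == rep, , drop = FALSE]
    if (nrow(mk)) {
      bad <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(mk)))
        bad <- bad | (pos >= mk$start[i] & pos <= mk$end[i])
      pos <- pos[!bad]
    }
    data.frame(replicon = rep, pos = as.integer(pos),
               probe_id = sprintf("%s_p%06d", substr(rep, 1, 3), seq_along(pos)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# replace the sequence of one replicon, keeping the shared block identical on
# both replicons (an edit inside the shared region is mirrored to the other
# copy; this is genome design, done before any rearrangement is realized)
updateSequence <- function(model, replicon, chars) {
  sb <- model@sharedBlock
  src <- sb[as.character(seqnames(sb)) == "chromosome"]
  img <- sb[as.character(seqnames(sb)) == "episome"]
  seqs <- as.character(model@sequences)
  seqs[[replicon]] <- charsToSeq(chars)
  if (replicon == "episome") {
    other <- seqToChars(seqs[["chromosome"]])
    other[start(src):end(src)] <- chars[start(img):end(img)]
    seqs[["chromosome"]] <- charsToSeq(other)
  } else {
    other <- seqToChars(seqs[["episome"]])
    other[start(img):end(img)] <- chars[start(src):end(src)]
    seqs[["episome"]] <- charsToSeq(other)
  }
  model@sequences <- Biostrings::DNAStringSet(seqs)
  validObject(model)
  model
}

repliconChars <- function(model, replicon) {
  seqToChars(as.character(model@sequences[[replicon]]))
}
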