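#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
NULL

#' ReferenceModel: a synthetic chromosome + episome reference
#'
#' Container for the synthetic study system: a circular bacterial chromosome
#' and a circular F'-like episome that carries a block of chromosomal
#' sequence (the shared block) including a selectable marker locus (the
#' \emph{lac} analogue).  Pseudopalindromic repeat cassettes (REP analogues)
#' are planted on both replicons, a set of masked intervals (repeat/prophage
#' analogue) is excluded from copy-number calling, and a tiling
#' oligonucleotide probe array covers all unmasked sequence.
#'
#' All intervals are 1-based, closed (the native Bioconductor convention);
#' BED output is converted to 0-based half-open on export.
#'
#' @slot sequences A [Biostrings::DNAStringSet] with elements named
#'   `"chromosome"` and `"episome"`.  Both replicons are circular.
#' @slot sharedBlock A [GenomicRanges::GRanges] of length 2: the chromosomal
#'   source interval (seqname `"chromosome"`) and its verbatim image on the
#'   episome (seqname `"episome"`).
#' @slot markerLocus A `GRanges` of length 1 on the episome, inside the
#'   shared-block image: the selectable marker.
#' @slot repSites `GRanges` of planted pseudopalindromic repeat cassette
#'   clusters on both replicons.
#' @slot mask `GRanges` of intervals excluded from probe placement and
#'   calling.
#' @slot probes A `data.frame` with columns `replicon`, `pos`, `probe_id`:
#'   the probe manifest, ordered by replicon then position.
#' @slot spacing Integer probe spacing in nucleotides.
#' @export
setClass("ReferenceModel",
  representation(
    sequences   = "DNAStringSet",
    sharedBlock = "GRanges",
    markerLocus = "GRanges",
    repSites    = "GRanges",
    mask        = "GRanges",
    probes      = "data.frame",
    spacing     = "integer"
  )
)

setValidity("ReferenceModel", function(object) {
  msg <- character()
  if (!all(c("chromosome", "episome") %in% names(object@sequences)))
    msg <- c(msg, "sequences must contain 'chromosome' and 'episome'")
  lens <- repliconLengths(object)
  grl <- list(shared = object@sharedBlock, marker = object@markerLocus,
              rep = object@repSites, mask = object@mask)
  for (nm in names(grl)) {
    gr <- grl[[nm]]
    if (length(gr) == 0L) next
    sq <- as.character(seqnames(gr))
    if (!all(sq %in% names(lens))) {
      msg <- c(msg, sprintf("%s intervals on unknown replicon", nm)); next
    }
    if (any(start(gr) < 1L) || any(end(gr) > lens[sq]))
      msg <- c(msg, sprintf("%s intervals out of replicon bounds", nm))
  }
  if (length(object@sharedBlock) == 2L) {
    src <- object@sharedBlock[seqnames(object@sharedBlock) == "chromosome"]
    img <- object@sharedBlock[seqnames(object@sharedBlock) == "episome"]
    if (length(src) != 1L || length(img) != 1L) {
      msg <- c(msg, "sharedBlock needs one chromosome and one episome interval")
    } else {
      a <- subseq(object@sequences[["chromosome"]], start(src), end(src))
      b <- subseq(object@sequences[["episome"]], start(img), end(img))
      if (as.character(a) != as.character(b))
        msg <- c(msg, "shared block image differs from chromosomal source")
      m <- object@markerLocus
      if (length(m) != 1L || as.character(seqnames(m)) != "episome" ||
          start(m) < start(img) || end(m) > end(img))
        msg <- c(msg, "marker locus must lie inside the shared-block image on the episome")
    }
  } else msg <- c(msg, "sharedBlock must have length 2")
  pr <- object@probes
  if (!all(c("replicon", "pos", "probe_id") %in% names(pr)))
    msg <- c(msg, "probes must have columns replicon, pos, probe_id")
  if (length(msg)) msg else TRUE
})

#' SegmentPlan: a rearranged replicon as an ordered list of oriented segments
#'
#' The universal rearrangement representation: one rearranged (circular)
#' replicon written as an ordered list of oriented reference intervals.
#' Repetition of a segment encodes multiplicity; `"-"` orientation means the
#' reverse complement of the reference interval.  The identity plan (one
#' `+` segment covering the whole replicon) realizes the reference sequence.
#'
#' @slot repliconId `"chromosome"` or `"episome"`.
#' @slot segments `data.frame` with columns `start`, `end`, `strand`
#'   (1-based closed intervals on the reference replicon).
#' @slot events `list` of event descriptors (label plus the reference
#'   interval(s) the event occupies), used for composition and truth tables.
#' @slot junctionInfo `data.frame` of designed junctions with columns
#'   `donor_pos`, `donor_strand`, `acceptor_pos`, `acceptor_strand`,
#'   `mh_len`, `label`.
#' @export
setClass("SegmentPlan",
  representation(
    repliconId   = "character",
    segments     = "data.frame",
    events       = "list",
    junctionInfo = "data.frame"
  )
)

setValidity("SegmentPlan", function(object) {
  msg <- character()
  seg <- object@segments
  if (!all(c("start", "end", "strand") %in% names(seg)))
    return("segments must have columns start, end, strand")
  if (nrow(seg)) {
    if (any(seg$start > seg$end)) msg <- c(msg, "empty or reversed segment")
    if (any(seg$start < 1L)) msg <- c(msg, "segment start below 1")
    if (!all(seg$strand %in% c("+", "-"))) msg <- c(msg, "strand must be + or -")
  }
  if (length(object@repliconId) != 1L) msg <- c(msg, "repliconId must be length 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceModel-class Named lengths of the two replicons.
#' @param model A `ReferenceModel`.
#' @export
repliconLengths <- function(model) {
  setNames(Biostrings::width(model@sequences), names(model@sequences))
}

#' Accessors for ReferenceModel slots
#'
#' @param model A [ReferenceModel-class] object.
#' @return The corresponding slot (`GRanges`, `DNAStringSet`, `data.frame`
#'   or integer).
#' @name reference-accessors
NULL

#' @rdname reference-accessors
#' @export
refSequences <- function(model) model@sequences

#' @rdname reference-accessors
#' @export
sharedBlock <- function(model) model@sharedBlock

#' @rdname reference-accessors
#' @export
markerLocus <- function(model) model@markerLocus

#' @rdname reference-accessors
#' @export
repSites <- function(model) model@repSites

#' @rdname reference-accessors
#' @export
maskIntervals <- function(model) model@mask

#' @rdname reference-accessors
#' @export
probeManifest <- function(model) model@probes

#' @rdname reference-accessors
#' @export
probeSpacing <- function(model) model@spacing

#' Accessors for SegmentPlan slots
#'
#' @param plan A [SegmentPlan-class] object.
#' @name plan-accessors
NULL

#' @rdname plan-accessors
#' @export
planSegments <- function(plan) plan@segments

#' @rdname plan-accessors
#' @export
planReplicon <- function(plan) plan@repliconId

#' @rdname plan-accessors
#' @export
planEvents <- function(plan) plan@events

#' @rdname plan-accessors
#' @export
planJunctionInfo <- function(plan) plan@junctionInfo

setMethod("show", "ReferenceModel", function(object) {
  lens <- repliconLengths(object)
  cat("ReferenceModel\n")
  cat(sprintf("  chromosome: %d nt (circular)\n", lens["chromosome"]))
  cat(sprintf("  episome:    %d nt (circular)\n", lens["episome"]))
  sb <- object@sharedBlock
  src <- sb[seqnames(sb) == "chromosome"]
  cat(sprintf("  shared block: %d nt (chromosome %d-%d)\n",
              width(src), start(src), end(src)))
  m <- object@markerLocus
  cat(sprintf("  marker locus: episome %d-%d\n", start(m), end(m)))
  cat(sprintf("  REP cassette clusters: %d; masked intervals: %d (%d nt)\n",
              length(object@repSites), length(object@mask),
              sum(width(object@mask))))
  cat(sprintf("  probes: %d at %d nt spacing\n",
              nrow(object@probes), object@spacing))
})

setMethod("show", "SegmentPlan", function(object) {
  seg <- object@segments
  cat(sprintf("SegmentPlan on %s: %d segment(s), realized length %d nt\n",
              object@repliconId, nrow(seg),
              sum(seg$end - seg$start + 1)))
  lab <- vapply(object@events, function(e) e$label, character(1))
  if (length(lab)) cat("  events:", paste(lab, collapse = ", "), "\n")
  if (nrow(object@junctionInfo))
    cat(sprintf("  designed junctions: %d\n", nrow(object@junctionInfo)))
})
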