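#' Write a ReferenceModel to a directory
#'
#' Emits `reference.fasta` (two records, headers carrying replicon id and
#' length), BED files for the shared block, marker locus, REP cassette
#' clusters and mask (0-based half-open, as BED requires), a TSV probe
#' manifest and a small YAML with the scalar geometry.  The file set
#' round-trips losslessly through [readReference()].
#'
#' @param model A [ReferenceModel-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
writeReference <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  lens <- repliconLengths(model)
  seqs <- model@sequences
  names(seqs) <- sprintf("%s length=%d circular", names(seqs), lens)
  fa <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(seqs, fa, width = 80L)

  si <- GenomeInfoDb::Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
  beds <- c(shared_block = "sharedBlock", marker_locus = "markerLocus",
            rep_sites = "repSites", mask = "mask")
  paths <- fa
  for (nm in names(beds)) {
    gr <- slot(model, beds[[nm]])
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
    names(gr) <- sprintf("%s_%03d", nm, seq_along(gr))
    p <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(gr, p, format = "BED")
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "probes.tsv")
  writeTsv(model@probes, mp)
  yp <- file.path(dir, "reference.yaml")
  yaml::write_yaml(list(spacing = model@spacing,
                        lengths = as.list(lens)), yp)
  invisible(c(paths, mp, yp))
}

#' Read a ReferenceModel back from a directory written by [writeReference()]
#'
#' @param dir Directory containing the reference file set.
#' @return A [ReferenceModel-class].
#' @export
readReference <- function(dir) {
  fa <- file.path(dir, "reference.fasta")
  if (!file.exists(fa)) stop("no reference.fasta under ", dir)
  seqs <- Biostrings::readDNAStringSet(fa)
  ids <- vapply(strsplit(names(seqs), " "), `[`, character(1), 1L)
  declared <- as.integer(sub(".*length=(\\d+).*", "\\1", names(seqs)))
  if (!all(declared == Biostrings::width(seqs)))
    stop("FASTA header length does not match sequence length")
  names(seqs) <- ids

  readBed <- function(nm) {
    gr <- rtracklayer::import(file.path(dir, paste0(nm, ".bed")), format = "BED")
    GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  }
  meta <- yaml::read_yaml(file.path(dir, "reference.yaml"))
  probes <- readTsv(file.path(dir, "probes.tsv"))
  probes$replicon <- as.character(probes$replicon)
  probes$probe_id <- as.character(probes$probe_id)

  new("ReferenceModel",
      sequences = seqs,
      sharedBlock = readBed("shared_block"),
      markerLocus = readBed("marker_locus"),
      repSites = readBed("rep_sites"),
      mask = readBed("mask"),
      probes = probes,
      spacing = as.integer(meta$spacing))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialize a SegmentPlan to a TSV segment table
#'
#' Columns: `replicon`, `start`, `end`, `strand`, `event_label` (label of
#' the event an individual segment belongs to, or `"backbone"`).
#'
#' @param plan A [SegmentPlan-class].
#' @param path Output TSV path.
#' @export
writeSegmentTable <- function(plan, path) {
  seg <- plan@segments
  lab <- if (!is.null(seg$event_label)) seg$event_label else "backbone"
  out <- data.frame(replicon = plan@repliconId,
                    start = seg$start, end = seg$end, strand = seg$strand,
                    event_label = lab)
  writeTsv(out, path)
}

#' Write a junction report TSV
#'
#' @param junctions Data frame from [junctionsOf()] (optionally annotated by
#'   [annotateRep()] / [classifyJunctionStructure()]).
#' @param path Output TSV path.
#' @export
writeJunctionTable <- function(junctions, path) {
  drop <- intersect("context", names(junctions))
  writeTsv(junctions[, setdiff(names(junctions), drop), drop = FALSE], path)
}
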