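# DNA stem-loop prediction by inverted-repeat enumeration, and positional
# classification of junction footprints against predicted structures.
# Deliberately no thermodynamics: the claims supported here are positional
# (is the junction on a stem or a loop), not energetic.

#' Find stem-loop (hairpin) structures in a DNA sequence
#'
#' Enumerates all maximal inverted repeats: for every candidate loop
#' interval within `loopRange`, the stem is extended outwards base by base
#' (stem2 must be the reverse complement of stem1 up to `maxMismatch`
#' substitutions; the innermost and outermost stem pairs must match) and is
#' reported if it reaches `minStem`.  Overlapping reports from different
#' loop choices are allowed.  Intended for windows of up to a few hundred
#' nt (junction contexts, REP cassettes).
#'
#' @param seq DNA string (character or `DNAString`).
#' @param minStem Minimal stem arm length (nt).
#' @param loopRange Length-2: allowed loop lengths (nt).
#' @param maxMismatch Maximal substitutions between stem2 and the reverse
#'   complement of stem1.
#' @return Data frame sorted by stem length (desc) then position:
#'   `stem1_start`, `stem1_end`, `loop_start`, `loop_end`, `stem2_start`,
#'   `stem2_end`, `stem_len`, `mismatches`.
#' @export
findStemLoops <- function(seq, minStem = 6L, loopRange = c(3L, 50L),
                          maxMismatch = 1L) {
  chars <- seqToChars(toupper(as.character(seq)))
  n <- length(chars)
  empty <- data.frame(stem1_start = integer(), stem1_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      stem2_start = integer(), stem2_end = integer(),
                      stem_len = integer(), mismatches = integer())
  if (n < 2L * minStem + loopRange[1]) return(empty)
  comp <- compBase(chars)
  out <- list()
  for (i in seq.int(2L, n - 1L)) {             # loop start
    for (lambda in seq.int(loopRange[1], loopRange[2])) {
      j <- i + lambda - 1L                     # loop end
      if (j > n - 1L) break
      # innermost pair must base-pair
      if (chars[i - 1L] != comp[j + 1L]) next
      a <- 1L; mm <- 0L; lastMatch <- 1L
      while (i - 1L - a >= 1L && j + 1L + a <= n) {
        if (chars[i - 1L - a] == comp[j + 1L + a]) {
          lastMatch <- a + 1L
        } else {
          mm <- mm + 1L
          if (mm > maxMismatch) break
        }
        a <- a + 1L
      }
      stemLen <- lastMatch                     # trimmed to outermost match
      if (stemLen < minStem) next
      usedMm <- sum(chars[(i - stemLen):(i - 1L)] !=
                    comp[(j + stemLen):(j + 1L)])
      out[[length(out) + 1L]] <- c(i - stemLen, i - 1L, i, j,
                                   j + 1L, j + stemLen, stemLen, usedMm)
    }
  }
  if (!length(out)) return(empty)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- names(empty)
  df <- unique(df)
  df[order(-df$stem_len, df$stem1_start, df$loop_start), , drop = FALSE]
}

#' Classify a junction's position against predicted stem-loops
#'
#' Considers the junction's shared tract (the microhomology footprint, not
#' a single point) against every stem-loop found in a window of context:
#' `"stem"` if the footprint intersects only stem arms, `"loop"` if only
#' loops, `"both"` if it touches stems and loops, `"unstructured"` if no
#' predicted structure overlaps it.
#'
#' @param context DNA string around the junction (>= `window` nt each side
#'   recommended; with less parental context the result carries a
#'   `not_classified` attribute).
#' @param footprint Length-2 integer: the footprint interval within
#'   `context` (for a zero-length tract, the two bases flanking the join).
#' @param window Context window (nt) centred on the footprint within which
#'   structures are considered.
#' @param minStem,loopRange,maxMismatch Passed to [findStemLoops()].
#' @return One of `"stem"`, `"loop"`, `"both"`, `"unstructured"`.
#' @export
classifyJunctionStructure <- function(context, footprint, window = 100L,
                                      minStem = 6L, loopRange = c(3L, 50L),
                                      maxMismatch = 1L) {
  n <- nchar(as.character(context))
  fs <- footprint[1]; fe <- footprint[2]
  if (fs < 1L || fe > n || fs > fe) stop("footprint outside context")
  lo <- max(1L, fs - window)
  hi <- min(n, fe + window)
  res <- "unstructured"
  if (fs - lo < 10L || hi - fe < 10L)
    attr(res, "not_classified") <- "insufficient context"
  sl <- findStemLoops(substr(as.character(context), lo, hi),
                      minStem, loopRange, maxMismatch)
  if (!nrow(sl)) return(res)
  fs0 <- fs - lo + 1L; fe0 <- fe - lo + 1L
  ovl <- function(s, e) fs0 <= e & fe0 >= s
  inStem <- any(ovl(sl$stem1_start, sl$stem1_end) |
                ovl(sl$stem2_start, sl$stem2_end))
  inLoop <- any(ovl(sl$loop_start, sl$loop_end))
  cls <- if (inStem && inLoop) "both"
    else if (inStem) "stem"
    else if (inLoop) "loop"
    else "unstructured"
  attributes(cls) <- attributes(res)
  cls
}

#' Classify every junction of a junction table
#'
#' Appends a `structure_class` column by running
#' [classifyJunctionStructure()] on each junction's realized context with
#' the microhomology footprint centred on the join.
#'
#' @param junctions Data frame from [junctionsOf()] (needs `context` and
#'   `mh_len`).
#' @param ... Passed to [classifyJunctionStructure()].
#' @export
annotateStructure <- function(junctions, ...) {
  junctions$structure_class <- vapply(seq_len(nrow(junctions)), function(i) {
    ctx <- junctions$context[i]
    half <- nchar(ctx) %/% 2L
    k <- junctions$mh_len[i]
    fp <- if (k > 0L) c(half - k + 1L, half) else c(half, half + 1L)
    as.character(classifyJunctionStructure(ctx, fp, ...))
  }, character(1))
  junctions
}
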