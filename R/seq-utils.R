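# Low-level circular-sequence helpers.  Replicon sequences are handled as
# plain character strings here; all public containers use Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

revcompChr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

compBase <- function(b) chartr("ACGT", "TGCA", b)

# wrap a vector of 1-based positions onto a circular replicon of length L
wrapPos <- function(i, L) ((i - 1L) %% L) + 1L

# oriented substring of a circular sequence given as a character vector of
# single bases; i..j in reading order along the given strand
circChars <- function(chars, i, len, L) chars[wrapPos(seq.int(i, length.out = len), L)]

seqToChars <- function(s) strsplit(s, "")[[1]]
charsToSeq <- function(ch) paste(ch, collapse = "")

# Oriented template reads around a junction.  A junction joins a donor end
# (position p read on strand sigma; the last base synthesized before the
# switch) to an acceptor start (position q on strand tau; the first base
# after the switch).
#
#  donorIn(k):   last k oriented bases of the donor segment (ends at p)
#  donorOut(k):  next k bases continuing past p on the donor template
#  acceptorIn(k):  first k oriented bases of the acceptor segment (from q)
#  acceptorOut(k): k bases immediately upstream of q on the acceptor template
donorIn <- function(chars, p, sigma, k, L) {
  if (k == 0L) return(character(0))
  if (sigma == "+") circChars(chars, p - k + 1L, k, L)
  else rev(compBase(circChars(chars, p, k, L)))
}
donorOut <- function(chars, p, sigma, k, L) {
  if (k == 0L) return(character(0))
  if (sigma == "+") circChars(chars, p + 1L, k, L)
  else rev(compBase(circChars(chars, p - k, k, L)))
}
acceptorIn <- function(chars, q, tau, k, L) {
  if (k == 0L) return(character(0))
  if (tau == "+") circChars(chars, q, k, L)
  else rev(compBase(circChars(chars, q - k + 1L, k, L)))
}
acceptorOut <- function(chars, q, tau, k, L) {
  if (k == 0L) return(character(0))
  if (tau == "+") circChars(chars, q - k, k, L)
  else rev(compBase(circChars(chars, q + 1L, k, L)))
}

# reference position (and whether the template base must be written as a
# complement) of the j-th base of acceptorOut counting backwards from the
# junction (j = 1 is the base immediately upstream of q)
acceptorOutPos <- function(q, tau, j, L) {
  if (tau == "+") wrapPos(q - j, L) else wrapPos(q + j, L)
}
donorOutPos <- function(p, sigma, j, L) {
  if (sigma == "+") wrapPos(p + j, L) else wrapPos(p - j, L)
}

pickOtherBase <- function(avoid, rng = DNA_BASES) {
  cand <- setdiff(rng, avoid)
  cand[1L]
}

# Plant a designed microhomology tract of length k at a junction.  The whole
# tract is placed on the left of the breakpoint (k_L = k, k_R = 0): the k
# oriented bases ending at the donor end are copied into the k template
# positions immediately upstream of the acceptor start, then one capping
# base immediately outside the tract on the acceptor side and the first
# donor-template base beyond the donor end are mutated so that the measured
# breakpoint ambiguity equals k exactly.
plantJunctionHomology <- function(chars, p, sigma, q, tau, k, L) {
  if (k > 0L) {
    tract <- donorIn(chars, p, sigma, k, L)            # oriented, ends at junction
    # write tract into acceptorOut positions j = k..1 (tract[1] is furthest
    # from the junction)
    for (j in seq_len(k)) {
      pos <- acceptorOutPos(q, tau, k + 1L - j, L)
      chars[pos] <- if (tau == "+") tract[j] else compBase(tract[j])
    }
  }
  # cap the left extension: oriented base k+1 upstream must differ between
  # donor and acceptor templates
  dk1 <- donorIn(chars, p, sigma, k + 1L, L)[1L]
  capPos <- acceptorOutPos(q, tau, k + 1L, L)
  capOriented <- pickOtherBase(dk1)
  chars[capPos] <- if (tau == "+") capOriented else compBase(capOriented)
  # cap the right extension: first acceptor base must differ from the first
  # donor-template base past the end (mutate the donor side, which is outside
  # every realized segment boundary involved in this junction)
  a1 <- acceptorIn(chars, q, tau, 1L, L)
  d1pos <- donorOutPos(p, sigma, 1L, L)
  d1cur <- if (sigma == "+") chars[d1pos] else compBase(chars[d1pos])
  if (identical(d1cur, a1)) {
    newOriented <- pickOtherBase(a1)
    chars[d1pos] <- if (sigma == "+") newOriented else compBase(newOriented)
  }
  chars
}

# random DNA as a character string
randomDna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# evaluate code under a fixed seed, restoring the caller's RNG state
# (minimal hot-path replacement for the usual wrappers)
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
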