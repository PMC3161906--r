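test_that("microhomology measurement: constructed shared tract, zero case, oracle agreement", {
  # construct a circular sequence with a designed 5-nt shared tract "TCAGG"
  # at a direct junction: donor ends at p, acceptor starts at q, and the 5
  # bases before q equal the 5 bases before p (capped on both sides)
  set.seed(12)
  chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  p <- 200L; q <- 100L
  chars[(p - 4):p] <- c("T", "C", "A", "G", "G")
  chars[(q - 5):(q - 1)] <- c("T", "C", "A", "G", "G")
  chars[q - 6] <- "A"; chars[p - 5] <- "C"      # cap left extension
  chars[p + 1] <- "A"; chars[q] <- "C"          # cap right extension
  s <- paste(chars, collapse = "")
  m <- measureMicrohomology(s, p, "+", q, "+")
  expect_identical(m$mh_len, 5L)
  expect_identical(m$mh_seq, "TCAGG")
  expect_identical(m$mh_len,
                   oracleMicrohomology(s, p, "+", q, "+"))
  # leftmost placement: coordinates slid maximally left
  expect_identical(m$donor_left, p - 5L)
  expect_identical(m$acceptor_left, q - 5L)

  # junction with no shared bases
  chars2 <- chars
  chars2[(q - 5):(q - 1)] <- c("G", "G", "T", "C", "C")
  chars2[q - 1] <- "A"    # != chars2[p] = "G"? ensure mismatch at first slide
  if (chars2[q - 1] == chars2[p]) chars2[q - 1] <- "C"
  if (chars2[q] == chars2[p + 1]) chars2[q] <- "G"
  s2 <- paste(chars2, collapse = "")
  m2 <- measureMicrohomology(s2, p, "+", q, "+")
  expect_identical(m2$mh_len, 0L)
  expect_identical(m2$mh_seq, "")
})

test_that("designed microhomology is recovered exactly across builders (oracle-checked)", {
  ref <- smallRef()
  set.seed(77)
  for (i in 1:25) {
    k <- sample(0:30, 1)
    res <- buildAmplification(ref, c(6001, 12000 + sample(0:1000, 1)),
                              copies = 2, mhLen = k)
    j <- junctionsOf(res$plan, res$ref)
    expect_identical(j$mh_len[1], k)
    expect_identical(
      oracleMicrohomology(episomeSeq(res$ref), j$donor_pos[1], j$donor_strand[1],
                          j$acceptor_pos[1], j$acceptor_strand[1]),
      k)
  }
  for (i in 1:15) {
    ks <- sample(0:30, 2)
    res <- buildEmbeddedInvertedDuplication(ref, c(6001, 13000), c(7001, 10000),
                                            copies = 2, mhLens = ks)
    j <- junctionsOf(res$plan, res$ref)
    j <- j[!duplicated(j$label), ]
    expect_identical(j$mh_len[j$label == "eid_inv1"], ks[1])
    expect_identical(j$mh_len[j$label == "eid_inv2"], ks[2])
    for (r in which(j$label != "amp")) {
      expect_identical(
        oracleMicrohomology(episomeSeq(res$ref), j$donor_pos[r],
                            j$donor_strand[r], j$acceptor_pos[r],
                            j$acceptor_strand[r]),
        j$mh_len[r])
    }
  }
})

test_that("microhomology is strand-symmetric", {
  ref <- smallRef()
  set.seed(5)
  flip <- function(s) if (s == "+") "-" else "+"
  for (i in 1:20) {
    res <- buildAmplification(ref, c(6001, 12000), copies = 2,
                              mhLen = sample(0:20, 1))
    j <- junctionsOf(res$plan, res$ref)[1, ]
    seqF <- episomeSeq(res$ref)
    # the same physical junction read on the opposite strand: donor and
    # acceptor swap roles with flipped strands
    mF <- measureMicrohomology(seqF, j$donor_pos, j$donor_strand,
                               j$acceptor_pos, j$acceptor_strand)
    mR <- measureMicrohomology(seqF, j$acceptor_pos,
                               flip(j$acceptor_strand),
                               j$donor_pos, flip(j$donor_strand))
    expect_identical(mF$mh_len, mR$mh_len)
    expect_identical(oracleRevcomp(mF$mh_seq), mR$mh_seq)
  }
})

test_that("REP annotation uses half-open containment of either breakpoint", {
  ref <- smallRef()
  rs <- repSites(ref)
  epiRep <- rs[GenomicRanges::seqnames(rs) == "episome"]
  a <- GenomicRanges::start(epiRep)[1]
  b <- GenomicRanges::end(epiRep)[1]
  j <- data.frame(replicon = "episome",
                  donor_pos = c(a, a - 1, 500, b, b + 1),
                  acceptor_pos = c(600, 600, b, 600, 600))
  out <- annotateRep(j, ref)
  expect_identical(out$at_rep, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("unidirectional PCR: orientation logic and product sizes", {
  ref <- smallRef()
  epi <- episomeSeq(ref)

  # same-orientation primer pairs give no product on the reference
  set.seed(9)
  for (i in 1:100) {
    at <- sort(sample(seq(500, 19000, by = 10), 2))
    p1 <- substr(epi, at[1], at[1] + 19)
    p2 <- substr(epi, at[2], at[2] + 19)
    expect_identical(nrow(suppressWarnings(unidirectionalPcr(epi, p1, p2))), 0L)
  }

  # convergent positive control: product of the designed size
  p1 <- substr(epi, 1001, 1020)
  p2 <- oracleRevcomp(substr(epi, 2981, 3000))
  prod <- unidirectionalPcr(epi, p1, p2)
  expect_identical(nrow(prod), 1L)
  expect_identical(prod$size, 2000L)
  expect_identical(prod$product_seq, substr(epi, 1001, 3000))

  # primers shorter than 15 nt are rejected
  expect_error(unidirectionalPcr(epi, "ACGTACGT", p2), "15")
})

test_that("an inversion spanning one primer site creates exactly one product", {
  ref <- smallRef()
  epi <- episomeSeq(ref)
  p1 <- substr(epi, 11001, 11020)
  p2 <- substr(epi, 14001, 14020)
  expect_identical(nrow(unidirectionalPcr(epi, p1, p2)), 0L)

  res <- buildInversionWithIndels(ref, c(13001, 15000), 0, 0)
  sample <- as.character(realizeSequence(res$plan, res$ref))
  prod <- unidirectionalPcr(sample, p1, p2)
  expect_identical(nrow(prod), 1L)
  # site 2 is inverted: its reverse complement now sits at
  # 13001 + (15000 - 14020) .. ; product spans site1 start to that end
  expectedEnd <- 13001L + (15000L - 14001L)
  expect_identical(prod$size, expectedEnd - 11001L + 1L)

  scr <- inversionScreen(sample, ref, flank = 6000, step = 1500)
  expect_true(scr$detected)
  expect_false(inversionScreen(epi, ref, flank = 6000, step = 1500)$detected)
})

test_that("inversion endpoint micro-indels are recovered exactly", {
  ref <- smallRef()
  res <- buildInversionWithIndels(ref, c(12001, 16000), 0, 0)
  expect_identical(junctionMicroindels(res$plan, res$ref),
                   c(left = 0L, right = 0L))
  res <- buildInversionWithIndels(ref, c(12001, 16000), 12, -7)
  expect_identical(junctionMicroindels(res$plan, res$ref),
                   c(left = 12L, right = -7L))
  set.seed(21)
  for (i in 1:40) {
    offs <- sample(-50:50, 2, replace = TRUE)
    res <- buildInversionWithIndels(ref, c(12001, 16000), offs[1], offs[2])
    expect_identical(junctionMicroindels(res$plan, res$ref),
                     c(left = offs[1], right = offs[2]))
  }
  # not applicable to a non-inversion plan
  resA <- buildAmplification(ref, c(6001, 12000), copies = 2,
                             designHomology = FALSE)
  expect_message(out <- junctionMicroindels(resA$plan, ref), "not applicable")
  expect_null(out)
})

test_that("cohort REP-snap frequency is recovered at the simulated rate", {
  ref <- defaultRef()
  cfg <- cohortConfig(nAmplified = 90, nControl = 0, repSnapProb = 0.24,
                      pEid = 0, pSplit = 0, pEmbeddedDel = 0,
                      pSecondaryDel = 0, pSecondaryInv = 0, sequences = TRUE)
  coh <- simulateCohort(cfg, ref, seed = 13)
  atRep <- vapply(coh$isolates[1:90], function(iso) {
    j <- junctionsOf(iso$plans[[1]], iso$ref)[1, ]
    annotateRep(j, iso$ref)$at_rep
  }, logical(1))
  k <- sum(atRep)
  # within the exact binomial 95% interval for p = 0.24, n = 90
  expect_gte(k, qbinom(0.025, 90, 0.24))
  expect_lte(k, qbinom(0.975, 90, 0.24))
})
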