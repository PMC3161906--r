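test_that("realizeSequence concatenates oriented segments", {
  ref <- smallRef()
  epi <- episomeSeq(ref)
  L <- nchar(epi)

  expect_identical(as.character(realizeSequence(identityPlan(ref), ref)), epi)

  # forward + reverse complement of the same prefix
  plan <- makePlan("episome", c(1, 1), c(10, 10), c("+", "-"))
  expect_identical(as.character(realizeSequence(plan, ref)),
                   paste0(substr(epi, 1, 10), oracleRevcomp(substr(epi, 1, 10))))

  # length additivity over random plans
  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:6, 1)
    s <- sample(L - 100, n)
    e <- pmin(L, s + sample(0:80, n, replace = TRUE))
    plan <- makePlan("episome", s, e, sample(c("+", "-"), n, replace = TRUE))
    expect_identical(length(realizeSequence(plan, ref)), sum(e - s + 1L))
  }

  expect_error(realizeSequence(makePlan("episome", 5, L + 10, "+"), ref),
               "bounds")
})

test_that("copyNumberProfile matches a per-base counting oracle and conserves mass", {
  ref <- smallRef()
  L <- repliconLengths(ref)[["episome"]]
  set.seed(17)
  for (i in 1:10) {
    n <- sample(1:5, 1)
    s <- sample(L - 500, n)
    e <- pmin(L, s + sample(1:400, n, replace = TRUE))
    plan <- makePlan("episome", s, e, sample(c("+", "-"), n, replace = TRUE))
    prof <- copyNumberProfile(plan, ref)
    expect_identical(prof, oracleProfile(planSegments(plan), L))
    expect_identical(sum(prof), sum(e - s + 1L))
  }
  expect_identical(unique(copyNumberProfile(identityPlan(ref), ref)), 1L)
})

test_that("conservation holds for every builder over random parameters", {
  ref <- smallRef()
  set.seed(53)
  for (i in 1:200) {
    builder <- sample(c("amp", "eid", "pia", "edel", "inv", "del"), 1)
    res <- switch(builder,
      amp = buildAmplification(ref, c(6001, 12000 + sample(0:2000, 1)),
                               copies = sample(2:20, 1),
                               mhLen = sample(0:30, 1),
                               designHomology = FALSE),
      eid = buildEmbeddedInvertedDuplication(ref, c(6001, 13000),
                                             c(7001, 9500 + sample(0:2000, 1)),
                                             copies = sample(1:10, 1),
                                             mhLens = sample(0:30, 2),
                                             triplication = sample(c(TRUE, FALSE), 1),
                                             designHomology = FALSE),
      pia = buildPartiallyInvertedAmplification(ref, c(6001, 11000),
                                                c(12001, 14000 + sample(0:2000, 1)),
                                                copies = sample(2:10, 1),
                                                designHomology = FALSE),
      edel = buildEmbeddedDeletionAmplicon(ref, c(6001, 13000),
                                           c(9501, 10000 + sample(0:1500, 1)),
                                           copies = 2 * sample(1:6, 1),
                                           designHomology = FALSE),
      inv = buildInversionWithIndels(ref, c(12001, 16000),
                                     sample(-50:50, 1), sample(-50:50, 1),
                                     designHomology = FALSE),
      del = buildSecondaryDeletion(ref, c(22001, 23000 + sample(0:2000, 1)),
                                   replicon = "chromosome",
                                   designHomology = FALSE))
    segs <- planSegments(res$plan)
    prof <- copyNumberProfile(res$plan, res$ref)
    expect_identical(sum(prof), sum(segs$end - segs$start + 1L))
  }
})

test_that("builder copy-number profiles have the designed shape", {
  ref <- smallRef()
  L <- repliconLengths(ref)[["episome"]]

  res <- buildAmplification(ref, c(6001, 12000), copies = 7, designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6001:12000]), 7L)
  expect_identical(unique(prof[c(1:6000, 12001:L)]), 1L)

  # pre-crossover precursor: flanks 1, inner 2
  res <- buildEmbeddedInvertedDuplication(ref, c(6001, 13000), c(7001, 10000),
                                          copies = 1, designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6001:7000]), 1L)
  expect_identical(unique(prof[7001:10000]), 2L)

  # expanded: flanks at copies, inner at 2x copies
  res <- buildEmbeddedInvertedDuplication(ref, c(6001, 13000), c(7001, 10000),
                                          copies = 5, designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6005:7000]), 5L)
  expect_identical(unique(prof[7001:10000]), 10L)

  # triplication layout: inner at 3x the flank copy
  res <- buildEmbeddedInvertedDuplication(ref, c(6001, 13000), c(7001, 10000),
                                          copies = 2, triplication = TRUE,
                                          designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6005:7000]), 2L)
  expect_identical(unique(prof[7005:10000]), 6L)

  # split amplification: both blocks at copies, gap unchanged
  res <- buildPartiallyInvertedAmplification(ref, c(6001, 11000),
                                             c(12001, 15000), copies = 6,
                                             designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6001:11000]), 6L)
  expect_identical(unique(prof[11001:12000]), 1L)
  expect_identical(unique(prof[12001:15000]), 6L)

  # embedded deletion at half the amplicon copy
  res <- buildEmbeddedDeletionAmplicon(ref, c(6001, 13000), c(9501, 10500),
                                       copies = 4, designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof[6001:9500]), 4L)
  expect_identical(unique(prof[9501:10500]), 2L)

  # reciprocal inversion preserves everything
  res <- buildInversionWithIndels(ref, c(12001, 16000), 0, 0,
                                  designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, ref)
  expect_identical(unique(prof), 1L)
  expect_identical(length(realizeSequence(res$plan, ref)), L)

  # offsets book-keeping: realized length = L + lo + ro
  res <- buildInversionWithIndels(ref, c(12001, 16000), 12, -7,
                                  designHomology = FALSE)
  expect_identical(length(realizeSequence(res$plan, ref)), L + 12L - 7L)
  prof <- copyNumberProfile(res$plan, ref)
  expect_true(all(prof %in% 0:2))

  # deletion removes its interval
  res <- buildSecondaryDeletion(ref, c(22001, 23600), replicon = "chromosome",
                                designHomology = FALSE)
  prof <- copyNumberProfile(res$plan, res$ref)
  expect_identical(unique(prof[22001:23600]), 0L)
  expect_identical(sum(prof), repliconLengths(ref)[["chromosome"]] - 1600L)
})

test_that("degenerate embedded deletion reduces to a plain amplification", {
  ref <- smallRef()
  a <- buildEmbeddedDeletionAmplicon(ref, c(6001, 12000), c(10, 9),
                                     copies = 4, mhLens = c(5, 5),
                                     designHomology = FALSE)
  b <- buildAmplification(ref, c(6001, 12000), copies = 4, mhLen = 5,
                          designHomology = FALSE)
  expect_identical(planSegments(a$plan)[, c("start", "end", "strand")],
                   planSegments(b$plan)[, c("start", "end", "strand")])
})

test_that("junction enumeration: identity has none, builders have their designed set", {
  ref <- smallRef()
  expect_identical(nrow(junctionsOf(identityPlan(ref), ref)), 0L)

  res <- buildAmplification(ref, c(6001, 12000), copies = 4, mhLen = 5)
  j <- junctionsOf(res$plan, res$ref)
  expect_identical(nrow(j), 3L)                  # copies - 1 instances
  expect_identical(unique(j$label), "amp")

  res <- buildEmbeddedInvertedDuplication(res$ref, c(6001, 13000),
                                          c(7001, 10000), copies = 2,
                                          mhLens = c(4, 9))
  j <- junctionsOf(res$plan, res$ref)
  types <- unique(j[, c("donor_pos", "donor_strand", "acceptor_pos",
                        "acceptor_strand", "label")])
  expect_identical(sort(types$label[types$label != "amp"]),
                   c("eid_inv1", "eid_inv2"))    # two novel junction types
  expect_identical(sum(types$label == "amp"), 1L)

  # amplification + unlinked deletion composed: 1 + 1 junction types
  resA <- buildAmplification(ref, c(6001, 12000), copies = 3, mhLen = 5,
                             replicon = "episome")
  resD <- buildSecondaryDeletion(resA$ref, c(14001, 15000), mhLen = 2,
                                 replicon = "episome")
  comp <- composePlans(resD$ref, resA$plan, resD$plan)
  j <- junctionsOf(comp, resD$ref)
  expect_identical(sort(unique(j$label)), c("amp", "secondary_del"))
  expect_identical(nrow(unique(j[, c("donor_pos", "acceptor_pos")])), 2L)
})

test_that("composition refuses overlapping event regions", {
  ref <- smallRef()
  a <- buildAmplification(ref, c(6001, 12000), copies = 3,
                          designHomology = FALSE)
  b <- buildSecondaryDeletion(ref, c(11001, 13000), replicon = "episome",
                              designHomology = FALSE)
  expect_error(composePlans(ref, a$plan, b$plan), "overlap")
})

test_that("builder preconditions are enforced", {
  ref <- smallRef()
  expect_warning(buildAmplification(ref, c(12001, 14000), copies = 3,
                                    designHomology = FALSE),
                 "not be selectable")
  expect_error(buildAmplification(ref, c(6001, 12000), copies = 1),
               "copies")
  expect_error(buildEmbeddedInvertedDuplication(ref, c(6001, 13000),
                                                c(10001, 12000), copies = 2),
               "marker")
  expect_error(buildEmbeddedDeletionAmplicon(ref, c(6001, 13000),
                                             c(7901, 9100), copies = 4),
               "marker")
  expect_error(buildPartiallyInvertedAmplification(ref, c(6001, 12000),
                                                   c(11001, 14000),
                                                   copies = 3),
               "disjoint")
  expect_error(buildInversionWithIndels(ref, c(12001, 16000), 150, 0),
               "offset")
  expect_error(buildSecondaryDeletion(ref, c(7901, 9100),
                                      replicon = "episome"),
               "marker")
})
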