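test_that("noise-free ratios are exact log2 copy ratios", {
  ref <- smallRef()
  tab <- simulateIsolateRatios(NULL, ref, sigma = 0)
  expect_true(all(tab$log2_ratio == 0))

  res <- buildAmplification(ref, c(6001, 12000), copies = 70,
                            designHomology = FALSE)
  tab <- simulateIsolateRatios(res$plan, ref, sigma = 0)
  inAmp <- tab$replicon == "episome" & tab$pos >= 6001 & tab$pos <= 12000
  expect_equal(unique(tab$log2_ratio[inAmp]), log2(70), tolerance = 1e-12)
  expect_true(all(tab$log2_ratio[!inAmp] == 0))
})

test_that("noise level matches the requested sigma", {
  ref <- defaultRef()
  tab <- simulateIsolateRatios(NULL, ref, sigma = 0.2, seed = 99)
  expect_gt(nrow(tab), 2500)
  expect_gt(sd(tab$log2_ratio), 0.19)
  expect_lt(sd(tab$log2_ratio), 0.21)
  # deterministic per seed
  tab2 <- simulateIsolateRatios(NULL, ref, sigma = 0.2, seed = 99)
  expect_identical(tab$log2_ratio, tab2$log2_ratio)
})

test_that("zero copies floor to a flagged pseudo-count; zero reference drops probes", {
  ref <- smallRef()
  res <- buildSecondaryDeletion(ref, c(6001, 7000), replicon = "episome",
                                designHomology = FALSE)
  tab <- simulateIsolateRatios(res$plan, ref, sigma = 0)
  del <- tab$replicon == "episome" & tab$pos >= 6001 & tab$pos <= 7000
  expect_true(all(tab$floored[del]))
  expect_equal(unique(tab$log2_ratio[del]), log2(0.01), tolerance = 1e-12)

  cn <- rep(1, nrow(probeManifest(ref)))
  cnRef <- cn; cnRef[1:3] <- 0
  expect_warning(tab <- simulateRatios(cn, ref, profileReference = cnRef),
                 "dropped")
  expect_identical(nrow(tab), nrow(probeManifest(ref)) - 3L)
})

test_that("calling rule: a single supra-threshold probe is never called, two adjacent always are", {
  ref <- smallRef()
  base <- simulateIsolateRatios(NULL, ref, sigma = 0)
  epi <- which(base$replicon == "episome")
  set.seed(4)
  for (rep in 1:20) {
    i <- sample(epi[3:(length(epi) - 3)], 1)
    t1 <- base; t1$log2_ratio[i] <- 3
    expect_identical(nrow(callSegments(t1, ref)), 0L)
    # threshold boundary is inclusive: exactly 1.0 on two adjacent probes
    t2 <- base; t2$log2_ratio[c(i, i + 1)] <- 1.0
    calls <- callSegments(t2, ref)
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$direction, "gain")
    expect_identical(calls$n_probes, 2L)
    # just under threshold: nothing
    t3 <- base; t3$log2_ratio[c(i, i + 1)] <- 0.999
    expect_identical(nrow(callSegments(t3, ref)), 0L)
  }
})

test_that("adjacency breaks across masked gaps and wraps across the origin", {
  ref <- smallRef()
  base <- simulateIsolateRatios(NULL, ref, sigma = 0)
  # chromosome mask 2001-3000: probes 1901 and 3001 flank it
  i <- which(base$replicon == "chromosome" & base$pos == 1901)
  j <- which(base$replicon == "chromosome" & base$pos == 3001)
  t <- base; t$log2_ratio[c(i, j)] <- 2
  expect_identical(nrow(callSegments(t, ref)), 0L)

  # circular adjacency: last and first probes of the episome are adjacent
  epi <- which(base$replicon == "episome")
  t <- base
  t$log2_ratio[c(utils::head(epi, 2), utils::tail(epi, 2))] <- 2
  calls <- callSegments(t, ref)
  expect_identical(nrow(calls), 1L)
  expect_true(calls$wraps)
  expect_identical(calls$n_probes, 4L)
})

test_that("noise-free amplicon recovery: boundaries within one spacing, est_copy exact", {
  ref <- smallRef()
  res <- buildAmplification(ref, c(6001, 12000), copies = 70,
                            designHomology = FALSE)
  tab <- simulateIsolateRatios(res$plan, ref, sigma = 0)
  calls <- callSegments(tab, ref)
  expect_identical(nrow(calls), 1L)
  expect_lte(abs(calls$start - 6001), probeSpacing(ref))
  expect_lte(abs(calls$end - 12000), probeSpacing(ref))
  expect_equal(calls$est_copy, 70, tolerance = 1e-9)
})

test_that("raising the threshold never increases the total called extent", {
  ref <- smallRef()
  res <- buildAmplification(ref, c(6001, 12000), copies = 3,
                            designHomology = FALSE)
  tab <- simulateIsolateRatios(res$plan, ref, sigma = 0.3, seed = 8)
  called <- vapply(c(0.5, 1, 1.5, 2, 3), function(thr) {
    calls <- callSegments(tab, ref, thresholdLog2 = thr)
    if (!nrow(calls)) 0 else sum(calls$end - calls$start)
  }, numeric(1))
  expect_true(all(diff(called) <= 0))
})

test_that("each builder's noise-free scan classifies to its own label", {
  ref <- smallRef()
  cases <- list(
    AMP = buildAmplification(ref, c(6001, 12000), copies = 70,
                             designHomology = FALSE),
    EID = buildEmbeddedInvertedDuplication(ref, c(6001, 13000), c(7001, 10000),
                                           copies = 70, designHomology = FALSE),
    EMBEDDED_DEL = buildEmbeddedDeletionAmplicon(ref, c(6001, 13000),
                                                 c(9501, 10500), copies = 70,
                                                 designHomology = FALSE),
    SPLIT_AMPLICON = buildPartiallyInvertedAmplification(ref, c(6001, 11000),
                                                         c(12001, 15000),
                                                         copies = 70,
                                                         designHomology = FALSE),
    SECONDARY_DEL = buildSecondaryDeletion(ref, c(22001, 24000),
                                           replicon = "chromosome",
                                           designHomology = FALSE))
  for (expected in names(cases)) {
    tab <- simulateIsolateRatios(cases[[expected]]$plan, ref, sigma = 0)
    cl <- classifyEvents(callSegments(tab, ref), ref, tab)
    hit <- cl$primary == expected || expected %in% cl$secondary
    expect_true(hit, label = sprintf("%s classified as %s", expected, cl$primary))
  }

  # amplification + unlinked loss on another replicon -> AMP + SECONDARY_DEL
  resA <- buildAmplification(ref, c(6001, 12000), copies = 70,
                             designHomology = FALSE)
  resD <- buildSecondaryDeletion(ref, c(22001, 23600), replicon = "chromosome",
                                 designHomology = FALSE)
  tab <- simulateIsolateRatios(list(resA$plan, resD$plan), ref, sigma = 0)
  cl <- classifyEvents(callSegments(tab, ref), ref, tab)
  expect_identical(cl$primary, "AMP")
  expect_identical(cl$secondary, "SECONDARY_DEL")
})

test_that("unsorted probe tables are rejected and empty tables give empty calls", {
  ref <- smallRef()
  tab <- simulateIsolateRatios(NULL, ref, sigma = 0)
  expect_identical(nrow(callSegments(tab[0, ], ref)), 0L)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_error(callSegments(shuffled, ref), "sorted")
})
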