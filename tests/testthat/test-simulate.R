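test_that("the packaged mock profile matches the standard's declaration", {
  p <- defaultMockProfile()
  ab <- mockAbundance(p)
  expect_setequal(mockTaxa(p),
                  c("Pseudomonas", "Enterobacteriaceae_1",
                    "Enterobacteriaceae_2", "Listeria", "Staphylococcus",
                    "Lactobacillus", "Enterococcus", "Bacillus"))
  expect_equal(unname(ab["Lactobacillus"]), 18.8)
  expect_equal(sum(ab), 100, tolerance = 1e-9)
  expect_gte(sum(ab), 99); expect_lte(sum(ab), 101)
  g <- gramFlags(p)
  expect_equal(sum(g == "negative"), 3)
  expect_equal(sum(g == "positive"), 5)
})

test_that("simulateComposition respects depth, seed and the multinomial limit", {
  one <- simulateComposition(c(X = 1.0), depth = 500, seed = 1)
  expect_identical(unname(one), 500L)

  a <- simulateComposition(c(x = .3, y = .7), 1000, seed = 42)
  b <- simulateComposition(c(x = .3, y = .7), 1000, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a), 1000L)

  # overdispersion -> Inf is a plain multinomial: each count of a uniform
  # 4-taxon profile at depth 1e5 within 5 binomial SDs of 25000
  u <- simulateComposition(setNames(rep(.25, 4), letters[1:4]), 1e5,
                           overdispersion = Inf, seed = 7)
  sd <- sqrt(1e5 * .25 * .75)
  expect_true(all(abs(u - 25000) < 5 * sd))

  expect_error(simulateComposition(c(a = -0.1, b = 1.1), 10), ">= 0")
  expect_error(simulateComposition(c(a = .4, b = .4), 10), "sum to 1")
})

test_that("kit bias reweights and renormalizes compositions", {
  f <- c(x = .5, y = .5)
  expect_equal(applyKitBias(f, kitBiasModel(A = c(x = 1, y = 1)), "A"), f)
  expect_equal(applyKitBias(f, kitBiasModel(A = c(x = 1, y = 3)), "A"),
               c(x = .25, y = .75))
  rnd <- runif(6); names(rnd) <- letters[1:6]
  biased <- applyKitBias(rnd / sum(rnd),
                         kitBiasModel(B = c(a = .1, d = 7)), "B")
  expect_equal(sum(biased), 1)
  expect_warning(applyKitBias(f, kitBiasModel(A = c(x = 2)), "C"),
                 "absent")
  expect_error(kitBiasModel(A = c(x = -1)), "> 0")
})

test_that("a full-factorial design yields the expected study shape", {
  sim <- simulateStudy(studyDesign(nDonors = 10, replicates = 2), seed = 3)
  meta <- sampleMeta(sim$experiment)
  expect_equal(sum(meta$role == "sample"), 160)
  expect_equal(sum(meta$role == "ntc"), 4)
  expect_equal(sum(meta$role == "mock_spiked"), 16)
  expect_true(all(is.na(meta$donor[meta$role == "ntc"])))
  # truth compositions are proper per-sample compositions
  cs <- colSums(sim$truth$sampleComposition[, meta$role != "ntc"])
  expect_equal(unname(cs), rep(1, sum(meta$role != "ntc")))
  # every OTU carries a 250 bp sequence and a lineage
  expect_equal(length(otuSequences(sim$experiment)),
               nrow(sim$experiment))
  expect_true(all(Biostrings::width(otuSequences(sim$experiment)) == 250))
})

test_that("contaminant-free NTCs contain only the cyanobacteria spike", {
  empty <- contaminantModel(list(A = numeric(0), B = numeric(0),
                                 C = numeric(0), D = numeric(0)))
  sim <- simulateStudy(studyDesign(nDonors = 2), contam = empty, seed = 4)
  meta <- sampleMeta(sim$experiment)
  ntc <- counts(sim$experiment)[, meta$sample_id[meta$role == "ntc"]]
  nonSpike <- rownames(ntc) != sim$truth$spikeOtu
  expect_true(all(ntc[nonSpike, ] == 0))
  expect_true(all(colSums(ntc) > 0))
})

test_that("simulation is bit-exactly reproducible under a fixed seed", {
  s1 <- simulateStudy(studyDesign(nDonors = 2), seed = 11)
  s2 <- simulateStudy(studyDesign(nDonors = 2), seed = 11)
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(s1$qpcr, s2$qpcr)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateStudy(studyDesign(nDonors = 2), seed = 12)
  expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("qPCR copies reproduce spike dominance of mock-spiked extracts", {
  sim <- simulateStudy(studyDesign(nDonors = 4), seed = 5)
  meta <- sampleMeta(sim$experiment)
  q <- setNames(sim$qpcr$log10_copies, sim$qpcr$sample_id)
  spiked <- median(q[meta$sample_id[meta$role == "mock_spiked"]])
  unspiked <- median(q[meta$sample_id[meta$role == "sample"]])
  expect_equal(spiked, 5.7, tolerance = 0.01)
  expect_equal(unspiked, 1.9, tolerance = 0.2)
})

test_that("study design validity catches bad layouts", {
  expect_error(studyDesign(nDonors = 0), "nDonors")
  expect_error(studyDesign(kits = character(0)), "kits")
  expect_error(studyDesign(kits = "Z"), "kits")
  expect_error(studyDesign(depthMean = -5), "depthMean")
})
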