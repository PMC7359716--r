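# A hand-built 4-OTU study: one cyanobacteria spike OTU, one contaminant
# present in NTCs, two endogenous OTUs.
toyStudy <- function(ntcCounts = c(cyano = 900, c1 = 5)) {
  m <- cbind(S1 = c(cyano = 0, c1 = 10, e1 = 50, e2 = 40),
             S2 = c(cyano = 2, c1 = 2, e1 = 30, e2 = 60),
             NTC1 = c(ntcCounts["cyano"], ntcCounts["c1"], e1 = 0,
                      e2 = 0))
  rownames(m) <- c("cyano", "c1", "e1", "e2")
  meta <- data.frame(
    sample_id = c("S1", "S2", "NTC1"),
    donor = c("D1", "D2", NA), kit = "B",
    milk = c("WM", "WM", NA), replicate = c(1L, 1L, NA),
    role = c("sample", "sample", "ntc"))
  seqs <- c(cyano = strrep("A", 250), c1 = strrep("C", 250),
            e1 = strrep("G", 250), e2 = strrep("T", 250))
  lin <- c(cyano = "k__Bacteria; p__Cyanobacteria; g__Arthrospira",
           c1 = "k__Bacteria; p__Proteobacteria; g__Ralstonia",
           e1 = "k__Bacteria; p__Firmicutes; g__Staphylococcus",
           e2 = "k__Bacteria; p__Proteobacteria; g__Acinetobacter")
  MilkExperiment(m, meta, sequences = seqs, taxonomy = lin)
}

test_that("spike identification partitions NTC reads", {
  x <- toyStudy()
  sp <- identifySpike(x)
  expect_identical(sp$spikeOtus, "cyano")
  expect_identical(rownames(sp$residual), "c1")
  expect_equal(unname(sp$residual["c1", "NTC1"]), 5)

  # all-spike NTC leaves an empty contaminant set
  sp2 <- identifySpike(toyStudy(c(cyano = 900, c1 = 0)))
  expect_equal(nrow(sp2$residual), 0)

  # a label matching nothing warns and keeps the table
  expect_warning(sp3 <- identifySpike(x, spikeLabel = "Nonexistent"),
                 "mislabel")
  expect_setequal(rownames(sp3$residual), c("cyano", "c1"))
})

test_that("profile means include zero-count NTCs in the denominator", {
  # four pooled NTCs with contaminant counts (2, 0, 1, 1) -> mean 1.0
  m <- cbind(N1 = c(c1 = 2), N2 = c(c1 = 0), N3 = c(c1 = 1),
             N4 = c(c1 = 1))
  rownames(m) <- "c1"
  meta <- data.frame(sample_id = paste0("N", 1:4), donor = NA,
                     kit = c("A", "B", "C", "D"), milk = NA,
                     replicate = NA, role = "ntc")
  seqs <- c(c1 = strrep("C", 250))
  pooled <- buildContaminantProfile(m, meta, seqs, scope = "pooled")
  expect_equal(unname(profileMeans(pooled)), (2 + 0 + 1 + 1) / 4)

  # per-kit with one NTC per kit: the profile is that NTC's own counts
  perkit <- buildContaminantProfile(m, meta, seqs, scope = "per_kit")
  expect_equal(unname(profileMeans(perkit, "A")), 2)
  expect_equal(length(profileMeans(perkit, "B")), 0)  # mean 0 dropped
  expect_equal(unname(profileMeans(perkit, "C")), 1)
  expect_identical(profileScope(perkit), "per_kit")

  expect_error(buildContaminantProfile(m, meta, c(zz = "ACGT")),
               "missing a representative sequence")
})

test_that("auto scope resolves on NTC coverage of the kits in use", {
  x <- toyStudy()  # single kit B with one NTC -> per_kit
  d <- decontaminate(x)
  expect_identical(profileScope(d$profile), "per_kit")

  # a study kit without any NTC forces pooled scope
  meta <- sampleMeta(x)
  meta$kit[meta$sample_id == "S2"] <- "C"
  y <- MilkExperiment(counts(x), meta,
                      sequences = as.character(otuSequences(x)),
                      taxonomy = otuLineage(x))
  expect_identical(profileScope(decontaminate(y)$profile), "pooled")
})

test_that("contaminant matching is exact equality on truncated sequences", {
  base <- randomSeq(250)
  prof <- ContaminantProfile("pooled", list(all = setNames(5, base)),
                             "N1")

  mm <- matchContaminants(c(o1 = base), prof)
  expect_identical(mm[[base]], "o1")

  # one mismatched position breaks the match
  off <- base
  substr(off, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                   substr(base, 100, 100))[1]
  expect_length(matchContaminants(c(o1 = off), prof)[[1]], 0)

  # a 260-mer identical over the first 250 bp matches under truncation
  long <- paste0(base, randomSeq(10))
  expect_identical(matchContaminants(c(o1 = long), prof)[[1]], "o1")
  expect_length(matchContaminants(c(o1 = long), prof,
                                  truncateTo = NULL)[[1]], 0)
})

test_that("subtraction removes per-kit means, clamps at zero and reports", {
  x <- toyStudy()
  prof <- ContaminantProfile(
    "per_kit", list(B = setNames(3.5, strrep("C", 250))), "NTC1")
  out <- subtractContaminants(x, prof)
  m <- counts(out$experiment)
  expect_equal(m["c1", "S1"], 10 - 3.5)
  expect_equal(m["c1", "S2"], 0)           # 2 - 3.5 clamps at zero
  expect_equal(m["e1", "S1"], 50)          # unmatched OTUs untouched
  expect_equal(m["c1", "NTC1"], 5)         # NTC columns pass through
  expect_true(isDecontaminated(out$experiment))

  # the report totals equal sum(min(count, mean)) over matched cells
  expect_equal(sum(out$report$removed), min(10, 3.5) + min(2, 3.5))

  # decontamination never increases any count
  expect_true(all(m <= counts(x)))

  # integerize rounds half away from zero
  mi <- counts(subtractContaminants(x, prof,
                                    integerize = TRUE)$experiment)
  expect_equal(mi["c1", "S1"], 7)

  bad <- ContaminantProfile("per_kit",
                            list(A = setNames(1, strrep("C", 250))),
                            "NTC1")
  expect_error(subtractContaminants(x, bad), "lacks kit")
})

test_that("subtraction is idempotent once matched counts fall below the mean", {
  x <- toyStudy()
  prof <- ContaminantProfile(
    "per_kit", list(B = setNames(20, strrep("C", 250))), "NTC1")
  once <- subtractContaminants(x, prof)$experiment
  twice <- subtractContaminants(once, prof)$experiment
  expect_equal(counts(twice), counts(once))
})

test_that("end-to-end decontamination strips spike and contaminants", {
  x <- toyStudy()
  d <- decontaminate(x)
  m <- counts(d$experiment)
  expect_equal(unname(m["cyano", c("S1", "S2")]), c(0, 0))
  expect_equal(m["c1", "S1"], 10 - 5)  # mean of the single NTC
  expect_true(all(m["e1", c("S1", "S2")] == c(50, 30)))
  expect_setequal(d$report$source, c("contaminant", "spike"))
})

test_that("profile estimates sharpen as NTCs per kit accumulate", {
  rmseFor <- function(nNtc, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulateStudy(studyDesign(nDonors = 2, nNtcPerKit = nNtc),
                           seed = s + 1000 * nNtc)
      d <- decontaminate(sim$experiment)
      seqs <- as.character(otuSequences(sim$experiment))
      errs <- unlist(lapply(names(sim$truth$contaminantMeans),
                            function(k) {
        tr <- sim$truth$contaminantMeans[[k]]
        est <- profileMeans(d$profile, k)
        byOtu <- setNames(rep(0, length(tr)), names(tr))
        ids <- names(seqs)[match(names(est), seqs)]
        ok <- ids %in% names(tr)
        byOtu[ids[ok]] <- est[ok]
        byOtu - tr
      }))
      sqrt(mean(errs^2))
    }, numeric(1)))
  }
  seeds <- 1:5
  r <- vapply(c(1, 4, 16), rmseFor, numeric(1), seeds = seeds)
  expect_true(r[1] > r[2] && r[2] > r[3])
})
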