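test_that("Shannon index matches closed forms and the direct formula", {
  expect_equal(shannonIndex(c(1, 0, 0)), 0)
  expect_equal(shannonIndex(rep(5, 4)), log(4))
  expect_equal(shannonIndex(c(5, 3, 2)), 1.0297, tolerance = 1e-4)
  # invariant under positive rescaling
  x <- c(12, 7, 0, 3, 1)
  expect_equal(shannonIndex(x), shannonIndex(37 * x))
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  expect_error(shannonIndex(c(-1, 2)), "non-negative")

  set.seed(101)
  for (i in 1:100) {
    v <- rpois(sample(3:20, 1), lambda = 5)
    v[1] <- v[1] + 1L
    expect_equal(shannonIndex(v), oracleShannon(v))
  }
})

test_that("Bray-Curtis matches its formula, bounds and symmetry", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(5, 0), c(0, 3)), 1)
  expect_equal(brayCurtis(c(6, 2), c(2, 2)), 4 / 12)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(202)
  for (i in 1:100) {
    n <- sample(2:15, 1)
    x <- rpois(n, 4); y <- rpois(n, 4)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[1] <- 1
    bc <- brayCurtis(x, y)
    expect_equal(bc, oracleBray(x, y))
    expect_equal(bc, brayCurtis(y, x))
    expect_gte(bc, 0); expect_lte(bc, 1)
  }
})

test_that("complete linkage reproduces exhaustive recomputation", {
  # 3-point worked case: merge (A,B) at 0.1, then C at max = 0.5
  d <- matrix(c(0, .1, .5, .1, 0, .4, .5, .4, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  hc <- hclustComplete(d)
  expect_equal(hc$height, c(0.1, 0.5))
  first <- hc$merge[1, ]
  expect_setequal(first, c(-1, -2))

  # equidistant points merge at a single height
  e <- matrix(0.3, 4, 4); diag(e) <- 0
  dimnames(e) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_true(all(hclustComplete(e)$height == 0.3))

  # merge heights are non-decreasing and match the naive oracle
  set.seed(303)
  for (i in 1:100) {
    m <- randomDistMatrix(6)
    hc <- hclustComplete(m)
    expect_true(all(diff(hc$height) >= 0))
    expect_equal(sort(hc$height), oracleCompleteHeights(m))
  }

  expect_error(hclustComplete(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("rarefaction subsamples without replacement at exact depth", {
  x <- c(a = 30, b = 50, c = 20)
  expect_identical(rarefyCounts(x, sum(x), seed = 1), as.integer(x) |>
                     setNames(names(x)))
  expect_identical(unname(rarefyCounts(c(z = 400), 100, seed = 1)), 100L)
  expect_error(rarefyCounts(x, 101), "exceeds")

  r1 <- rarefyCounts(x, 40, seed = 99)
  expect_identical(r1, rarefyCounts(x, 40, seed = 99))
  expect_equal(sum(r1), 40)

  # mean over repeated draws matches the hypergeometric expectation
  reps <- 3000
  draws <- vapply(seq_len(reps), function(i)
    rarefyCounts(c(30, 70), 20)[1], numeric(1))
  hypMean <- 20 * 30 / 100
  hypSd <- sqrt(20 * .3 * .7 * (100 - 20) / (100 - 1))
  expect_lt(abs(mean(draws) - hypMean), 3 * hypSd / sqrt(reps))
})

test_that("alpha-rarefaction curves behave at their limits", {
  expect_true(all(alphaRarefactionCurve(c(one = 500), c(10, 100, 500),
                                        seed = 1)$mean_shannon == 0))
  # 2-taxon 50/50 community plateaus near log(2)
  x <- c(a = 5000, b = 5000)
  curve <- alphaRarefactionCurve(x, c(10, 10000), reps = 20, seed = 2)
  expect_equal(curve$mean_shannon[2], log(2), tolerance = 1e-9)
  expect_lte(curve$mean_shannon[1], curve$mean_shannon[2])
  # samples shallower than a depth drop out
  m <- cbind(S1 = c(10, 10), S2 = c(200, 200))
  rownames(m) <- c("a", "b")
  out <- alphaRarefactionCurve(m, c(20, 100), seed = 3)
  expect_equal(out$n_samples, c(2L, 1L))
  expect_error(alphaRarefactionCurve(x, c(100, 10)), "ascending")
})

test_that("log-ratio biplot coordinates give the best rank-2 fit", {
  set.seed(404)
  m <- matrix(rpois(6 * 4, 40) + 1, nrow = 6,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:4)))
  m[2, 1] <- 0  # exercise zero replacement
  bp <- logratioBiplot(m, minAbundance = 0)

  # the biplot product equals the best rank-2 approximation of the
  # centered clr matrix (error cross-checked by an eigen oracle)
  p <- sweep(m + 0.5, 2, colSums(m) + 0.5 * nrow(m), "/")
  clr <- t(apply(log(p), 2, function(v) v - mean(v)))
  z <- sweep(clr, 2, colMeans(clr), "-")
  recon <- bp$samples %*% t(bp$taxa)  # lambda cancels in the product
  expect_equal(sqrt(sum((z - recon)^2)), oracleRank2Error(z),
               tolerance = 1e-8)

  # clr rows sum to zero by construction
  expect_true(all(abs(rowSums(clr)) < 1e-9))

  # lambda scaling equalizes the two point sets' total spread
  expect_equal(sum(bp$samples^2), sum(bp$taxa^2), tolerance = 1e-9)

  # identical samples land on identical coordinates
  m2 <- cbind(m, s5 = m[, "s4"])
  bp2 <- logratioBiplot(m2, minAbundance = 0)
  expect_equal(bp2$samples["s5", ], bp2$samples["s4", ],
               tolerance = 1e-9)

  # oracle equivalence across random instances
  set.seed(405)
  for (i in 1:100) {
    mm <- matrix(rpois(7 * 5, 30) + 1, nrow = 7)
    dimnames(mm) <- list(paste0("t", 1:7), paste0("s", 1:5))
    bb <- logratioBiplot(mm, minAbundance = 0)
    pp <- sweep(mm + 0.5, 2, colSums(mm) + 0.5 * nrow(mm), "/")
    cc <- t(apply(log(pp), 2, function(v) v - mean(v)))
    zz <- sweep(cc, 2, colMeans(cc), "-")
    rec <- bb$samples %*% t(bb$taxa)
    expect_equal(sqrt(sum((zz - rec)^2)), oracleRank2Error(zz),
                 tolerance = 1e-8)
  }

  # abundance floor: everything below 0.5% vanishes, few taxa error
  expect_error(logratioBiplot(matrix(c(1, 1, 1, 1), 2,
                                     dimnames = list(c("a", "b"),
                                                     c("x", "y"))),
                              minAbundance = 60), "retained")
})

test_that("donor identity dominates Bray-Curtis clustering of synthetic milk", {
  skip_if_not_installed("mclust")
  sim <- simulateStudy(studyDesign(nDonors = 6,
                                   donorEffectConcentration = 3),
                       seed = 21)
  meta <- sampleMeta(sim$experiment)
  dec <- decontaminate(sim$experiment)$experiment
  samp <- dec[, meta$sample_id[meta$role == "sample"]]
  cl <- stats::cutree(hclustComplete(brayCurtisMatrix(samp)), k = 6)
  ari <- mclust::adjustedRandIndex(cl, sampleMeta(samp)$donor)
  expect_gt(ari, 0.9)
})
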