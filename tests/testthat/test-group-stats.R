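test_that("Type II ANOVA handles degenerate and balanced layouts", {
  # two identical groups: no between-group variance at all
  a <- anovaTypeII(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)

  # balanced two-factor design: Type II coincides with sequential SS
  set.seed(7)
  kit <- rep(c("A", "B", "C", "D"), each = 4)
  milk <- rep(c("WM", "SM"), 8)
  y <- rnorm(16) + (kit == "B")
  t2 <- anovaTypeII(y, data.frame(kit = kit, milk = milk))
  t1 <- anova(lm(y ~ kit + milk))
  expect_equal(t2$statistic[t2$factor == "kit"], t1["kit", "F value"])
  expect_equal(t2$statistic[t2$factor == "milk"], t1["milk", "F value"])
  expect_equal(t2$p_value[t2$factor == "kit"], t1["kit", "Pr(>F)"])

  expect_error(anovaTypeII(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("Tukey HSD collapses to the two-sample t-test at k = 2", {
  g <- rep(c("A", "B"), each = 6)
  set.seed(8)
  y <- rnorm(12) + (g == "B") * 0.8
  tk <- tukeyHsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(tk$diff, unname(diff(tapply(y, g, mean))))

  same <- tukeyHsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$diff, rep(0, 3))
  expect_equal(same$lwr, -same$upr)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    q <- benjaminiHochberg(p)
    expect_equal(q, oracleBH(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # ordering preserved
  }
})

test_that("repeatability R-squared matches hand computation and is affine-invariant", {
  expect_equal(repeatabilityR2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(repeatabilityR2(c(1, 2, 3), 2 * c(1, 2, 3) + 7), 1)
  expect_equal(repeatabilityR2(c(1, 2, 3), c(1, 3, 2)), 0.25)
  d1 <- c(4, 9, 1, 6, 3)
  d2 <- c(5, 7, 2, 8, 2)
  expect_equal(repeatabilityR2(d1, d2), repeatabilityR2(d2, d1))
  expect_equal(repeatabilityR2(d1, d2),
               repeatabilityR2(3 * d1 - 2, 0.5 * d2 + 10))
  expect_error(repeatabilityR2(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(repeatabilityR2(c(1, 2), c(2, 1)), "at least 3")
})

test_that("replicate-day totals drive the per-cell repeatability table", {
  set.seed(10)
  sim <- simulateStudy(studyDesign(nDonors = 3), seed = 31)
  rt <- repeatabilityTable(sim$experiment)
  expect_equal(nrow(rt), 8)  # 4 kits x 2 milks
  expect_true(all(rt$r2 >= 0 & rt$r2 <= 1))
  # manual recomputation for one cell
  meta <- sampleMeta(sim$experiment)
  m <- counts(sim$experiment)
  s1 <- meta$sample_id[meta$role == "sample" & meta$kit == "B" &
                         meta$milk == "WM" & meta$replicate == 1]
  s2 <- meta$sample_id[meta$role == "sample" & meta$kit == "B" &
                         meta$milk == "WM" & meta$replicate == 2]
  r2 <- cor(rowSums(m[, s1]), rowSums(m[, s2]))^2
  expect_equal(rt$r2[rt$kit == "B" & rt$milk == "WM"], r2)
})

test_that("taxa collapse to ranks with an unassigned pool", {
  m <- matrix(c(5L, 3L, 2L), ncol = 1,
              dimnames = list(c("o1", "o2", "o3"), "S1"))
  tx <- c(o1 = "k__Bacteria; g__Staphylococcus",
          o2 = "k__Bacteria; g__Staphylococcus",
          o3 = "k__Bacteria; g__")
  out <- collapseByRank(m, "genus", taxonomy = tx)
  expect_equal(out["Staphylococcus", "S1"], 8)
  expect_equal(out["unassigned", "S1"], 2)
})

test_that("differential abundance is null on flat tables and finds planted effects", {
  # a taxon with identical counts in every sample cannot be significant
  flat <- matrix(rep(c(50L, 100L), each = 16), nrow = 2, byrow = TRUE)
  ex <- taxonExperiment(flat, kit = rep(c("A", "B", "C", "D"), 4),
                        milk = rep(c("WM", "SM"), 8))
  res <- diffAbundance(ex, prevalenceFloor = 0)
  expect_true(all(res$p_value > 0.99))
  expect_true(all(res$q_value > 0.99))

  # an 8-fold kit effect on 3 of 40 taxa is recovered at q < 0.05
  set.seed(11)
  ex2 <- dmTable(boost = c(5, 12, 20))
  res2 <- diffAbundance(ex2)
  hits <- res2$taxon[res2$factor == "kit" & !is.na(res2$q_value) &
                       res2$q_value < 0.05]
  expect_true(all(c("taxon05", "taxon12", "taxon20") %in% hits))

  # the negative-binomial route agrees on the planted effects
  res3 <- diffAbundance(ex2, model = "negative_binomial")
  hits3 <- res3$taxon[res3$factor == "kit" & !is.na(res3$q_value) &
                        res3$q_value < 0.05]
  expect_true(all(c("taxon05", "taxon12", "taxon20") %in% hits3))
  expect_true(all(res2$model == "quasi_poisson"))
  expect_true(all(res3$model == "negative_binomial"))
})
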