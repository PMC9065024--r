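test_that("Spearman correlation matches hand-ranked values and the exact
           permutation oracle", {
  expect_equal(spearmanCorr(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearmanCorr(1:4, c(40, 30, 20, 10))$rho, -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 4
  expect_equal(spearmanCorr(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)

  set.seed(14)
  for (r in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    got <- spearmanCorr(x, y)
    expect_equal(got$rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(got$p, bruteSpearmanP(x, y), tolerance = 1e-12)
  }
  # large-n path agrees with the t approximation of cor.test
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearmanCorr(x, y)$rho, unname(ct$estimate),
               tolerance = 1e-12)

  expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "at least 3")
})

test_that("rank invariance: correlating ranks equals correlating values", {
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  a <- spearmanCorr(x, y)
  b <- spearmanCorr(rank(x), rank(y))
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("rank-sum test equals brute-force enumeration on tie-free
           samples and is symmetric", {
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(rankSumTest(c(4, 5, 6), c(1, 2, 3))$p, 0.1)

  set.seed(16)
  for (na in c(2L, 4L, 5L)) {
    for (nb in c(3L, 5L)) {
      x <- sample(100, na); y <- sample(200, nb) + 0.5
      got <- rankSumTest(x, y)
      expect_true(got$exact)
      expect_equal(got$p, bruteRankSumP(x, y), tolerance = 1e-12)
    }
  }
  # ties force the corrected normal approximation
  tied <- rankSumTest(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_false(tied$exact)
  expect_true(tied$p > 0 && tied$p <= 1)
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni adjustment caps at one and preserves ordering", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- c(0.001, 0.04, 0.2)
  expect_equal(order(bonferroni(p, 3)), order(p))
  expect_equal(bonferroni(p, 3), p.adjust(p, "bonferroni", n = 3))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("decimal acuity converts to logMAR", {
  expect_equal(decimalToLogmar(1), 0)
  expect_equal(decimalToLogmar(0.7), 0.1549, tolerance = 1e-4)
  expect_equal(decimalToLogmar(1.5), -0.1761, tolerance = 1e-4)
  expect_error(decimalToLogmar(0), "> 0")
})

test_that("cohort summary reproduces the reference report at printed
           precision", {
  s <- summarizeCohort(referenceCohort())
  getm <- function(v) s$mean[s$variable == v]
  expect_equal(round(getm("entropy_fovea"), 2), 0.41)
  expect_equal(round(getm("entropy_temporal"), 2), 0.29)
  expect_equal(round(getm("entropy_nasal"), 2), 0.26)
  expect_equal(round(getm("ez_width_um")), 1991)
  expect_equal(round(getm("crt_um")), 225)
  expect_equal(round(getm("age"), 1), 37.9)
  expect_equal(round(getm("logmar_bcva"), 2), -0.05)
  gets <- function(v) s$sd[s$variable == v]
  expect_equal(round(gets("age"), 1), 12.2)
  expect_equal(round(gets("ez_width_um")), 1187)
})

test_that("section comparisons flag fovea-vs-periphery but not
           temporal-vs-nasal", {
  cmp <- sectionComparison(referenceCohort())
  adj <- function(n) cmp$p_adjusted[cmp$comparison == n]
  expect_lt(adj("fovea_vs_temporal"), 0.05)
  expect_lt(adj("fovea_vs_nasal"), 0.05)
  expect_gt(adj("temporal_vs_nasal"), 0.05)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))

  # identical columns: z = 0 under the tie-corrected approximation
  same <- referenceCohort()
  same$entropy_temporal <- same$entropy_fovea
  same$entropy_nasal <- same$entropy_fovea
  cmp2 <- sectionComparison(same)
  expect_true(all(cmp2$p_raw == 1))

  # a huge shift attains the minimal achievable enumeration p
  shifted <- referenceCohort()
  shifted$entropy_temporal <- shifted$entropy_temporal / 1000
  cmp3 <- sectionComparison(shifted)
  expect_lt(cmp3$p_raw[cmp3$comparison == "fovea_vs_temporal"], 1e-4)
})

test_that("pooled correlations hit +/-1 for perfectly aligned or
           inverted AF profiles", {
  set.seed(18)
  ent <- lapply(1:3, function(i) flatProfile(runif(9)))
  afSame <- lapply(ent, function(e)
    afProfileFrom(profileMeans(e), centers = binCenters(e)))
  expect_equal(pooledAFCorrelation(ent, afSame)$rho, 1)
  afInv <- lapply(ent, function(e)
    afProfileFrom(1 - profileMeans(e), centers = binCenters(e)))
  expect_equal(pooledAFCorrelation(ent, afInv)$rho, -1)

  far <- lapply(ent, function(e)
    afProfileFrom(profileMeans(e), centers = binCenters(e) + 100))
  expect_error(pooledAFCorrelation(ent, far), "overlapping")
})

test_that("clinical panel returns bounded correlations and detects a
           constructed age dependence", {
  pan <- clinicalPanel(referenceCohort())
  expect_setequal(pan$variable,
                  c("age", "logmar_bcva", "ez_width_um", "crt_um"))
  expect_true(all(pan$rho >= -1 & pan$rho <= 1))

  rigged <- referenceCohort()
  rigged$entropy_fovea <- 0.2 + 0.005 * rigged$age
  pan2 <- clinicalPanel(rigged)
  expect_equal(pan2$rho[pan2$variable == "age"], 1)

  # permutation null: the reference panel correlations are unremarkable
  ref <- referenceCohort()
  set.seed(19)
  for (v in c("age", "ez_width_um", "crt_um")) {
    obs <- abs(spearmanCorr(ref$entropy_fovea, ref[[v]])$rho)
    null <- replicate(200, abs(spearmanCorr(sample(ref$entropy_fovea),
                                            ref[[v]])$rho))
    expect_gt(mean(null >= obs), 0.05)
  }
})
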