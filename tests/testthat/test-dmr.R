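test_that("probe regressions recover exact and closed-form slopes", {
  ages <- c(10, 20, 30, 40, 50)
  b <- rbind(0.1 + 0.01 * ages,          # exact linear
             rep(0.42, 5),               # constant
             c(0.1, 0.2, 0.2, 0.4, 0.5)) # hand oracle case
  mset <- toyMSet(pmin(b, 1), ages = ages)
  s <- fitProbeStatistics(mset, "beta")
  expect_equal(unname(s[1]), 0.01, tolerance = 1e-12)
  expect_equal(unname(s[2]), 0, tolerance = 1e-12)
  x <- ages; y <- b[3, ]
  beta_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(s[3]), beta_hand, tolerance = 1e-12)

  # t-statistic agrees with lm()
  st <- fitProbeStatistics(mset, "t")
  lt <- summary(lm(y ~ x))$coefficients["x", "t value"]
  expect_equal(unname(st[3]), lt, tolerance = 1e-9)

  expect_error(fitProbeStatistics(toyMSet(b, ages = rep(5, 5))),
               "zero variance")
})

test_that("missing-data handling excludes heavily missing probes", {
  set.seed(1)
  b <- matrix(runif(50, 0.3, 0.7), 5, 10)
  b[1, 1:3] <- NA          # 30% missing -> excluded
  b[2, 1] <- NA            # 10% missing -> kept, fitted on the rest
  mset <- toyMSet(b, ages = seq(1, 50, length.out = 10))
  s <- fitProbeStatistics(mset, "beta")
  expect_true(is.na(s[1]))
  expect_false(is.na(s[2]))
})

test_that("percentile thresholds interpolate order statistics per side", {
  th <- percentileThresholds(c(1:100, -(1:100)))
  expect_equal(th@q1, 95.05)
  expect_equal(th@q2, -95.05)
  expect_equal(percentileThresholds(c(rep(7, 10), -1))@q1, 7)
  expect_error(percentileThresholds(c(1, 2, 3)), "negative")
  expect_error(percentileThresholds(-c(1, 2, 3)), "positive")
  # MAD mode uses all values, upper cut only
  thm <- percentileThresholds(1:100, mode = "mad")
  expect_equal(thm@q1, 95.05)
  expect_true(is.na(thm@q2))
})

test_that("threshold harmonization takes the least extreme cut per side", {
  a <- StatThresholds(2, -3)
  b <- StatThresholds(3, -2)
  h <- harmonizeThresholds(list(a, b))
  expect_equal(h@q1, 2)
  expect_equal(h@q2, -2)
  expect_equal(harmonizeThresholds(list(a))@q1, 2)
})

test_that("candidate detection finds maximal same-direction runs", {
  m <- toyManifest(pos = c(100, 300, 500, 700, 900))
  cl <- clusterProbes(m, 1000)
  th <- StatThresholds(1, -1)

  s <- setNames(c(2, 3, 2.5, 1.5, 2), names(m))
  cand <- detectCandidates(cl, s, th, "dmr", m)
  expect_length(cand, 1L)
  expect_equal(cand$n_probes, 5L)
  expect_equal(cand$direction, "hyper")

  # sign switch splits runs
  s2 <- setNames(c(2, 3, -2, -3, 0.5), names(m))
  cand2 <- detectCandidates(cl, s2, th, "dmr", m)
  expect_equal(cand2$direction, c("hyper", "hypo"))
  expect_equal(cand2$n_probes, c(2L, 2L))

  # an interior failing probe leaves only length-1 runs
  s3 <- setNames(c(2, 0.5, 2, 0.5, 2), names(m))
  expect_length(detectCandidates(cl, s3, th, "dmr", m), 0L)

  # exactly at the cut fails (strict inequality)
  s4 <- setNames(c(1, 1, 1, 1, 1), names(m))
  expect_length(detectCandidates(cl, s4, th, "dmr", m), 0L)

  # VMR mode: upper tail only
  cand5 <- detectCandidates(cl, setNames(c(2, 2, 0, 2, 2), names(m)),
                            StatThresholds(1), "vmr", m)
  expect_equal(cand5$direction, c("variable", "variable"))
})

test_that("region area is the trapezoid of |stat| over position", {
  expect_equal(regionArea(c(0, 100), stats = c(0.5, 0.7)), 60)
  expect_equal(regionArea(c(0, 100, 300), stats = c(1, 1, 1)), 300)
  expect_equal(regionArea(c(0, 100, 300), stats = c(0, 0, 0)), 0)
  expect_equal(regionArea(c(0, 100), stats = c(-0.5, 0.7)), 60)  # |.|
  expect_error(regionArea(c(100, 100), stats = c(1, 2)), "duplicate")

  skip_if_not_installed("pracma")
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    pos <- sort(sample(1:10000, n))
    s <- rnorm(n)
    expect_equal(regionArea(pos, stats = s), pracma::trapz(pos, abs(s)),
                 tolerance = 1e-9)
  }
})

test_that("empirical p counts null areas at least as large, ties included", {
  cand <- makeCandidate(c(100, 200), c(0.1, 0.1))
  mcols(cand)$area <- 10
  null <- NullAreaDistribution(as.numeric(1:20), 20L)
  expect_equal(empiricalPvalues(cand, null)$p, 11 / 20)
  mcols(cand)$area <- 21
  expect_equal(empiricalPvalues(cand, null)$p, 0)
  mcols(cand)$area <- 1
  expect_equal(empiricalPvalues(cand, null)$p, 1)
  expect_equal(empiricalPvalues(cand, null, laplace = TRUE)$p, 21 / 21)
  expect_error(empiricalPvalues(cand, NullAreaDistribution(numeric(),
                                                           integer())),
               "empty")
})

test_that("q-values are BH step-up, order preserved, monotone in sorted p", {
  expect_equal(estimateQvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(estimateQvalues(rep(1, 5)), rep(1, 5))
  expect_equal(estimateQvalues(0.2), 0.2)
  set.seed(2)
  p <- runif(50)
  q <- estimateQvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("permutation null is reproducible and identity gives observed areas", {
  set.seed(99)
  scn <- simScenario(n_probes = 400, seed = 13)
  m <- generateManifest(scn)
  sim <- generateAgeSeries(scn, m, ages = round(seq(1, 80,
                                                    length.out = 20)))
  cl <- clusterProbes(m, 1000)
  n1 <- permutationNull(sim$mset, cl, K = 5, seed = 7)
  n2 <- permutationNull(sim$mset, cl, K = 5, seed = 7)
  expect_identical(nullAreas(n1), nullAreas(n2))
  expect_equal(nSimulations(n1), 5L)

  # identity "permutation" must reproduce the observed candidate areas
  s <- fitProbeStatistics(sim$mset, "beta")
  th <- percentileThresholds(s)
  obs <- detectCandidates(cl, s, th, "dmr", m)
  nid <- permutationNull(sim$mset, cl, K = 1, seed = 1,
                         permuteFun = seq_len)
  expect_equal(sort(nullAreas(nid)), sort(regionArea(obs)),
               tolerance = 1e-12)
})

test_that("fast permutation scan agrees with detect + area on random data", {
  set.seed(31)
  for (rep in 1:10) {
    m <- randomManifest(120, n_chroms = 2, max_gap = 1500)
    cl <- clusterProbes(m, 1000)
    if (!length(cl)) next
    s <- setNames(rnorm(length(m)), names(m))
    th <- StatThresholds(0.8, -0.8)
    cand <- detectCandidates(cl, s, th, "dmr", m)
    fast <- regionscan:::.runAreas(s, regionscan:::.scanLayout(cl),
                                   start(m), 0.8, -0.8)
    expect_equal(sort(fast), sort(regionArea(cand)), tolerance = 1e-12)
  }
})

test_that("pipeline output is invariant to sample and probe input order", {
  scn <- simScenario(n_probes = 300, seed = 17)
  m <- generateManifest(scn)
  scn$planted_dmrs <- data.frame(region = selectPlantRegions(m, 2),
                                 slope = 0.004)
  sim <- generateAgeSeries(scn, m, ages = round(seq(1, 80,
                                                    length.out = 16)))
  res1 <- runDMRPipeline(sim$mset, K = 10, seed = 5)
  perm <- sample(ncol(sim$mset))
  res2 <- runDMRPipeline(sim$mset[, perm], K = 10, seed = 5)
  expect_equal(scannedRegions(res1)$area, scannedRegions(res2)$area)
  expect_equal(scannedRegions(res1)$p, scannedRegions(res2)$p)
})

test_that("power comparison behaves like the rank-test approximation", {
  pw <- powerComparison(1, 50, 50, m_single = 450000, m_region = 55003)
  expect_gte(pw["power_region"], pw["power_single"])
  same <- powerComparison(1, 50, 50, m_single = 1000, m_region = 1000)
  expect_equal(unname(same["power_single"]), unname(same["power_region"]))
  big <- powerComparison(50, 10, 10)
  expect_true(all(big > 0.999))
  expect_error(powerComparison(1, 10, 10, m_single = 0), "positive")

  # Monte-Carlo WMW oracle at d = 1, n = 50 per group, single test
  set.seed(123)
  reps <- 4000
  rej <- mean(replicate(reps, {
    x <- rnorm(50); y <- rnorm(50, 1)
    suppressWarnings(wilcox.test(x, y)$p.value) < 0.05
  }))
  approx <- powerComparison(1, 50, 50, m_single = 1, m_region = 1)
  expect_equal(unname(approx["power_single"]), rej, tolerance = 0.02)
})
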