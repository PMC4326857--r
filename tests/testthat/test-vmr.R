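test_that("MAD is the unscaled median absolute deviation", {
  b <- rbind(c(0.01, 0.02, 0.03, 0.04, 1.00),
             rep(0.5, 5),
             c(0.15, 0.2, 0.25, 0.2, 0.2))
  mset <- toyMSet(b)
  mad3 <- computeMAD(mset, colnames(mset))
  expect_equal(unname(mad3[1]), 0.01)   # devs {.02,.01,0,.01,.97}
  expect_equal(unname(mad3[2]), 0)      # constant probe
  expect_equal(unname(mad3[3]), 0.00)   # median .2, devs {.05,0,.05,0,0}
  expect_error(computeMAD(mset, colnames(mset)[1:2]), "at least 3")
})

test_that("MAD is shift invariant and scale equivariant", {
  set.seed(4)
  x <- runif(9, 0.1, 0.4)
  mad1 <- unname(computeMAD(toyMSet(rbind(x)), sprintf("S%02d", 1:9)))
  mad2 <- unname(computeMAD(toyMSet(rbind(x + 0.3)), sprintf("S%02d", 1:9)))
  mad3 <- unname(computeMAD(toyMSet(rbind(x * 2)), sprintf("S%02d", 1:9)))
  expect_equal(mad1, mad2, tolerance = 1e-15)
  expect_equal(2 * mad1, mad3, tolerance = 1e-15)
})

test_that("order-1 Burg fit matches its closed form and stays stationary", {
  # alternating series drives rho to the -1 boundary but never past it
  alt <- rep(c(1, -1), 10)
  f <- fitAR1Burg(alt)
  expect_lt(arRho(f), -0.99)
  expect_gt(arRho(f), -1)

  # closed form on a short series
  x <- c(0.3, 0.1, 0.4, 0.2, 0.6)
  xc <- x - mean(x)
  rho_hand <- 2 * sum(xc[-1] * xc[-5]) / sum(xc[-1]^2 + xc[-5]^2)
  expect_equal(arRho(fitAR1Burg(x)), rho_hand, tolerance = 1e-12)
  expect_equal(arSigma(fitAR1Burg(x)),
               sqrt((1 - rho_hand^2) * mean(xc^2)), tolerance = 1e-12)

  expect_error(fitAR1Burg(rep(2, 10)), "zero-variance")
  expect_error(fitAR1Burg(c(1, 2)), "too short")

  # |rho| < 1 on arbitrary finite inputs
  set.seed(12)
  for (rep in 1:20) {
    r <- arRho(fitAR1Burg(rnorm(sample(3:50, 1)) * 10^sample(-3:3, 1)))
    expect_lt(abs(r), 1)
  }
})

test_that("Burg recovers AR(1) coefficients and agrees with ar.burg", {
  set.seed(77)
  for (rho in c(0, 0.6)) {
    x <- if (rho == 0) rnorm(10000)
    else as.numeric(arima.sim(list(ar = rho), n = 10000))
    est <- fitAR1Burg(x)
    expect_lt(abs(arRho(est) - rho), 0.05)
    ref <- ar.burg(x, order.max = 1, aic = FALSE)
    if (rho > 0) expect_lt(abs(arRho(est) - ref$ar), 0.02)
  }
})

test_that("pooled AR(1) averages per-region fits over large regions", {
  m <- toyManifest(pos = seq(100, by = 200, length.out = 9))
  cl <- clusterProbes(m, 1000)
  mads <- setNames(exp(rnorm(9)), names(m))
  single <- poolAR1(mads, cl, min_probes = 9)
  direct <- fitAR1Burg(log(pmax(mads, 1e-6)))
  expect_equal(arRho(single), arRho(direct))
  expect_error(poolAR1(mads, cl, min_probes = 50), "min_probes")

  # recovery on a 10-region layout of 60 probes each
  set.seed(55)
  pos <- unlist(lapply(0:9, function(c) 1e6 * c + seq(1, by = 200,
                                                      length.out = 60)))
  m10 <- makeManifest(sprintf("p%03d", 1:600), "chr1", pos)
  cl10 <- clusterProbes(m10, 1000)
  expect_length(cl10, 10L)
  rho <- 0.5; sigma <- 0.3
  lm10 <- unlist(lapply(1:10, function(i)
    as.numeric(arima.sim(list(ar = rho), n = 60, sd = sigma))))
  pooled <- poolAR1(setNames(exp(lm10), names(m10)), cl10, min_probes = 50)
  expect_lt(abs(arRho(pooled) - rho), 0.05)
  expect_lt(abs(arSigma(pooled) - sigma), 0.05)
  expect_equal(pooled@n, 10L)
})

test_that("bootstrap null areas are reproducible and respect candidate rates", {
  set.seed(66)
  m <- randomManifest(400, n_chroms = 1, max_gap = 900)  # one big cluster zone
  cl <- clusterProbes(m, 1000)
  par0 <- AR1Params(rho = 0, sigma = 0.5)
  n1 <- simulateNullVMRAreas(m, cl, par0, x = 50, n_sim = 30, seed = 3)
  n2 <- simulateNullVMRAreas(m, cl, par0, x = 50, n_sim = 30, seed = 3)
  expect_identical(nullAreas(n1), nullAreas(n2))
  expect_error(simulateNullVMRAreas(m, cl, par0, x = 5, n_sim = 0), "n_sim")

  # rho = 0: landscapes are iid lognormal; compare the mean number of
  # candidate runs per simulation against a direct iid simulation oracle
  got_rate <- mean(n1@n_per_sim)
  layout <- regionscan:::.scanLayout(cl)
  set.seed(4)
  oracle <- mean(replicate(200, {
    v <- exp(rnorm(length(m), sd = 0.5))
    q1 <- quantile(v, 0.95, names = FALSE)
    length(regionscan:::.runAreas(v, layout, start(m), q1, vmr = TRUE))
  }))
  expect_equal(got_rate, oracle, tolerance = 0.35)
})

test_that("MAD percentile ratios scale with group variance", {
  set.seed(14)
  a <- setNames(runif(200, 0.01, 0.1), sprintf("p%03d", 1:200))
  expect_equal(unname(madPercentileRatio(list(g1 = a, g2 = a))[1, 2]), 1)
  r <- madPercentileRatio(list(g1 = a, g2 = 2 * a))
  expect_equal(unname(r["g2", "g1"]), 2)
  expect_error(madPercentileRatio(list(g1 = a, g2 = a * 0)), "zero")
})

test_that("VMR pipeline flags inflated groups and not homogeneous ones", {
  scn <- simScenario(n_probes = 1200, short_gap_fraction = 0.97,
                     short_gap_mean = 250, seed = 23)
  m <- generateManifest(scn)
  scn$planted_vmrs <- data.frame(
    region = selectPlantRegions(m, 4, min_probes = 12), shift = 1.5)
  sim <- generateGroupSeries(scn, m, groups = c(young = 30, old = 30))
  res <- runVMRPipeline(sim$mset, sim$group_samples$old,
                        harmonize_with = list(sim$group_samples$young),
                        K = 50, min_probes = 40, seed = 9)
  sig <- significantRegions(res)
  expect_gte(sum(countOverlaps(sim$truth, sig) > 0), 3L)
  expect_true(all(sig$direction == "variable"))
  # the uninflated group stays quiet
  resy <- runVMRPipeline(sim$mset, sim$group_samples$young,
                         harmonize_with = list(sim$group_samples$old),
                         K = 50, min_probes = 40, seed = 9)
  expect_lte(length(significantRegions(resy)), 1L)
})
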