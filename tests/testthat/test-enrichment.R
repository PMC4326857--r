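test_that("hypergeometric upper tail matches closed forms and enumeration", {
  expect_equal(hypergeomP(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeomP(0, 3, 4, 8), 1)
  expect_equal(hypergeomP(2, 3, 4, 8), enumHyperP(2, 3, 4, 8))
  expect_error(hypergeomP(5, 3, 4, 8), "invalid")
  expect_error(hypergeomP(2, 9, 4, 8), "invalid")

  # random small-universe spot checks against full enumeration
  set.seed(19)
  for (rep in 1:20) {
    N <- sample(4:10, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomP(k, n, K, N), enumHyperP(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p is monotone non-increasing in the overlap", {
  p <- vapply(0:5, function(k) hypergeomP(k, 5, 6, 20), 0)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("probe-weighted gene enrichment counts probes, not genes", {
  m <- toyManifest(pos = c(100, 300, 500, 2000, 2300, 4000, 4300, 6000,
                           6200, 8000, 8100),
                   genes = c("A", "A", "A", "B", "B", "C", "C", "D", "D",
                             "E", "E"))
  bg <- clusterProbes(m, 1000)
  gs <- list(name = "set", genes = c("a", "B"))   # case-insensitive
  # query = the cluster of gene B probes (all its probes in the set)
  query <- bg[start(bg) == 2000]
  res <- probeWeightedGeneEnrichment(query, gs, bg, m)
  expect_equal(res$background_N, 11L)
  expect_equal(res$success_K, 5L)   # 3 A-probes + 2 B-probes
  expect_equal(res$draw_n, 2L)
  expect_equal(res$overlap_k, 2L)
  expect_equal(res$p, hypergeomP(2, 2, 5, 11))
  expect_equal(res$genes_overlap, 1L)

  # query = background is degenerate: k = K, n = N, p = 1
  res2 <- probeWeightedGeneEnrichment(bg, gs, bg, m)
  expect_equal(res2$p, 1)

  # gene set absent from the background
  expect_warning(
    res3 <- probeWeightedGeneEnrichment(query,
                                        list(name = "x", genes = "ZZZ"),
                                        bg, m),
    "no probes")
  expect_equal(res3$p, 1)
})

test_that("island-category enrichment flags a pure-island query", {
  set.seed(30)
  m <- toyManifest(pos = seq(100, by = 300, length.out = 40),
                   island_category = rep(c("island", "open_sea"), 20))
  bg <- clusterProbes(m, 1000)
  stats <- setNames(rep(1, 40), names(m))
  stats[m$island_category != "island"] <- 0
  query <- detectCandidates(bg, stats, StatThresholds(0.5), "vmr", m)
  res <- categoryEnrichment(query, bg, m)
  island_p <- res$p[res$category == "island"]
  expect_equal(island_p, min(res$p, na.rm = TRUE))
  # categories with no background probes are skipped with NA
  expect_true(all(is.na(res$p[res$success_K == 0])))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("interval overlap uses half-open boundary semantics", {
  # region [100,200) and interval [199,300) share base 199 (0-based)
  r <- GRanges("chr1", IRanges(101, 200))
  expect_equal(intervalOverlapCount(r, GRanges("chr1", IRanges(200, 300))),
               1L)
  # [100,200) vs [200,300): adjacent, no overlap
  expect_equal(intervalOverlapCount(r, GRanges("chr1", IRanges(201, 300))),
               0L)
  expect_equal(intervalOverlapCount(r, GRanges("chr2", IRanges(1, 1e6))),
               0L)

  set.seed(44)
  rr <- GRanges("chr1", IRanges(sample(1:5000, 100), width = 50))
  ii <- GRanges("chr1", IRanges(sample(1:5000, 80), width = 30))
  expect_equal(intervalOverlapCount(rr, ii),
               bruteOverlapCount(rep("chr1", 100), start(rr), end(rr),
                                 rep("chr1", 80), start(ii), end(ii)))
})

test_that("hot-spot enrichment degenerates to p = 1 at both extremes", {
  m <- toyManifest()
  bg <- clusterProbes(m, 1000)
  all_cover <- GRanges("chr1", IRanges(1, 1e7))
  expect_equal(dnaseEnrichment(bg, bg, all_cover)$p, 1)
  none <- GRanges("chr2", IRanges(1, 10))
  expect_equal(dnaseEnrichment(bg, bg, none)$p, 1)
})

test_that("multi-list overlap simulation detects a forced common core", {
  set.seed(50)
  pos <- seq(1000, by = 5000, length.out = 200)
  m <- makeManifest(sprintf("p%03d", seq_along(pos) * 2 - 1), "chr1",
                    pos)
  # build a 100-region background from pairs
  m2 <- makeManifest(sprintf("q%03d", 1:400), "chr1",
                     sort(c(pos, pos + 100)))
  bg <- clusterProbes(m2, 200)
  expect_length(bg, 200L)
  bg <- bg[1:100]

  core <- bg[1:10]
  lists <- lapply(1:3, function(i)
    c(core, bg[sample(11:100, 10)]))
  res <- multiListOverlapP(lists, bg, reps = 1e4, seed = 2)
  expect_gte(res$observed, 10)
  expect_lt(res$p, 0.01)

  # three disjoint lists: observed overlap 0, never exceeded
  disj <- list(bg[1:10], bg[11:20], bg[21:30])
  res0 <- multiListOverlapP(disj, bg, reps = 1000, seed = 3)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
  # literal (strict) reading can never reject a full overlap
  resl <- multiListOverlapP(list(bg, bg, bg), bg, reps = 500, seed = 4,
                            direction = "literal")
  expect_equal(resl$p, 0)   # null never strictly exceeds N
  expect_warning(multiListOverlapP(disj, bg, reps = 50, seed = 1),
                 "repetitions")
})
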