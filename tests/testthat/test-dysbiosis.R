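test_that("median split uses strict inequality for the high group", {
  # worm counts spanning 3-45 with median 21: the high group starts at 22
  counts <- setNames(c(3, 10, 21, 21, 22, 30, 45), paste0("h", 1:7))
  sp <- splitByMedian(counts)
  expect_equal(sp@median, 21)
  expect_equal(min(counts[sp@high]), 22)
  expect_equal(range(counts[sp@low]), c(3, 21))

  sp2 <- splitByMedian(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(sp2@median, 2.5)
  expect_setequal(sp2@high, c("c", "d"))
  expect_setequal(sp2@low, c("a", "b"))
  expect_error(splitByMedian(c(a = 5, b = 5)), "distinct")
})

test_that("a median split of distinct values is near-balanced", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(1000, 21)
    names(v) <- paste0("h", seq_along(v))
    sp <- splitByMedian(v)
    expect_lte(abs(length(sp@high) - length(sp@low)), 1)
  }
})

test_that("volcano statistics match hand computation and the identity case", {
  m <- cbind(h1 = c(10, 30, 5), h2 = c(12, 28, 5), h3 = c(9, 33, 5),
             l1 = c(11, 29, 5), l2 = c(10, 31, 5), l3 = c(10, 30, 5))
  rownames(m) <- c("t1", "t2", "t3")
  sp <- new("BurdenSplit", median = 1, high = c("h1", "h2", "h3"),
            low = c("l1", "l2", "l3"))
  v <- volcanoTable(burdenDysbiosis(m, sp))
  rel <- sweep(m, 2, colSums(m), "/")
  for (tx in rownames(m)) {
    o <- oracleTPooled(rel[tx, 1:3], rel[tx, 4:6])
    expect_equal(v$t[v$taxon == tx], o$t, tolerance = 1e-10)
    expect_equal(v$P[v$taxon == tx], o$P, tolerance = 1e-10)
    expect_equal(v$log2_fold_change[v$taxon == tx],
                 log2(mean(rel[tx, 1:3]) / mean(rel[tx, 4:6])),
                 tolerance = 1e-12)
  }

  # equal group compositions: zero fold change, P = 1
  me <- cbind(h1 = c(4, 6), h2 = c(4, 6), l1 = c(4, 6), l2 = c(4, 6))
  rownames(me) <- c("x", "y")
  spe <- new("BurdenSplit", median = 1, high = c("h1", "h2"),
             low = c("l1", "l2"))
  ve <- volcanoTable(burdenDysbiosis(me, spe))
  expect_equal(ve$log2_fold_change, c(0, 0))
  expect_equal(ve$P, c(1, 1))
})

test_that("spiked responder taxa are recovered with sign and significance", {
  cfg <- metacomConfig(nHosts = 40, sites = c(gut = 40), nTaxa = 150,
                       determinism = 0.8, burdenEffect = log(10) / 2,
                       nResponders = 6, librarySizeMean = 5000, seed = 33)
  sim <- simulateMetacommunity(cfg)
  m <- counts(sim$experiment)
  md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  split <- splitByMedian(setNames(md$nematode_count, md$sample_id))
  v <- volcanoTable(burdenDysbiosis(m, split))
  eff <- sim$truth@responderEffects$gut
  hits <- v[v$taxon %in% names(eff), ]
  expect_gt(nrow(hits), 0)
  signOk <- sign(hits$log2_fold_change) == sign(eff[hits$taxon])
  expect_gt(mean(signOk), 0.8)
  expect_gt(mean(hits$P < 0.05), 0.5)
})

test_that("every taxon is volcano-analysed, gained, lost or absent exactly once", {
  sim <- simulateMetacommunity(smallConfig(seed = 17))
  m <- counts(sim$experiment)
  md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  split <- splitByMedian(setNames(md$nematode_count, md$sample_id))
  p <- partitionCoreSatellite(m)
  rep <- burdenDysbiosis(m, split, p)
  v <- volcanoTable(rep); g <- gainedTaxa(rep); l <- lostTaxa(rep)
  ids <- c(v$taxon, g$taxon, l$taxon)
  expect_false(anyDuplicated(ids) > 0)
  # independent accounting of one-group-only taxa
  hi <- rowSums(m[, split@high, drop = FALSE]) > 0
  lo <- rowSums(m[, split@low, drop = FALSE]) > 0
  expect_equal(nrow(g) + nrow(l), sum(xor(hi, lo)))
  expect_equal(length(ids), sum(hi | lo))
  # gained/lost carry partition labels and are rank-sorted
  expect_true(all(c(g$fraction, l$fraction) %in% c("core", "satellite")))
  expect_false(is.unsorted(rev(g$mean_rel_abundance)))
})

test_that("a satellite taxon present only under low burden is reported lost", {
  m <- toyTable(6, 10, lambda = 5, seed = 18)
  sp <- new("BurdenSplit", median = 1, high = colnames(m)[1:5],
            low = colnames(m)[6:10])
  m["t01", ] <- 0
  m["t01", 7] <- 3  # single low-burden sample
  p <- partitionCoreSatellite(m)
  rep <- burdenDysbiosis(m, sp, p)
  l <- lostTaxa(rep)
  expect_true("t01" %in% l$taxon)
  expect_equal(l$fraction[l$taxon == "t01"], "satellite")
})
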