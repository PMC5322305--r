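test_that("identical communities over a large pool are deterministically similar", {
  G <- 200
  a <- rep(c(TRUE, FALSE), each = G / 2)
  s <- srcPair(a, a, nRand = 1000, seed = 1)
  expect_gt(s, 0.95)
})

test_that("disjoint sparse communities score at the zero-overlap tie value", {
  # with observed shared = 0 no null draw can fall below it, so S_RC is
  # half the null probability of zero overlap (here ~0.488, from the
  # hypergeometric oracle), not a small tail value
  G <- 1000
  a <- b <- rep(FALSE, G)
  a[1:5] <- TRUE; b[6:10] <- TRUE
  s <- srcPair(a, b, nRand = 2000, seed = 2)
  exact <- oracleSrcHyper(G, 5, 5, 0)
  expect_lt(abs(s - exact), 3 * sqrt(0.25 / 2000) + 1e-3)
  # overlapping pools are needed for deterministic dissimilarity: two
  # communities sharing far less than chance under a concentrated pool
  w <- c(rep(50, 10), rep(1, 10))
  a2 <- b2 <- rep(FALSE, 20)
  a2[c(1:5, 11)] <- TRUE   # avoid the other's taxa despite heavy weights
  b2[c(6:10, 12)] <- TRUE
  expect_lt(srcPair(a2, b2, w, nRand = 1000, seed = 3), 0.05)
})

test_that("Monte Carlo S_RC converges to the exact enumeration value", {
  G <- 4
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)   # observed shared = 1
  exact <- oracleSrcEnum(a, b, G)
  expect_equal(exact, oracleSrcHyper(G, 2, 2, 1), tolerance = 1e-12)
  nRand <- 20000
  s <- srcPair(a, b, nRand = nRand, seed = 3)
  se <- sqrt(exact * (1 - exact) / nRand)  # binomial bound on the MC error
  expect_lt(abs(s - exact), 3 * se + 3 / nRand)
})

test_that("S_RC is symmetric, bounded and seed-reproducible", {
  set.seed(4)
  G <- 50
  w <- runif(G, 0.5, 2)
  for (i in 1:5) {
    a <- runif(G) < 0.3; b <- runif(G) < 0.4
    if (!any(a) || !any(b)) next
    s1 <- srcPair(a, b, w, nRand = 500, seed = i)
    s2 <- srcPair(b, a, w, nRand = 500, seed = i)
    expect_true(s1 >= 0 && s1 <= 1)
    # order of arguments only changes the Monte Carlo draws, not the target
    expect_lt(abs(s1 - s2), 0.15)
    expect_equal(s1, srcPair(a, b, w, nRand = 500, seed = i))
  }
  expect_error(srcPair(rep(TRUE, 5), rep(TRUE, 5), rep(0, 5)), "drawable")
})

test_that("matrix Raup-Crick is symmetric, reproducible and sane on clones", {
  m <- cbind(a = c(5, 5, 0, 0, 2), b = c(4, 6, 0, 0, 1), c = c(5, 4, 0, 0, 2),
             d = c(0, 0, 7, 7, 0))
  rownames(m) <- paste0("t", 1:5)
  rc1 <- raupCrick(m, nRand = 500, seed = 9)
  rc2 <- raupCrick(m, nRand = 500, seed = 9)
  expect_identical(rc1@values, rc2@values)
  v <- rc1@values
  expect_equal(v[upper.tri(v)], t(v)[upper.tri(v)])
  expect_true(all(is.na(diag(v))))
  # near-identical trio scores similar, the disjoint sample dissimilar
  expect_gt(v["a", "b"], v["a", "d"])
})

test_that("assembly classes and histogram partition all pairs", {
  v <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(v) <- NA
  rc <- new("RaupCrickResult", values = v, nRand = 100L,
            nullModel = "equal_weight", seed = 1L)
  cl <- classifyAssembly(rc)
  expect_equal(unname(cl$percentages[["det_similar"]]), 100)
  expect_equal(sum(cl$percentages), 100, tolerance = 1e-9)
  expect_equal(sum(cl$histogram$count), nrow(cl$classes))
})

test_that("generated determinism gradient appears in assembly classes", {
  # fully templated site with the usual core/satellite occupancy contrast
  cfgHi <- metacomConfig(nHosts = 16, sites = c(gut = 16), nTaxa = 80,
                         determinism = 1,
                         librarySizeMean = 3000, burdenEffect = 0, seed = 21)
  simHi <- simulateMetacommunity(cfgHi)
  rcHi <- raupCrick(simHi$experiment, site = "gut", nRand = 500, seed = 1)
  clHi <- classifyAssembly(rcHi)$percentages
  expect_gt(clHi[["det_similar"]], clHi[["stochastic"]])

  # no template: the satellite fraction assembles stochastically
  cfgLo <- metacomConfig(nHosts = 16, sites = c(gut = 16), nTaxa = 60,
                         determinism = 0, librarySizeMean = 3000,
                         burdenEffect = 0, seed = 22)
  simLo <- simulateMetacommunity(cfgLo)
  satTx <- satelliteTaxa(simLo$truth, "gut")
  rcLo <- raupCrick(simLo$experiment, site = "gut", nRand = 500, seed = 2,
                    taxa = satTx)
  clLo <- classifyAssembly(rcLo)$percentages
  expect_gt(clLo[["stochastic"]], clLo[["det_similar"]])
})
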