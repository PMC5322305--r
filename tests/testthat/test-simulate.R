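test_that("generator is reproducible under a fixed seed and varies across seeds", {
  s1 <- simulateMetacommunity(smallConfig(seed = 1))
  s2 <- simulateMetacommunity(smallConfig(seed = 1))
  s3 <- simulateMetacommunity(smallConfig(seed = 2))
  expect_identical(counts(s1$experiment), counts(s2$experiment))
  expect_identical(s1$hosts, s2$hosts)
  expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("counts are non-negative integers with unique identifiers", {
  sim <- simulateMetacommunity(miniPipelineConfig())
  m <- counts(sim$experiment)
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  expect_false(anyDuplicated(rownames(m)) > 0)
  expect_false(anyDuplicated(colnames(m)) > 0)
  expect_setequal(unique(SummarizedExperiment::colData(sim$experiment)$site),
                  c("stomach", "cloaca", "faeces"))
})

test_that("host metadata obeys the colony's demographic structure", {
  cfg <- metacomConfig(nHosts = 40, seed = 3)
  h <- simulateHostMetadata(cfg)
  expect_equal(nrow(h), 40)
  expect_true(all(h$nematode_count >= 3 & h$nematode_count <= 45))
  expect_setequal(unique(h$sex), c("male", "female"))
  expect_true(all(h$age_years >= 3 & h$age_years <= 17))
  expect_true(all(h$chicks_fledged %in% 1:3))
  expect_true(all(h$phenology %in% c("early", "late")))

  h1 <- simulateHostMetadata(metacomConfig(nHosts = 1, sites = c(gut = 1)))
  expect_equal(nrow(h1), 1)
  expect_error(metacomConfig(nHosts = 0, sites = c(gut = 1)), "positive")
})

test_that("sex difference in burden matches the clamped-normal moments", {
  # oracle: expected value of round(Normal) clamped to [3, 45], by
  # direct integration of the censored normal
  clampedMean <- function(mu, sd) {
    a <- (3 - mu) / sd; b <- (45 - mu) / sd
    3 * pnorm(a) + 45 * (1 - pnorm(b)) +
      mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b))
  }
  expDiff <- clampedMean(28, 14.8) - clampedMean(20, 8.1)
  h <- simulateHostMetadata(metacomConfig(nHosts = 10000, sites = c(g = 10),
                                          seed = 11))
  m <- h$nematode_count[h$sex == "male"]
  f <- h$nematode_count[h$sex == "female"]
  obsDiff <- mean(m) - mean(f)
  se <- sqrt(var(m) / length(m) + var(f) / length(f))
  expect_lt(abs(obsDiff - expDiff), 3 * se)
  expect_gt(obsDiff, 5)  # males carry the heavier burdens
})

test_that("occupancy increases with log abundance in generated tables", {
  sim <- simulateMetacommunity(smallConfig(seed = 5))
  reg <- occupancyAbundanceRegression(counts(sim$experiment))
  expect_gt(reg$slope, 0)
  expect_lt(reg$P, 0.05)
})

test_that("full determinism without noise yields identical local communities", {
  cfg <- metacomConfig(nHosts = 8, sites = c(gut = 8), nTaxa = 40,
                       determinism = 1, noise = FALSE, fracSingle = 0,
                       librarySizeMean = 2000, seed = 4)
  sim <- simulateMetacommunity(cfg)
  pres <- counts(sim$experiment) > 0
  expect_true(all(pres == pres[, 1]))
})

test_that("zero burden effect leaves responder fold changes unremarkable", {
  cfg <- smallConfig(seed = 8, n = 30, nTaxa = 120, burdenEffect = 0)
  sim <- simulateMetacommunity(cfg)
  m <- counts(sim$experiment)
  md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  split <- splitByMedian(setNames(md$nematode_count, md$sample_id))
  v <- volcanoTable(burdenDysbiosis(m, split))
  resp <- names(sim$truth@responderEffects$gut)
  isResp <- v$taxon %in% resp
  expect_gt(sum(isResp), 0)
  w <- wilcox.test(abs(v$log2_fold_change[isResp]),
                   abs(v$log2_fold_change[!isResp]))
  expect_gt(w$p.value, 0.01)
})

test_that("core taxa are overdispersed and Poisson satellites are not", {
  sim <- simulateMetacommunity(smallConfig(seed = 6, n = 35, nTaxa = 150))
  m <- counts(sim$experiment)
  disp <- apply(m, 1, dispersionIndex)
  tr <- sim$truth
  core <- intersect(coreTaxa(tr, "gut"), rownames(m))
  occ <- rowSums(m > 0)
  sat <- intersect(satelliteTaxa(tr, "gut"), rownames(m))
  satPois <- sat[occ[sat] > 1]  # exclude the single-sample seeded taxa
  expect_gt(mean(disp[core], na.rm = TRUE), 5)
  di <- disp[satPois][!is.na(disp[satPois])]
  se <- sd(di) / sqrt(length(di))
  expect_lt(abs(mean(di) - 1), 3 * se + 0.05)
  # truth sets partition the site's taxa
  expect_length(intersect(core, sat), 0)
})
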