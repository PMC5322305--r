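test_that("total inertia equals the table chi-square over its grand total", {
  m <- toyTable(9, 15, lambda = 6, seed = 10)
  X <- data.frame(v = rnorm(15))
  fit <- ccaFit(m, X)
  cs <- suppressWarnings(chisq.test(t(m))$statistic)
  expect_equal(fit@totalInertia, unname(cs) / sum(m), tolerance = 1e-9)
})

test_that("constrained eigenvalues match the explicit projection oracle", {
  # 4 samples x 3 taxa toy
  Y <- matrix(c(10, 2, 1,
                8, 3, 2,
                1, 9, 4,
                2, 7, 6), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  X <- cbind(x1 = c(1, 1, 0, 0), x2 = c(0.2, -0.1, 0.3, 0.5))
  fit <- ccaFit(t(Y), X)
  ev <- oracleCcaEig(Y, X)
  expect_equal(fit@eig, ev, tolerance = 1e-8)
  expect_lte(fit@constrainedInertia, fit@totalInertia + 1e-12)
})

test_that("constrained eigenvalues match vegan on random tables", {
  for (seed in c(11, 12)) {
    m <- toyTable(12, 18, lambda = 5, seed = seed)
    X <- data.frame(a = rnorm(18), b = rep(c("u", "v"), 9))
    fit <- ccaFit(m, X)
    veg <- vegan::cca(t(m) ~ a + b, data = X)
    expect_equal(fit@totalInertia, veg$tot.chi, tolerance = 1e-10)
    expect_equal(fit@eig, unname(veg$CCA$eig), tolerance = 1e-8)
  }
})

test_that("a binary variable separating disjoint blocks explains almost everything", {
  m <- cbind(a1 = c(9, 8, 0, 0), a2 = c(10, 7, 0, 0), a3 = c(8, 9, 0, 0),
             b1 = c(0, 0, 6, 5), b2 = c(0, 0, 5, 7), b3 = c(0, 0, 7, 6))
  rownames(m) <- paste0("t", 1:4)
  fit <- ccaFit(m, data.frame(block = rep(c(0, 1), each = 3)))
  expect_gt(fit@constrainedInertia / fit@totalInertia, 0.95)
})

test_that("adding variables never decreases constrained inertia", {
  m <- toyTable(10, 16, lambda = 6, seed = 13)
  set.seed(13)
  X <- data.frame(a = rnorm(16), b = rnorm(16), c = rnorm(16))
  c1 <- ccaFit(m, X[, "a", drop = FALSE])@constrainedInertia
  c2 <- ccaFit(m, X[, c("a", "b")])@constrainedInertia
  c3 <- ccaFit(m, X)@constrainedInertia
  expect_lte(c1, c2 + 1e-12)
  expect_lte(c2, c3 + 1e-12)
  expect_lte(c3, ccaFit(m, X)@totalInertia + 1e-12)
})

test_that("forward selection admits a duplicated signal only once", {
  set.seed(14)
  m <- toyTable(8, 20, lambda = 4, seed = 14)
  sig <- rep(c(0, 1), each = 10)
  m[1, sig == 1] <- m[1, sig == 1] + 30  # strong association
  X <- data.frame(signal = sig, copy = sig)
  fs <- forwardSelect(m, X, nPerm = 199, alpha = 0.05, seed = 1)
  expect_equal(nrow(fs@selection), 1)
  expect_true(fs@selection$variable %in% c("signal", "copy"))
  expect_equal(sum(fs@selection$pct_total) + fs@undetermined, 100,
               tolerance = 1e-9)
})

test_that("burden explains more variation where its configured effect is larger", {
  mk <- function(effect, seed) {
    cfg <- metacomConfig(nHosts = 30, sites = c(gut = 30), nTaxa = 80,
                         determinism = 0.7, burdenEffect = effect,
                         nResponders = 6, librarySizeMean = 3000,
                         seed = seed)
    sim <- simulateMetacommunity(cfg)
    md <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
    vars <- data.frame(age = md$age_years, sex = md$sex,
                       burden = md$nematode_count, phenology = md$phenology)
    forwardSelect(counts(sim$experiment), vars, nPerm = 199, seed = 5)
  }
  upstream <- mk(0.2, seed = 31)    # weak effect (infection-site analogue)
  downstream <- mk(1.5, seed = 31)  # strong effect (faecal analogue)
  selDown <- downstream@selection
  expect_true("burden" %in% selDown$variable)
  pctUp <- upstream@selection$pct_total[upstream@selection$variable == "burden"]
  pctDown <- selDown$pct_total[selDown$variable == "burden"]
  expect_gt(pctDown, if (length(pctUp)) pctUp else 0)
})

test_that("marginal mode reports every candidate with percentages summing with undetermined to 100", {
  m <- toyTable(8, 14, lambda = 5, seed = 15)
  set.seed(15)
  X <- data.frame(a = rnorm(14), b = rep(c("u", "v"), 7))
  mg <- forwardSelect(m, X, nPerm = 99, seed = 2, mode = "marginal")
  expect_setequal(mg@selection$variable, c("a", "b"))
  expect_equal(sum(mg@selection$pct_total) + mg@undetermined, 100,
               tolerance = 1e-9)
})
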