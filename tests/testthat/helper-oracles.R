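# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, sharing no code with the package.

# core/satellite labels by explicit loops and the chi-squared dispersion test
oraclePartition <- function(m, tail = 0.025) {
  n <- ncol(m)
  crit <- qchisq(1 - tail, df = n - 1)
  labels <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    occ <- sum(x > 0)
    mu <- sum(x) / n
    v <- sum((x - mu)^2) / (n - 1)
    if (occ == 1) labels[i] <- "satellite"
    else if ((n - 1) * (v / mu) <= crit) labels[i] <- "satellite"
    else labels[i] <- "core"
  }
  setNames(labels, rownames(m))
}

# exact Raup-Crick probability for an equal-weight pool by exhaustive
# enumeration of all C(G, ra) x C(G, rb) subset draws
oracleSrcEnum <- function(a, b, G) {
  ra <- sum(a); rb <- sum(b); obs <- sum(a & b)
  subsA <- combn(G, ra, simplify = FALSE)
  subsB <- combn(G, rb, simplify = FALSE)
  less <- 0; equal <- 0; total <- 0
  for (sa in subsA) for (sb in subsB) {
    sh <- length(intersect(sa, sb))
    if (sh < obs) less <- less + 1 else if (sh == obs) equal <- equal + 1
    total <- total + 1
  }
  (less + 0.5 * equal) / total
}

# same tail probability in closed form: shared richness of two
# independent uniform subsets is hypergeometric
oracleSrcHyper <- function(G, ra, rb, obs) {
  phyper(obs - 1, ra, G - ra, rb) + 0.5 * dhyper(obs, ra, G - ra, rb)
}

# ANOSIM R and exact permutation P by exhaustive relabelling (2 groups)
oracleAnosim <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(d[lower.tri(d)])
  rk <- rk + t(rk)
  Rstat <- function(g) {
    bw <- wi <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (g[i] == g[j]) wi <- c(wi, rk[i, j]) else bw <- c(bw, rk[i, j])
    }
    (mean(bw) - mean(wi)) / (n * (n - 1) / 4)
  }
  obs <- Rstat(groups)
  lev <- unique(groups)
  n1 <- sum(groups == lev[1])
  stats <- apply(combn(n, n1), 2, function(idx) {
    g <- rep(lev[2], n); g[idx] <- lev[1]; Rstat(g)
  })
  list(R = obs, P = mean(stats >= obs - 1e-12), stats = stats)
}

# SIMPER contributions by explicit double loop over between-group pairs
oracleSimper <- function(rel, g1, g2) {
  contrib <- numeric(nrow(rel))
  np <- 0
  for (i in g1) for (j in g2) {
    den <- sum(rel[, i] + rel[, j])
    for (k in seq_len(nrow(rel)))
      contrib[k] <- contrib[k] + abs(rel[k, i] - rel[k, j]) / den
    np <- np + 1
  }
  setNames(contrib / np, rownames(rel))
}

# constrained CCA eigenvalues by explicitly building the weighted
# projection matrix and eigen-decomposing the projected cross-product
oracleCcaEig <- function(Y, X) {
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  X <- as.matrix(X)
  Xc <- X - matrix(colSums(r * X), nrow(X), ncol(X), byrow = TRUE)
  Xs <- diag(sqrt(r)) %*% Xc
  H <- Xs %*% solve(t(Xs) %*% Xs) %*% t(Xs)
  Qhat <- H %*% Qbar
  ev <- eigen(Qhat %*% t(Qhat), symmetric = TRUE)$values
  ev[ev > 1e-10]
}

# bisection solver for Fisher's log-series alpha
oracleFisherAlpha <- function(S, N, iter = 200) {
  f <- function(a) a * log(1 + N / a) - S
  lo <- 1e-12; hi <- max(S, 1)
  while (f(hi) < 0) hi <- hi * 2
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# pooled-variance two-sample t by the textbook formula
oracleTPooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, P = 2 * pt(-abs(t), na + nb - 2))
}
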