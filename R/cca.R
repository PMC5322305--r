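# chi-square standardised community matrix and its total inertia
.ccaPrep <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("counts must be non-negative")
  tot <- sum(Y)
  if (tot == 0) stop("empty table")
  P <- Y / tot
  r <- rowSums(P); c <- colSums(P)
  if (any(r == 0)) stop("samples with zero total are not allowed")
  keep <- c > 0
  P <- P[, keep, drop = FALSE]; c <- c[keep]
  E <- outer(r, c)
  Qbar <- (P - E) / sqrt(E)
  list(Qbar = Qbar, r = r, totalInertia = sum(Qbar^2))
}

# weighted projection of Qbar onto the span of explanatory variables;
# eigen = FALSE skips the decomposition when only the inertia is needed
# (permutation tests), using ||Q'Qbar||^2 with Q the thin QR basis
.ccaConstrained <- function(prep, X, eigen = TRUE) {
  X <- as.matrix(X)
  r <- prep$r
  Xc <- sweep(X, 2, colSums(r * X))        # weighted centring
  Xs <- Xc * sqrt(r)
  qrX <- qr(Xs)
  rankDef <- qrX$rank < ncol(Xs)
  B <- crossprod(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE], prep$Qbar)
  if (!eigen)
    return(list(eig = NULL, constrained = sum(B^2), rankDeficient = rankDef))
  sv <- svd(B, nu = 0, nv = 0)$d
  eig <- sv[sv^2 > 1e-12 * max(1, sv[1]^2)]^2
  eig <- eig[seq_len(min(length(eig), qrX$rank))]
  list(eig = eig, constrained = sum(B^2), rankDeficient = rankDef)
}

#' Canonical correspondence analysis
#'
#' Relates a chi-square-standardised taxa table to host variables: the
#' standardised table is projected (row-weighted least squares) onto the
#' span of the weighted, centred explanatory variables and the projected
#' matrix eigen-decomposed. Total inertia equals the table's chi-square
#' statistic divided by its grand total; the constrained inertia (sum of
#' canonical eigenvalues) is the part of it the variables explain.
#'
#' @param counts taxa-by-sample count matrix
#' @param variables data.frame or matrix of per-sample explanatory
#'   variables (numerically coded; factors as 0/1 indicators)
#' @return a [CcaResult-class] (no selection: `selection` lists every
#'   variable jointly with the full-model explained %)
#' @export
ccaFit <- function(counts, variables) {
  Y <- t(as.matrix(counts))  # samples x taxa
  X <- .numericDesign(variables)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(Y) <= ncol(X) + 1)
    stop("need more samples than variables + 1")
  prep <- .ccaPrep(Y)
  con <- .ccaConstrained(prep, X)
  if (con$rankDeficient) warning("collinear (rank-deficient) variables")
  sel <- data.frame(variable = colnames(X),
                    added_inertia = NA_real_, pct_total = NA_real_,
                    P = NA_real_, order = NA_integer_,
                    stringsAsFactors = FALSE)
  methods::new("CcaResult", eig = con$eig, totalInertia = prep$totalInertia,
               constrainedInertia = con$constrained,
               variables = colnames(X), selection = sel,
               undetermined = 100 * (1 - con$constrained / prep$totalInertia),
               mode = "joint", nPerm = 0L, alpha = NA_real_, seed = NA_integer_)
}

# coerce a covariate table to a numeric design matrix (0/1 indicators
# for two-level factors/characters, numeric otherwise)
.numericDesign <- function(variables) {
  if (is.matrix(variables)) return(apply(variables, 2, as.numeric))
  X <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    if (is.numeric(v)) return(as.numeric(v))
    f <- factor(v)
    if (nlevels(f) > 2)
      stop("variable ", nm, " has >2 levels; code indicators explicitly")
    as.numeric(f) - 1
  })
  out <- do.call(cbind, X)
  colnames(out) <- names(variables)
  out
}

#' Forward selection of host variables in CCA
#'
#' Iteratively adds the candidate variable contributing the largest
#' additional constrained inertia, admitting it only if its Monte Carlo
#' permutation P (candidate values permuted across samples, conditioned
#' on the variables already selected) is below `alpha`; stops when no
#' candidate qualifies. Each selected variable's additional inertia is
#' reported as a percentage of total inertia, with the unexplained
#' remainder as "undetermined". `mode = "marginal"` instead reports each
#' variable alone (no conditioning), with P from its marginal test.
#'
#' @param counts taxa-by-sample count matrix
#' @param variables data.frame of candidate variables
#' @param nPerm Monte Carlo permutations per test (default 1000)
#' @param alpha admission threshold on permutation P (default 0.05)
#' @param seed integer seed
#' @param mode `"conditional"` (forward selection, default) or
#'   `"marginal"`
#' @return a [CcaResult-class]; `selection` has one row per selected
#'   (or, marginal mode, per candidate) variable
#' @export
forwardSelect <- function(counts, variables, nPerm = 1000, alpha = 0.05,
                          seed = 1L, mode = c("conditional", "marginal")) {
  mode <- match.arg(mode)
  Y <- t(as.matrix(counts))
  X <- .numericDesign(variables)
  prep <- .ccaPrep(Y)
  tot <- prep$totalInertia
  n <- nrow(Y)
  set.seed(seed)

  baseConstr <- function(selCols) {
    if (!length(selCols)) return(0)
    .ccaConstrained(prep, X[, selCols, drop = FALSE], eigen = FALSE)$constrained
  }
  addedInertia <- function(selCols, v, base) {
    full <- .ccaConstrained(prep, cbind(X[, selCols, drop = FALSE], v),
                            eigen = FALSE)
    list(added = full$constrained - base,
         redundant = full$rankDeficient)
  }
  permTest <- function(selCols, v, obsAdded, base) {
    extreme <- 0
    for (p in seq_len(nPerm)) {
      permAdded <- addedInertia(selCols, v[sample.int(n)], base)$added
      if (permAdded >= obsAdded - 1e-12) extreme <- extreme + 1
    }
    (1 + extreme) / (1 + nPerm)
  }

  if (mode == "marginal") {
    rows <- lapply(colnames(X), function(nm) {
      a <- addedInertia(integer(0), X[, nm], 0)
      data.frame(variable = nm, added_inertia = a$added,
                 pct_total = 100 * a$added / tot,
                 P = permTest(integer(0), X[, nm], a$added, 0),
                 order = NA_integer_, stringsAsFactors = FALSE)
    })
    sel <- do.call(rbind, rows)
    return(methods::new("CcaResult", eig = numeric(0), totalInertia = tot,
                        constrainedInertia = NA_real_, variables = colnames(X),
                        selection = sel,
                        undetermined = 100 - sum(sel$pct_total),
                        mode = "marginal", nPerm = as.integer(nPerm),
                        alpha = alpha, seed = as.integer(seed)))
  }

  selCols <- integer(0)
  sel <- NULL
  remaining <- seq_len(ncol(X))
  step <- 0L
  while (length(remaining)) {
    base <- baseConstr(selCols)
    adds <- lapply(remaining, function(k) addedInertia(selCols, X[, k], base))
    addVals <- vapply(adds, `[[`, numeric(1), "added")
    redund <- vapply(adds, `[[`, logical(1), "redundant")
    addVals[redund] <- -Inf  # collinear with selected set: never admitted
    ord <- order(addVals, decreasing = TRUE)
    admitted <- FALSE
    for (o in ord) {
      if (!is.finite(addVals[o])) break
      k <- remaining[o]
      p <- permTest(selCols, X[, k], addVals[o], base)
      if (p < alpha) {
        step <- step + 1L
        sel <- rbind(sel, data.frame(
          variable = colnames(X)[k], added_inertia = addVals[o],
          pct_total = 100 * addVals[o] / tot, P = p, order = step,
          stringsAsFactors = FALSE))
        selCols <- c(selCols, k)
        remaining <- remaining[remaining != k]
        admitted <- TRUE
        break
      }
    }
    if (!admitted) break
  }

  con <- if (length(selCols))
    .ccaConstrained(prep, X[, selCols, drop = FALSE])
  else list(eig = numeric(0), constrained = 0)
  if (is.null(sel))
    sel <- data.frame(variable = character(0), added_inertia = numeric(0),
                      pct_total = numeric(0), P = numeric(0),
                      order = integer(0), stringsAsFactors = FALSE)
  methods::new("CcaResult", eig = con$eig, totalInertia = tot,
               constrainedInertia = con$constrained,
               variables = colnames(X), selection = sel,
               undetermined = 100 - sum(sel$pct_total),
               mode = "conditional", nPerm = as.integer(nPerm),
               alpha = alpha, seed = as.integer(seed))
}

#' @export
setMethod("show", "CcaResult", function(object) {
  cat(sprintf("CCA (%s): total inertia %.4f", object@mode,
              object@totalInertia))
  if (!is.na(object@constrainedInertia))
    cat(sprintf(", constrained %.4f (%.1f%%)", object@constrainedInertia,
                100 * object@constrainedInertia / object@totalInertia))
  cat("\n")
  sel <- object@selection
  if (nrow(sel) && any(!is.na(sel$pct_total))) {
    for (i in seq_len(nrow(sel)))
      cat(sprintf("  %s: %.1f%% of variation (P = %.3g)\n",
                  sel$variable[i], sel$pct_total[i], sel$P[i]))
    cat(sprintf("  undetermined: %.1f%%\n", object@undetermined))
  }
  invisible(NULL)
})
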