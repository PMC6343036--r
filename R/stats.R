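# Group-difference, correlation, matrix-association and path-analysis
# statistics linking recombination summaries to lifestyle and genomic
# variables. Permutation tests are seed-deterministic with add-one
# p-values; exact enumeration is used for small problems.

# all assignments of N items to groups of the given sizes, as a list of
# group-label vectors; NULL if the count exceeds `limit`
.enumAssignments <- function(sizes, limit = 1e5) {
  total <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  if (total > limit) return(NULL)
  rec <- function(idx, g) {
    if (g == length(sizes))
      return(list(stats::setNames(rep(g, length(idx)), idx)))
    picks <- utils::combn(idx, sizes[g], simplify = FALSE)
    out <- list()
    for (p in picks) {
      lab <- stats::setNames(rep(g, length(p)), p)
      for (restLab in rec(setdiff(idx, p), g + 1))
        out[[length(out) + 1L]] <- c(lab, restLab)
    }
    out
  }
  asn <- rec(seq_len(sum(sizes)), 1)
  lapply(asn, function(a) {
    v <- integer(sum(sizes))
    v[as.integer(names(a))] <- a
    v
  })
}

.kwStat <- function(values, g) {
  r <- rank(values)
  N <- length(values)
  ns <- tabulate(g)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(ns), function(k)
      sum(r[g == k])^2 / ns[k], numeric(1))) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

#' Kruskal-Wallis test with optional exact permutation p
#'
#' Tie-corrected rank statistic H with a chi-squared p-value on k-1 df;
#' with `exact = TRUE` the p-value is instead computed over all
#' assignments of the observations to the group sizes (when their number
#' is at most `enumLimit`) or by seeded random permutation otherwise.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length, >= 2 levels.
#' @param exact Use permutation instead of the chi-squared approximation.
#' @param nPerm Random permutations when enumeration is infeasible.
#' @param seed Integer seed.
#' @param enumLimit Maximum number of assignments to enumerate.
#' @return A list with `H`, `p` and `method`.
#' @export
kruskalWallis <- function(values, groups, exact = FALSE, nPerm = 1999L,
                          seed = 1L, enumLimit = 1e5) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  g <- as.integer(groups)
  H <- .kwStat(values, g)
  if (!exact) {
    p <- stats::pchisq(H, nlevels(groups) - 1, lower.tail = FALSE)
    return(list(H = H, p = p, method = "chi-squared"))
  }
  sizes <- tabulate(g)
  asn <- .enumAssignments(sizes, enumLimit)
  if (!is.null(asn)) {
    hs <- vapply(asn, function(a) .kwStat(values, a), numeric(1))
    return(list(H = H, p = mean(hs >= H - 1e-12), method = "exact"))
  }
  set.seed(as.integer(seed))
  hs <- vapply(seq_len(nPerm), function(i)
    .kwStat(values, sample(g)), numeric(1))
  list(H = H, p = (1 + sum(hs >= H - 1e-12)) / (nPerm + 1),
       method = "permutation")
}

.jtStat <- function(values, g, k) {
  s <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- values[g == i]; y <- values[g == j]
    if (!length(x) || !length(y)) next
    cmp <- outer(x, y, "<")
    tie <- outer(x, y, "==")
    s <- s + sum(cmp) + 0.5 * sum(tie)
  }
  s
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' JT is the sum of pairwise Mann-Whitney counts over ordered group pairs
#' (ties counted 1/2); the one-sided p-value (increasing trend) is exact
#' by enumeration when the number of arrangements is at most `enumLimit`,
#' otherwise a seeded permutation p (add-one) or, with
#' `method = "normal"`, a tie-adjusted normal approximation.
#'
#' @param values Numeric vector.
#' @param groups An **ordered** factor giving the hypothesized ordering.
#' @param method `"auto"` (exact when feasible, else permutation),
#'   `"exact"`, `"permutation"` or `"normal"`.
#' @param nPerm,seed,enumLimit As in [kruskalWallis()].
#' @return A list with `JT`, `p` and `method`.
#' @export
jonckheereTerpstra <- function(values, groups, method = "auto",
                               nPerm = 1999L, seed = 1L, enumLimit = 1e5) {
  if (!is.ordered(groups))
    stop("groups must be an ordered factor")
  g <- as.integer(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two ordered groups")
  JT <- .jtStat(values, g, k)
  if (method %in% c("auto", "exact")) {
    asn <- .enumAssignments(tabulate(g, k), enumLimit)
    if (!is.null(asn)) {
      js <- vapply(asn, function(a) .jtStat(values, a, k), numeric(1))
      return(list(JT = JT, p = mean(js >= JT - 1e-12), method = "exact"))
    }
    if (method == "exact") stop("exact enumeration infeasible")
  }
  if (method == "normal") {
    ns <- tabulate(g, k)
    N <- length(values)
    mu <- (N^2 - sum(ns^2)) / 4
    tj <- table(values)
    v <- (N * (N - 1) * (2 * N + 5) - sum(ns * (ns - 1) * (2 * ns + 5)) -
            sum(tj * (tj - 1) * (2 * tj + 5))) / 72 +
      sum(ns * (ns - 1) * (ns - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
        (36 * N * (N - 1) * (N - 2)) +
      sum(ns * (ns - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
    z <- (JT - mu) / sqrt(v)
    return(list(JT = JT, p = stats::pnorm(z, lower.tail = FALSE),
                method = "normal"))
  }
  set.seed(as.integer(seed))
  js <- vapply(seq_len(nPerm), function(i)
    .jtStat(values, sample(g), k), numeric(1))
  list(JT = JT, p = (1 + sum(js >= JT - 1e-12)) / (nPerm + 1),
       method = "permutation")
}

.checkDist <- function(d, name) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(name, " must be a square matrix")
  if (any(!is.finite(d))) stop(name, " contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop(name, " must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop(name, " must have a zero diagonal")
}

.upper <- function(d) d[upper.tri(d)]

#' Mantel test of association between two distance matrices
#'
#' r is the Pearson correlation of the upper-triangle entries; the
#' one-sided p-value (positive association) permutes the row/column
#' labels of the first matrix, exactly over all permutations when
#' `n <= exactN`, otherwise by seeded random permutation with add-one.
#'
#' @param dA,dB Square symmetric zero-diagonal matrices, same dimension
#'   (>= 4).
#' @param nPerm Random permutations (default 1999).
#' @param seed Integer seed.
#' @param exactN Exhaustive enumeration up to this dimension (default 7).
#' @return A list with `r`, `p` and `method`.
#' @export
mantelTest <- function(dA, dB, nPerm = 1999L, seed = 1L, exactN = 7L) {
  .checkDist(dA, "dA"); .checkDist(dB, "dB")
  n <- nrow(dA)
  if (nrow(dB) != n || n < 4) stop("matrices must share dimension >= 4")
  r <- stats::cor(.upper(dA), .upper(dB))
  rPerm <- function(ord) stats::cor(.upper(dA[ord, ord]), .upper(dB))
  if (n <= exactN) {
    perms <- .allPerms(n)
    rs <- vapply(perms, rPerm, numeric(1))
    return(list(r = r, p = mean(rs >= r - 1e-12), method = "exact"))
  }
  set.seed(as.integer(seed))
  rs <- vapply(seq_len(nPerm), function(i) rPerm(sample.int(n)),
               numeric(1))
  list(r = r, p = (1 + sum(rs >= r - 1e-12)) / (nPerm + 1),
       method = "permutation")
}

#' Partial Mantel test controlling a third matrix
#'
#' First-order partial correlation of dA and dB given dC on the upper
#' triangles; significance by permutation of dA's labels as in
#' [mantelTest()].
#'
#' @inheritParams mantelTest
#' @param dC Control distance matrix.
#' @return A list with `r`, `p` and `method`.
#' @export
partialMantel <- function(dA, dB, dC, nPerm = 1999L, seed = 1L,
                          exactN = 7L) {
  .checkDist(dA, "dA"); .checkDist(dB, "dB"); .checkDist(dC, "dC")
  n <- nrow(dA)
  if (nrow(dB) != n || nrow(dC) != n || n < 4)
    stop("matrices must share dimension >= 4")
  pcor <- function(a) {
    rab <- stats::cor(a, .upper(dB))
    rac <- stats::cor(a, .upper(dC))
    rbc <- stats::cor(.upper(dB), .upper(dC))
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  r <- pcor(.upper(dA))
  if (n <= exactN) {
    perms <- .allPerms(n)
    rs <- vapply(perms, function(o) pcor(.upper(dA[o, o])), numeric(1))
    return(list(r = r, p = mean(rs >= r - 1e-12), method = "exact"))
  }
  set.seed(as.integer(seed))
  rs <- vapply(seq_len(nPerm), function(i) {
    o <- sample.int(n)
    pcor(.upper(dA[o, o]))
  }, numeric(1))
  list(r = r, p = (1 + sum(rs >= r - 1e-12)) / (nPerm + 1),
       method = "permutation")
}

#' Euclidean distance matrix from species-table columns
#'
#' Selected numeric columns are z-standardized (constant columns dropped
#' with a warning); factor/character columns are expanded to 0/1 dummy
#' blocks before distancing.
#'
#' @param data A `data.frame`, one row per species.
#' @param cols Columns to use (default all).
#' @param standardize Z-standardize numeric columns (default `TRUE`).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
euclideanDistances <- function(data, cols = NULL, standardize = TRUE) {
  if (is.null(cols)) cols <- names(data)
  if (length(cols) < 1) stop("select at least one column")
  blocks <- list()
  for (cc in cols) {
    v <- data[[cc]]
    if (is.numeric(v)) {
      if (standardize) {
        s <- stats::sd(v)
        if (is.na(s) || s == 0) {
          warning("dropping constant column '", cc, "'")
          next
        }
        v <- (v - mean(v)) / s
      }
      blocks[[cc]] <- matrix(v, ncol = 1)
    } else {
      f <- factor(v)
      blocks[[cc]] <- stats::model.matrix(~ f - 1)
    }
  }
  if (!length(blocks)) stop("no usable columns remain")
  X <- do.call(cbind, blocks)
  m <- as.matrix(stats::dist(X))
  dimnames(m) <- list(rownames(data), rownames(data))
  m
}

.topoSort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges$to[i]] <- indeg[edges$to[i]] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0) avail <- sort(c(avail, w))
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  if (length(order) != length(nodes)) stop("path model must be acyclic")
  order
}

#' Recursive path analysis by OLS on standardized data
#'
#' Fits one ordinary-least-squares equation per endogenous variable on
#' z-standardized data; edge coefficients are therefore standardized path
#' coefficients. The indirect effect of X on Y is the sum over all
#' directed paths of length >= 2 of the products of edge coefficients;
#' total = direct + indirect. R-squared is reported per equation.
#' Character/factor exogenous variables are dummy-coded 0/1 (first level
#' dropped) before standardization.
#'
#' @param data A `data.frame`.
#' @param edges A `data.frame` with columns `from`, `to` (or a list of
#'   `c(from, to)` pairs) defining an acyclic directed graph.
#' @param condLimit Condition-number threshold for a collinearity warning.
#' @return A list with `coefficients` (`from`, `to`, `coef`, `p`),
#'   `r2` (named per endogenous variable) and `effects` (`from`, `to`,
#'   `direct`, `indirect`, `total` for every connected ordered pair).
#' @export
pathAnalysis <- function(data, edges, condLimit = 30) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- data.frame(from = vapply(edges, `[`, character(1), 1),
                        to = vapply(edges, `[`, character(1), 2),
                        stringsAsFactors = FALSE)
  vars <- unique(c(edges$from, edges$to))
  # dummy-code non-numeric variables
  d <- data
  for (v in vars) {
    if (is.null(d[[v]])) stop("variable '", v, "' not in data")
    if (!is.numeric(d[[v]])) {
      f <- factor(d[[v]])
      if (nlevels(f) > 2)
        stop("multi-level factor '", v,
             "' must be pre-coded into dummies")
      d[[v]] <- as.numeric(f) - 1
    }
  }
  .topoSort(vars, edges)  # validates acyclicity
  z <- as.data.frame(lapply(d[vars], function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop("constant variable in path model")
    (v - mean(v)) / s
  }))
  endo <- unique(edges$to)
  coefRows <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  B <- matrix(0, length(vars), length(vars),
              dimnames = list(vars, vars))  # B[from,to]
  for (y in endo) {
    preds <- edges$from[edges$to == y]
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", preds), y),
                     data = z)
    X <- stats::model.matrix(fit)
    if (ncol(X) > 2 && kappa(X[, -1, drop = FALSE]) > condLimit)
      warning("collinear predictors for '", y,
              "' (condition number above ", condLimit, ")")
    sm <- summary(fit)$coefficients
    # coefficient rows follow the predictor order after the intercept
    for (i in seq_along(preds)) {
      x <- preds[i]
      coefRows[[length(coefRows) + 1L]] <- data.frame(
        from = x, to = y, coef = unname(sm[i + 1L, 1]),
        p = unname(sm[i + 1L, 4]), stringsAsFactors = FALSE)
      B[x, y] <- sm[i + 1L, 1]
    }
    r2[y] <- summary(fit)$r.squared
  }
  coefs <- do.call(rbind, coefRows)
  # total effect = sum over all directed paths of edge-coefficient
  # products; indirect = total - direct
  allPaths <- function(x, y) {
    total <- 0
    walk <- function(node, prod) {
      outs <- which(B[node, ] != 0)
      for (o in outs) {
        nn <- vars[o]
        pr <- prod * B[node, nn]
        if (nn == y) total <<- total + pr
        else walk(nn, pr)
      }
    }
    walk(x, 1)
    total
  }
  eff <- list()
  for (x in vars) for (y in vars) {
    if (x == y) next
    tot <- allPaths(x, y)
    direct <- B[x, y]
    if (tot == 0 && direct == 0) next
    eff[[length(eff) + 1L]] <- data.frame(
      from = x, to = y, direct = direct, indirect = tot - direct,
      total = tot, stringsAsFactors = FALSE)
  }
  eff <- do.call(rbind, eff)
  rownames(eff) <- NULL
  list(coefficients = coefs, r2 = r2, effects = eff)
}

#' Correlation with optional exact permutation p
#'
#' Pearson or Spearman coefficient with a two-sided p-value from the
#' usual t approximation, or an exact permutation p (all orderings of y)
#' when `exact = TRUE` and n <= 8.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @param exact Exact permutation p-value (n <= 8).
#' @return A list with `estimate`, `p` and `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      exact = FALSE) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(estimate = NA_real_, p = NA_real_, method = method))
  }
  if (exact) {
    if (length(x) > 8) stop("exact permutation limited to n <= 8")
    robs <- stats::cor(x, y, method = method)
    perms <- .allPerms(length(y))
    rs <- vapply(perms, function(o) stats::cor(x, y[o], method = method),
                 numeric(1))
    return(list(estimate = robs, p = mean(abs(rs) >= abs(robs) - 1e-12),
                method = paste0(method, "-exact")))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method)
}
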