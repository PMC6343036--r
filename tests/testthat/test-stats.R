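# group-difference, correlation, Mantel and path-analysis statistics

test_that("Kruskal-Wallis reproduces the rank formula and exact p", {
  out <- kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b"), exact = TRUE)
  expect_equal(out$H, 2.4, tolerance = 1e-12)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  expect_identical(out$method, "exact")

  # agrees with the base implementation on untied data
  set.seed(1)
  x <- rnorm(30)
  g <- rep(letters[1:3], each = 10)
  ours <- kruskalWallis(x, g)
  ref <- stats::kruskal.test(x, factor(g))
  expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  expect_equal(kruskalWallis(rep(5, 6), rep(c("a", "b"), 3))$H, 0)
  expect_error(kruskalWallis(1:4, rep("a", 4)), "two groups")
})

test_that("Jonckheere-Terpstra detects ordered trends with exact p", {
  g <- factor(c("lo", "lo", "hi", "hi"), levels = c("lo", "hi"),
              ordered = TRUE)
  out <- jonckheereTerpstra(c(1, 2, 3, 4), g)
  expect_equal(out$JT, 4)
  expect_equal(out$p, 1 / 6, tolerance = 1e-12)

  flat <- jonckheereTerpstra(rep(2, 6),
                             factor(rep(c("a", "b", "c"), 2),
                                    ordered = TRUE))
  expect_equal(flat$p, 1)   # every assignment ties the statistic

  anti <- jonckheereTerpstra(c(4, 3, 2, 1), g)
  expect_gte(anti$p, 5 / 6)  # one-sided for an increasing trend

  expect_error(jonckheereTerpstra(1:4, factor(c(1, 1, 2, 2))),
               "ordered factor")

  # permutation and normal approximations target the same tail
  set.seed(3)
  x <- rnorm(24) + rep(1:3, each = 8) * 0.8
  go <- factor(rep(1:3, each = 8), ordered = TRUE)
  pp <- jonckheereTerpstra(x, go, method = "permutation", nPerm = 999,
                           seed = 5)$p
  pn <- jonckheereTerpstra(x, go, method = "normal")$p
  expect_lt(abs(log10(pp + 1e-4) - log10(pn + 1e-4)), 1)
})

test_that("Mantel tests match exhaustive label enumeration", {
  set.seed(7)
  X <- matrix(rnorm(8), 4, 2)
  dA <- as.matrix(dist(X))
  expect_equal(mantelTest(dA, dA)$r, 1)

  Y <- matrix(rnorm(8), 4, 2)
  dB <- as.matrix(dist(Y))
  got <- mantelTest(dA, dB)
  # oracle: all 24 label permutations
  perms <- coreHR:::.allPerms(4)
  up <- function(d) d[upper.tri(d)]
  rs <- vapply(perms, function(o) stats::cor(up(dA[o, o]), up(dB)),
               numeric(1))
  expect_equal(got$p, mean(rs >= got$r - 1e-12), tolerance = 1e-12)
  expect_identical(got$method, "exact")

  # invariance to simultaneous relabeling
  o <- c(3, 1, 4, 2)
  expect_equal(mantelTest(dA[o, o], dB[o, o])$r, got$r, tolerance = 1e-12)

  expect_error(mantelTest(dA[1:3, 1:3], dB[1:3, 1:3]), "dimension")
  bad <- dA; bad[1, 2] <- NA
  expect_error(mantelTest(bad, dB), "non-finite")
})

test_that("the partial Mantel statistic controls the third matrix", {
  set.seed(11)
  n <- 12
  z <- rnorm(n)
  dC <- as.matrix(dist(z))
  dA <- as.matrix(dist(z + rnorm(n, sd = 0.1)))
  dB <- as.matrix(dist(z + rnorm(n, sd = 0.1)))
  full <- mantelTest(dA, dB, nPerm = 499, seed = 2)
  part <- partialMantel(dA, dB, dC, nPerm = 499, seed = 2)
  expect_lt(part$r, full$r)  # shared driver is partialled out

  # against the closed-form first-order partial correlation
  up <- function(d) d[upper.tri(d)]
  rab <- cor(up(dA), up(dB)); rac <- cor(up(dA), up(dC))
  rbc <- cor(up(dB), up(dC))
  expect_equal(part$r, (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2)),
               tolerance = 1e-12)
})

test_that("Mantel permutation p-values are calibrated under the null", {
  set.seed(21)
  ps <- replicate(60, {
    dA <- as.matrix(dist(rnorm(15)))
    dB <- as.matrix(dist(rnorm(15)))
    mantelTest(dA, dB, nPerm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Euclidean distances standardize, dummy-code and warn", {
  df <- data.frame(x = c(0, 3), y = c(0, 4))
  expect_equal(euclideanDistances(df, standardize = FALSE)[1, 2], 5)
  expect_equal(euclideanDistances(df)[1, 1], 0)

  # scale invariance under standardization
  df2 <- data.frame(x = rnorm(6), y = rnorm(6))
  df3 <- transform(df2, x = x * 10)
  expect_equal(euclideanDistances(df2), euclideanDistances(df3),
               tolerance = 1e-12)

  # categorical columns enter as 0/1 dummies
  df4 <- data.frame(x = rnorm(6),
                    lifestyle = rep(c("endosymbiont", "opportunist"), 3))
  m <- euclideanDistances(df4)
  expect_true(isSymmetric(m))

  df5 <- data.frame(x = rnorm(6), k = 1)
  expect_warning(euclideanDistances(df5), "constant column")
})

test_that("path analysis reduces to Pearson r on a single edge", {
  set.seed(13)
  d <- data.frame(x = rnorm(50))
  d$y <- 0.6 * d$x + rnorm(50, sd = 0.5)
  fit <- pathAnalysis(d, data.frame(from = "x", to = "y"))
  expect_equal(fit$coefficients$coef, cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(unname(fit$r2["y"]), cor(d$x, d$y)^2, tolerance = 1e-12)
  expect_lte(abs(fit$coefficients$coef), 1)
})

test_that("path analysis decomposes direct and indirect effects", {
  set.seed(14)
  n <- 300
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n, sd = 0.5)
  y <- 0.5 * m + 0.3 * x + rnorm(n, sd = 0.5)
  d <- data.frame(x = x, m = m, y = y)
  edges <- data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"))
  fit <- pathAnalysis(d, edges)
  eff <- fit$effects
  xy <- eff[eff$from == "x" & eff$to == "y", ]
  a <- fit$coefficients$coef[fit$coefficients$from == "x" &
                               fit$coefficients$to == "m"]
  b <- fit$coefficients$coef[fit$coefficients$from == "m" &
                               fit$coefficients$to == "y"]
  expect_equal(xy$indirect, a * b, tolerance = 1e-12)
  expect_equal(xy$total, xy$direct + xy$indirect, tolerance = 1e-12)

  cyc <- data.frame(from = c("x", "y"), to = c("y", "x"))
  expect_error(pathAnalysis(d, cyc), "acyclic")
})

test_that("correlations support exact permutation p-values", {
  x <- 1:5
  expect_equal(correlate(x, 2 * x)$estimate, 1)
  expect_equal(correlate(x, rev(x), method = "spearman")$estimate, -1)

  set.seed(15)
  y <- rnorm(5)
  got <- correlate(x, y, exact = TRUE)
  perms <- coreHR:::.allPerms(5)
  rs <- vapply(perms, function(o) cor(x, y[o]), numeric(1))
  expect_equal(got$p, mean(abs(rs) >= abs(got$estimate) - 1e-12),
               tolerance = 1e-12)

  expect_warning(correlate(rep(1, 5), y), "zero variance")
  expect_error(correlate(1:2, 1:2), "length")
})

test_that("the Mantel statistic agrees with the vegan implementation", {
  set.seed(33)
  dA <- as.matrix(dist(rnorm(10)))
  dB <- as.matrix(dist(rnorm(10)))
  ours <- mantelTest(dA, dB, nPerm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(dA), as.dist(dB), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})
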