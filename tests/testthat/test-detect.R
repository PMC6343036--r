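# the five detection statistics and their exact permutation nulls

test_that("polymorphic sites are exactly the planted variant columns", {
  b <- mkBlock(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA")
  expect_length(polymorphicSites(b), 0)

  b1 <- mkBlock(s1 = "AATA", s2 = "AAAA", s3 = "AAAA")
  expect_identical(polymorphicSites(b1), 2L)

  set.seed(3)
  W <- 300
  base <- rep("A", W)
  snp <- sort(sample(W, 12))
  r2 <- base; r2[snp] <- "G"
  b2 <- mkBlock(s1 = paste(base, collapse = ""),
                s2 = paste(r2, collapse = ""),
                s3 = paste(base, collapse = ""))
  expect_identical(polymorphicSites(b2), as.integer(snp - 1L))

  # gap/N columns never count as polymorphic on their own
  b3 <- mkBlock(s1 = "A-NA", s2 = "AAAA", s3 = "AAAA")
  expect_length(polymorphicSites(b3), 0)
})

test_that("MaxChi statistic and exact p match exhaustive enumeration", {
  tb <- mkTripletBlock(c(rep(TRUE, 6), rep(FALSE, 6)))
  h <- maxchiScan(tb$block, "child", "pa", "pb", alpha = 0.01)
  expect_equal(nrow(h), 1)
  expect_equal(h$stat, 12)                    # clean 6+6 split
  expect_equal(h$breakpointCol, tb$cols[6])

  # exact p equals full enumeration over C(12,6) site labelings
  labs <- allLabelings(6, 6)
  stats <- vapply(labs, bruteMaxChi, numeric(1))
  pEnum <- mean(stats >= 12 - 1e-9)
  expect_equal(h$rawP, pEnum, tolerance = 1e-12)

  # one-sided child (all matches to A) gives no informative contrast
  tbA <- mkTripletBlock(rep(TRUE, 10))
  hA <- maxchiScan(tbA$block, "child", "pa", "pb", alpha = 0.05)
  expect_equal(nrow(hA), 0)
})

test_that("exact max-chi2 scan p agrees with Monte-Carlo permutation", {
  for (cse in list(c(8, 7, 6), c(30, 25, 15))) {
    null <- coreHR:::cpp_maxchi_null(cse[1], cse[2], 4000, 13)
    pMC <- mean(null >= cse[3] - 1e-9)
    pDP <- coreHR:::cpp_maxchi_scan_pvalue(cse[1], cse[2], cse[3])
    expect_lt(abs(pMC - pDP), 3 * sqrt(pDP * (1 - pDP) / 4000) + 1e-6)
  }
})

test_that("Chimaera skips degenerate triplets and localizes planted mosaics", {
  # child identical to parentA: no site where it differs from exactly one
  W <- 200
  a <- paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
             collapse = "")
  b <- mkBlock(child = a, pa = a,
               pb = paste(rev(strsplit(a, "")[[1]]), collapse = ""))
  h <- chimaeraScan(b, "child", "pa", "pb")
  expect_equal(nrow(h), 0)

  # planted mosaic: A-allegiance then B-allegiance
  tb <- mkTripletBlock(c(rep(TRUE, 40), rep(FALSE, 40)))
  hm <- chimaeraScan(tb$block, "child", "pa", "pb", alpha = 0.001)
  expect_gte(nrow(hm), 1)
  expect_lt(abs(hm$breakpointCol[1] - tb$cols[40]), 3 * 5)  # +-2 sites
})

test_that("label swap of the parents leaves the scans invariant", {
  set.seed(8)
  tb <- mkTripletBlock(sample(c(TRUE, FALSE), 60, replace = TRUE,
                              prob = c(0.3, 0.7)))
  h1 <- maxchiScan(tb$block, "child", "pa", "pb", alpha = 1.1)
  h2 <- maxchiScan(tb$block, "child", "pb", "pa", alpha = 1.1)
  expect_equal(h1$stat, h2$stat)
  expect_equal(h1$rawP, h2$rawP)

  t1 <- threeseqTest(tb$block, "child", "pa", "pb")
  t2 <- threeseqTest(tb$block, "child", "pb", "pa")
  expect_equal(t1$stat, t2$stat)
  expect_equal(t1$rawP, t2$rawP)
})

test_that("RDP flags regions only when identity ranking flips", {
  # identical sequences: all pairwise identities equal everywhere
  row <- paste(rep("ACGT", 100), collapse = "")
  same <- mkBlock(child = row, pa = row, pb = row)
  h <- rdpScan(same, "child", "pa", "pb", windowNt = 90)
  expect_equal(nrow(h), 0)
  expect_gt(attr(h, "nTests"), 0)

  expect_error(rdpScan(tb$block, "child", "pa", "pb", windowNt = 5),
               "windowNt")

  # window longer than the block: logged skip
  small <- mkBlock(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "ACGTACGTAC")
  hs <- rdpScan(small, "s1", "s2", "s3", windowNt = 90)
  expect_equal(nrow(hs), 0)
  expect_identical(attr(hs, "skip"), "window longer than block")
})

test_that("RDP region p equals an independent binomial tail computation", {
  sim <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 30000,
                                     mu = 0.004, lambda = 1.5, nu = 0.08,
                                     seed = 14, importScope = "terminal"))
  strains <- strainNames(sim$block)
  found <- FALSE
  for (ci in 1:2) {
    h <- rdpScan(sim$block, strains[ci], strains[3], strains[4])
    if (!nrow(h)) next
    found <- TRUE
    # recompute the two-sided tail for the first region from scratch
    M <- coreHR:::.blockMatrix(sim$block)
    idx <- match(c(strains[ci], strains[3], strains[4]), strains)
    ok <- M[idx[1], ] > 0 & M[idx[2], ] > 0 & M[idx[3], ] > 0
    D <- sapply(idx[2:3], function(j) mean(M[idx[1], ok] != M[j, ok]))
    pj <- idx[2:3][which.min(D)]
    q <- 1 - min(D)
    span <- (h$startCol[1] + 1):h$endCol[1]
    nReg <- sum(ok[span])
    kM <- sum(ok[span] & M[idx[1], span] == M[pj, span])
    pLo <- sum(stats::dbinom(0:kM, nReg, q))
    pHi <- sum(stats::dbinom(kM:nReg, nReg, q))
    expect_equal(h$rawP[1], min(1, 2 * min(pLo, pHi)), tolerance = 1e-8)
    break
  }
  expect_true(found)
})

test_that("GENECONV scores the maximal inner fragment with an exact tail", {
  # 20 polymorphic columns; the pair agrees exactly at columns 6..15
  k <- 20
  spacing <- 4L
  W <- (k + 1L) * spacing
  r1 <- rep("A", W); r2 <- rep("A", W); r3 <- rep("A", W)
  cols <- seq_len(k) * spacing
  agree <- seq_len(k) %in% 6:15
  r1[cols] <- "C"
  r2[cols] <- ifelse(agree, "C", "G")
  r3[cols] <- "T"  # keeps every column polymorphic
  b <- mkBlock(s1 = paste(r1, collapse = ""), s2 = paste(r2, collapse = ""),
               s3 = paste(r3, collapse = ""))
  h <- geneconvScan(b, "s1", "s2")
  expect_equal(h$stat, 10)
  expect_equal(h$startCol, cols[6] - 1L)
  expect_equal(h$endCol, cols[15])
  expect_equal(h$rawP, coreHR:::.maxRunPvalue(10, 10, 10), tolerance = 1e-12)

  # saturated pair: identical at all polymorphic sites
  b2 <- mkBlock(s1 = paste(r1, collapse = ""),
                s2 = paste(r1, collapse = ""),
                s3 = paste(r3, collapse = ""))
  h2 <- geneconvScan(b2, "s1", "s2", nPerm = 1999)
  expect_true(h2$saturated)
  expect_equal(h2$rawP, 1 / 2000)
})

test_that("exact max-run tail matches enumeration and Monte Carlo", {
  # exhaustive: all C(10,6) arrangements of 6 ones and 4 zeros
  labs <- allLabelings(6, 4)
  for (L in 2:6) {
    pEnum <- mean(vapply(labs, function(lab) {
      r <- rle(lab == 1L)
      any(r$values & r$lengths >= L)
    }, logical(1)))
    expect_equal(coreHR:::.maxRunPvalue(6, 4, L), pEnum, tolerance = 1e-12)
  }
  # Monte Carlo at larger size
  null <- coreHR:::cpp_maxrun_null(60, 100, 4000, 5)
  pMC <- mean(null >= 10)
  pEx <- coreHR:::.maxRunPvalue(60, 40, 10)
  expect_lt(abs(pMC - pEx), 3 * sqrt(pEx * (1 - pEx) / 4000) + 1e-6)
})

test_that("GENECONV null p-values are superuniform on exchangeable strings", {
  set.seed(77)
  ps <- replicate(300, {
    agree <- sample(c(0L, 1L), 150, replace = TRUE)
    r <- rle(agree == 1L)
    L <- max(c(0, r$lengths[r$values]))
    if (L == 0) 1 else coreHR:::.maxRunPvalue(sum(agree), sum(!agree), L)
  })
  # exact p-values from a discrete null: P(p <= x) <= x
  for (x in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / 300))
  expect_gt(mean(ps), 0.4)
})

test_that("3Seq maximum descent and exact DP p match brute force", {
  expect_equal(coreHR:::cpp_descent(c(1, 1, -1, -1, -1))$stat, 3)
  expect_equal(coreHR:::cpp_descent(rep(1, 5))$stat, 0)

  # all 20 orderings of 3 up- and 3 down-steps
  labs <- allLabelings(3, 3)
  desc <- vapply(labs, function(lab)
    bruteDescent(ifelse(lab == 1L, 1, -1)), numeric(1))
  for (d in 1:3) {
    expect_equal(coreHR:::cpp_descent_pvalue(3, 3, d)$p, mean(desc >= d),
                 tolerance = 1e-12)
  }

  # DP agrees with brute force on random steps
  set.seed(4)
  for (r in 1:6) {
    steps <- sample(c(1L, -1L), 25, replace = TRUE)
    expect_equal(coreHR:::cpp_descent(steps)$stat, bruteDescent(steps))
  }

  # all up-steps: no descent, p = 1, no hit
  tbUp <- mkTripletBlock(rep(TRUE, 8))
  expect_equal(nrow(threeseqTest(tbUp$block, "child", "pa", "pb")), 0)
})

test_that("oracle equivalence holds on small random alignments", {
  set.seed(31)
  for (r in 1:8) {
    k <- sample(10:30, 1)
    lab <- sample(1:2, k, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(coreHR:::cpp_max_chi2(lab)$stat, bruteMaxChi(lab),
                 tolerance = 1e-9)
    x <- as.integer(lab == 1L)
    r1 <- rle(x == 1L)
    expect_equal(coreHR:::cpp_max_run(x)$len,
                 max(c(0, r1$lengths[r1$values])))
  }
})

test_that("scanAll enumerates the expected tests and validates input", {
  sim <- simulateAlignment(simConfig(nStrains = 3, genomeLength = 3000,
                                     mu = 0.01, lambda = 0, seed = 2))
  hits <- scanAll(sim$block, seed = 2)
  expect_equal(attr(hits, "nTriplets"), 3L)  # 3 child assignments

  expect_error(scanAll(sim$block, methods = "BOOTSCAN"), "unknown method")
  expect_error(scanAll(sim$block, settings = list(foo = 1)),
               "unknown settings")
})

test_that("a planted tract is reported by at least three methods", {
  sim <- simulateAlignment(simConfig(nStrains = 6, genomeLength = 40000,
                                     mu = 0.002, lambda = 0, seed = 55))
  # plant one crisp 3 kb tract (nu = 0.1) in strain s2
  rows <- strsplit(as.character(blockSeqs(sim$block)), "")
  set.seed(99)
  tract <- 15001:18000
  flip <- tract[runif(3000) < 0.1]
  bases <- c("A", "C", "G", "T")
  rows$s2[flip] <- vapply(rows$s2[flip], function(x)
    sample(setdiff(bases, x), 1), character(1))
  b <- alignmentBlock(vapply(rows, paste, character(1), collapse = ""))
  hits <- scanAll(b, seed = 55)
  sg <- hits[hits$correctedP < 0.001 & !is.na(hits$recombinant), ]
  atLocus <- sg[sg$startCol < 18000 & sg$endCol > 15000 &
                  sg$recombinant == "s2", ]
  expect_gte(length(unique(atLocus$method)), 3)
})
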