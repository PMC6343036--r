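# genome-evolution simulator: genealogy, mutation/import process, fixtures

test_that("coalescent genealogy has forced topology, correct expectation and determinism", {
  tr <- simulateGenealogy(3, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(tr$Nnode, 2L)  # rooted binary tree on 3 tips
  expect_error(simulateGenealogy(2), "invalid config")

  # same seed, identical newick
  expect_identical(ape::write.tree(simulateGenealogy(7, seed = 42)),
                   ape::write.tree(simulateGenealogy(7, seed = 42)))

  # Monte-Carlo check of E[total length] = 2 * sum_{k=1}^{n-1} 1/k
  set.seed(9)
  tot <- replicate(600, sum(simulateGenealogy(10)$edge.length))
  expected <- 2 * sum(1 / (1:9))
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("no imports and no mutation give clean degenerate alignments", {
  sim <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 2000,
                                     lambda = 0, seed = 5))
  expect_equal(nrow(truthEvents(sim$truth)), 0L)
  expect_true(all(originMask(sim$truth) == 0L))

  sim0 <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 1000,
                                      mu = 0, lambda = 0, seed = 5))
  rows <- as.character(blockSeqs(sim0$block))
  expect_equal(length(unique(rows)), 1L)
})

test_that("clonal mutation counts follow the Poisson expectation", {
  obs <- exp <- 0
  for (r in 1:40) {
    cfg <- simConfig(nStrains = 8, genomeLength = 20000, mu = 0.01,
                     lambda = 0, seed = 100 + r)
    sim <- simulateAlignment(cfg)
    obs <- obs + sim$truth@nClonalMutations
    exp <- exp + 0.01 * 20000 * sum(truthGenealogy(sim$truth)$edge.length)
  }
  expect_lt(abs(obs - exp), 3 * sqrt(exp))  # Poisson SE
})

test_that("identical configs give byte-identical output and coherent truth", {
  cfg <- simConfig(nStrains = 5, genomeLength = 5000, lambda = 2, seed = 77)
  s1 <- simulateAlignment(cfg)
  s2 <- simulateAlignment(cfg)
  expect_identical(as.character(blockSeqs(s1$block)),
                   as.character(blockSeqs(s2$block)))
  expect_identical(truthEvents(s1$truth), truthEvents(s2$truth))
  expect_identical(originMask(s1$truth), originMask(s2$truth))

  # conservation: mask covers every site of every strain
  expect_equal(dim(originMask(s1$truth)), c(5L, 5000L))
  # events lie within the genome
  ev <- truthEvents(s1$truth)
  if (nrow(ev)) {
    expect_true(all(ev$start >= 0 & ev$end <= 5000))
    expect_true(all(ev$length == ev$end - ev$start))
  }
})

test_that("expected event count scales linearly in lambda", {
  count <- function(lam, seeds) {
    vapply(seeds, function(sd)
      nrow(truthEvents(simulateAlignment(
        simConfig(nStrains = 6, genomeLength = 500, lambda = lam,
                  seed = sd))$truth)), numeric(1))
  }
  n1 <- count(2, 1:120)
  n2 <- count(4, 1:120)
  # difference of means ~ mean(n1), within Monte-Carlo error
  se <- sqrt(stats::var(n2) / 120 + 4 * stats::var(n1) / 120)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("imported tracts are more diverged than the clonal background", {
  sim <- simulateAlignment(simConfig(nStrains = 6, genomeLength = 30000,
                                     mu = 0.001, lambda = 2, nu = 0.08,
                                     seed = 11))
  mask <- originMask(sim$truth)
  M <- coreHR:::.blockMatrix(sim$block)
  diffIn <- diffOut <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    mm <- M[i, ] != M[j, ]
    imp <- mask[i, ] != 0L | mask[j, ] != 0L
    if (sum(imp) > 100) {
      diffIn <- c(diffIn, mean(mm[imp]))
      diffOut <- c(diffOut, mean(mm[!imp]))
    }
  }
  expect_gt(mean(diffIn), mean(diffOut))
})

test_that("terminal import scope restricts events to single strains", {
  sim <- simulateAlignment(simConfig(nStrains = 8, lambda = 2, seed = 3,
                                     importScope = "terminal"))
  ev <- truthEvents(sim$truth)
  expect_gt(nrow(ev), 0)
  expect_true(all(!grepl(",", ev$strains)))
})

test_that("fixtures round-trip and the truth table matches the registry", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(nStrains = 4, genomeLength = 4000, lambda = 2, seed = 8)
  sim <- simulateAlignment(cfg)
  paths <- writeFixtures(sim$block, sim$truth, dir)
  expect_true(all(file.exists(paths)))

  blocks <- readXMFA(paths["xmfa"])
  expect_length(blocks, 1)
  expect_identical(as.character(blockSeqs(blocks[[1]])),
                   as.character(blockSeqs(sim$block)))

  tt <- utils::read.delim(paths["truth"], comment.char = "#")
  expect_equal(nrow(tt), nrow(truthEvents(sim$truth)))
})

test_that("coords fixtures honour overlap directives and are seed-stable", {
  df <- writeCoordsFixture(4, "disjoint", seed = 1)
  ovl <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    if (i == j) return(0)
    max(0, min(df$ref_end[i], df$ref_end[j]) -
          max(df$ref_start[i], df$ref_start[j]) + 1)
  }))
  expect_true(all(ovl == 0))

  dfc <- writeCoordsFixture(3, "contained(1 in 0)", seed = 1)
  expect_gte(dfc$ref_start[2], dfc$ref_start[1])
  expect_lte(dfc$ref_end[2], dfc$ref_end[1])

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeCoordsFixture(5, "disjoint", seed = 9, path = f1)
  writeCoordsFixture(5, "disjoint", seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(writeCoordsFixture(3, "contained(0 in 0)"), "invalid config")
  expect_error(writeCoordsFixture(0), "invalid config")
})

test_that("gene categories are independent of events when the odds are 1", {
  nonsig <- 0
  for (r in 1:40) {
    sim <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 20000,
                                       lambda = 3, w = 1, seed = 400 + r))
    if (!nrow(truthEvents(sim$truth))) { nonsig <- nonsig + 1; next }
    gt <- simulateGeneTable(sim$truth, seed = r)
    ev <- truthEvents(sim$truth)
    # ortholog-level: overlaps any event of a carrying strain
    og <- gt[!duplicated(gt$ortholog), , drop = FALSE]
    hit <- vapply(og$ortholog, function(o) {
      copies <- gt[gt$ortholog == o, , drop = FALSE]
      any(vapply(seq_len(nrow(copies)), function(i) {
        mine <- ev[vapply(strsplit(ev$strains, ","), function(z)
          copies$strain[i] %in% z, logical(1)), , drop = FALSE]
        any(mine$start < copies$end[i] & mine$end > copies$start[i])
      }, logical(1)))
    }, logical(1))
    tab <- table(hit, og$cog == "V")
    p <- if (all(dim(tab) == 2)) suppressWarnings(
      stats::chisq.test(tab)$p.value) else 1
    if (p >= 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 36)  # ~ 95% of null replicates
})

test_that("realized truth intervals unify overlapping plants per strain", {
  sim <- simulateAlignment(simConfig(nStrains = 5, genomeLength = 10000,
                                     lambda = 4, seed = 21))
  ti <- truthIntervals(sim$truth)
  mask <- originMask(sim$truth)
  # intervals reconstruct the mask support exactly
  for (st in rownames(mask)) {
    own <- ti[vapply(strsplit(ti$strains, ","), function(z) st %in% z,
                     logical(1)), , drop = FALSE]
    covered <- rep(FALSE, ncol(mask))
    for (k in seq_len(nrow(own)))
      covered[(own$start[k] + 1):own$end[k]] <- TRUE
    expect_identical(covered, unname(mask[st, ] != 0L))
  }
})
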