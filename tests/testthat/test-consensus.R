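# consensus calling, breakpoint refinement, event characterization

# a fabricated hit row in the scanAll layout
mkHit <- function(method, rec, s, e, p = 1e-4, child = "s1", pa = "s2",
                  pb = "s3") {
  data.frame(method = method, child = child, parentA = pa, parentB = pb,
             recombinant = rec, startCol = s, endCol = e,
             breakpointCol = s, stat = 10, rawP = p, correctedP = p,
             nTests = 1L, saturated = FALSE, stringsAsFactors = FALSE)
}

bigBlock <- function(W = 1000, n = 3) {
  set.seed(1)
  row <- paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
               collapse = "")
  rows <- stats::setNames(rep(row, n), paste0("s", 1:n))
  alignmentBlock(rows)
}

test_that("the three-of-five rule and method-set semantics are enforced", {
  b <- bigBlock()
  two <- rbind(mkHit("MAXCHI", "s1", 100, 200),
               mkHit("RDP", "s1", 110, 210))
  expect_equal(nrow(callEvents(two, b)), 0)

  three <- rbind(two, mkHit("3SEQ", "s1", 105, 195))
  ev <- callEvents(three, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$nMethods, 3L)

  # five co-located hits, two sharing a method name -> 4 distinct methods
  five <- rbind(three, mkHit("MAXCHI", "s1", 120, 205),
                mkHit("GENECONV", "s1", 100, 190))
  ev5 <- callEvents(five, b)
  expect_equal(ev5$nMethods, 4L)

  # hits above alpha never support an event
  weak <- rbind(two, mkHit("3SEQ", "s1", 105, 195, p = 0.5))
  expect_equal(nrow(callEvents(weak, b)), 0)
  expect_equal(nrow(callEvents(NULL, b)), 0)
})

test_that("events get genome coordinates, size and GC from the block", {
  W <- 600
  row <- paste(rep("A", W), collapse = "")
  gcseg <- row
  substr(gcseg, 101, 104) <- "GGCC"
  b <- alignmentBlock(c(s1 = gcseg, s2 = row, s3 = row))
  hits <- rbind(mkHit("MAXCHI", "s1", 100, 104),
                mkHit("RDP", "s1", 100, 104),
                mkHit("3SEQ", "s1", 100, 104))
  ev <- callEvents(hits, b)
  expect_equal(ev$startBp, 100)
  expect_equal(ev$endBp, 104)
  expect_equal(ev$sizeBp, 4)
  expect_equal(ev$gc, 1.0)   # event sequence is GGCC
})

test_that("species summaries compute the characterization variables", {
  b <- bigBlock(W = 1000, n = 5)
  mkEv <- function(rec, s, e) data.frame(
    recombinant = rec, startCol = s, endCol = e, startBp = s, endBp = e,
    sizeBp = e - s, methods = "MAXCHI,RDP,3SEQ", nMethods = 3L,
    pMax = 1e-4, gc = 0.5, stringsAsFactors = FALSE)
  ev <- rbind(mkEv("s1", 0, 100), mkEv("s1", 50, 150))
  sm <- summarizeSpecies(ev, b)
  expect_equal(sm$nEvents, 2L)
  expect_equal(sm$eventsPerStrain, 2 / 5)
  # union of [0,100) and [50,150) spans 150 of 1000 columns
  expect_equal(sm$fractionRecombined, 15)
  expect_equal(sum(sm$sizeHist), 2L)
  expect_equal(unname(sm$sizeHist["<2kb"]), 2L)
  expect_equal(sum(sm$perStrainEvents), 2L)

  ev10 <- do.call(rbind, lapply(0:9, function(i)
    mkEv(paste0("s", i %% 5 + 1), i * 90, i * 90 + 60)))
  expect_equal(summarizeSpecies(ev10, b)$eventsPerStrain, 10 / 5)

  expect_error(summarizeSpecies(ev, alignmentBlock(character(0))),
               "empty alignment")
})

test_that("GC comparison flags compositional outliers and not nulls", {
  # AT-rich genome with GC-only events
  W <- 2000
  set.seed(5)
  row <- sample(c("A", "T"), W, replace = TRUE, prob = c(0.5, 0.5))
  for (s in seq(100, 1900, by = 400)) row[s:(s + 49)] <- "G"
  rows <- paste(row, collapse = "")
  b <- alignmentBlock(c(s1 = rows, s2 = rows, s3 = rows))
  mk3 <- function(rec, s, e) rbind(mkHit("MAXCHI", rec, s, e),
                                   mkHit("RDP", rec, s, e),
                                   mkHit("3SEQ", rec, s, e))
  ev <- callEvents(do.call(rbind, lapply(seq(100, 1900, by = 400),
                                         function(s)
                                           mk3("s1", s - 1, s + 49))), b)
  out <- gcCompare(ev, b, seed = 1)
  expect_lt(out$p, 0.01)
  expect_gt(out$gcEvents, out$gcBackground)

  # a single event spanning the whole alignment reproduces the genome GC
  evAll <- callEvents(mk3("s1", 0, W), b)
  gAll <- gcCompare(evAll, b, seed = 1)
  expect_equal(gAll$gcEvents, summarizeSpecies(evAll, b)$gcGenome,
               tolerance = 1e-12)
  expect_error(gcCompare(ev[0, ], b), "at least one event")
})

test_that("refinement is validated, idempotent and truth-accurate", {
  sim <- simulateAlignment(simConfig(nStrains = 6, genomeLength = 30000,
                                     lambda = 2, seed = 6,
                                     importScope = "terminal"))
  hits <- scanAll(sim$block, seed = 6)
  ev <- callEvents(hits, sim$block)
  if (nrow(ev)) {
    r1 <- refineBreakpoints(ev, sim$block)
    r2 <- refineBreakpoints(r1, sim$block)
    expect_identical(r1[, c("startCol", "endCol")],
                     r2[, c("startCol", "endCol")])
    expect_true(all(r1$refineFlag %in% c("refined", "unrefined")))
  }
  # degenerate event without informative sites stays unrefined
  b <- bigBlock()
  hits3 <- rbind(mkHit("MAXCHI", "s1", 100, 200),
                 mkHit("RDP", "s1", 110, 210),
                 mkHit("3SEQ", "s1", 105, 195))
  evd <- refineBreakpoints(callEvents(hits3, b), b)
  expect_identical(evd$refineFlag, "unrefined")
})

test_that("rarefaction is deterministic and matches the full analysis", {
  sim <- simulateAlignment(simConfig(nStrains = 5, genomeLength = 20000,
                                     lambda = 3, seed = 12,
                                     importScope = "terminal"))
  full <- callEvents(scanAll(sim$block, seed = 99), sim$block)
  r1 <- rarefaction(sim$block, c(3, 5), nDraws = 2, seed = 99)
  r2 <- rarefaction(sim$block, c(3, 5), nDraws = 2, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$meanEvents[r1$size == 5], nrow(full))
  expect_gte(stats::cor(r1$size, r1$meanEvents, method = "spearman"), 0)
  expect_error(rarefaction(sim$block, 2), "subset sizes")
})
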