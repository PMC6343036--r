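# Five nonparametric recombination-detection scans over AlignmentBlocks.
#
# All scans share conventions: alignment columns are 0-based half-open in
# hit intervals; sites with a gap or N in any member of the examined
# pair/triplet are excluded from that test; permutation null tails are
# computed exactly (exhaustively over all site orderings) by dynamic
# programming or closed form rather than by sampling; corrected p-values
# are Bonferroni across windows and triplets (pairs for GENECONV) per
# method.

#' Polymorphic alignment columns
#'
#' @param block An [AlignmentBlock-class].
#' @return Integer vector of 0-based columns carrying at least two distinct
#'   non-gap, non-N residues.
#' @export
polymorphicSites <- function(block) {
  .polyCols(.blockMatrix(block))
}

# a column is polymorphic if two distinct nonzero codes occur
.polyCols <- function(M) {
  W <- ncol(M)
  lo <- rep.int(5L, W)
  hi <- rep.int(0L, W)
  for (i in seq_len(nrow(M))) {
    r <- M[i, ]
    nz <- r > 0L
    lo[nz] <- pmin(lo[nz], r[nz])
    hi[nz] <- pmax(hi[nz], r[nz])
  }
  which(hi > lo) - 1L  # 0-based
}

.deriveSeed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.numeric(seed) * 1009 + a * 101 + b * 7 + 12345) %%
               2147483000) + 1L
}

# informative sites of a triplet on the condensed polymorphic matrix:
# parents differ, child matches exactly one, no gap/N in any of the three.
# Mp: strains x length(P) integer codes; P: 0-based columns.
.tripletSites <- function(Mp, P, ci, ai, bi) {
  a <- Mp[ai, ]; b <- Mp[bi, ]; cc <- Mp[ci, ]
  ok <- a > 0L & b > 0L & cc > 0L & a != b & (cc == a | cc == b)
  list(cols = P[ok], labels = ifelse(cc[ok] == a[ok], 1L, 2L))
}

.chi2cell <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 <= 0 || r2 <= 0 || c1 <= 0 || c2 <= 0) return(0)
  N <- r1 + r2
  N * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
}

# exact P(max run of ones >= L) over all arrangements of a ones and b
# zeros: sequences with all one-runs < L place the a ones into the b+1
# gaps with at most L-1 each (inclusion-exclusion over violated gaps)
.maxRunPvalue <- function(a, b, L) {
  if (L > a) return(0)
  if (L <= 0) return(1)
  tot <- lchoose(a + b, b)
  p <- 0
  for (j in seq_len(min(b + 1, a %/% L))) {
    rest <- a - j * L
    term <- exp(lchoose(b + 1, j) + lchoose(rest + b, b) - tot)
    p <- p + if (j %% 2 == 1) term else -term
  }
  min(1, max(1e-300, p))
}

.emptyHits <- function() {
  data.frame(method = character(0), child = character(0),
             parentA = character(0), parentB = character(0),
             recombinant = character(0), startCol = integer(0),
             endCol = integer(0), breakpointCol = integer(0),
             stat = numeric(0), rawP = numeric(0), correctedP = numeric(0),
             nTests = integer(0), saturated = logical(0),
             stringsAsFactors = FALSE)
}

# Delimit the recombinant tract around an anchor breakpoint t1 (1-based
# site index, sites 1..k): on each side of the anchor the second edge
# maximizing the inside-vs-outside chi-squared is found, and the tract
# side is chosen by informative-site density (imported tracts are locally
# dense), then by chi-squared. Returns 1-based inclusive site indices.
.tractSegment <- function(labels, t1, cols) {
  k <- length(labels)
  pre <- c(0, cumsum(labels == 1L))
  m <- pre[k + 1]
  segChi <- function(i, j) {  # segment sites i..j (1-based inclusive)
    a <- pre[j + 1L] - pre[i]
    len <- j - i + 1
    .chi2cell(a, len - a, m - a, (k - len) - (m - a))
  }
  segDensity <- function(i, j)
    (j - i + 1) / max(1, cols[j] - cols[i] + 1)
  bestR <- NULL
  if (t1 < k) {
    cand <- (t1 + 1L):k
    chis <- vapply(cand, function(j) segChi(t1 + 1L, j), numeric(1))
    j <- cand[which.max(chis)]
    bestR <- c(max(chis), t1 + 1L, j, segDensity(t1 + 1L, j))
  }
  bestL <- NULL
  if (t1 > 1L) {
    cand <- 1L:(t1 - 1L)
    chis <- vapply(cand, function(i) segChi(i, t1), numeric(1))
    i <- cand[which.max(chis)]
    bestL <- c(max(chis), i, t1, segDensity(i, t1))
  }
  if (is.null(bestR)) return(bestL[2:3])
  if (is.null(bestL)) return(bestR[2:3])
  # the imported tract is locally dense in informative sites (donor
  # divergence nu far exceeds the clonal background), while a flank
  # segment spans sparse clonal sites: prefer the denser side, then the
  # stronger chi-squared, then the shorter segment
  pick <- if (bestL[4] > 1.5 * bestR[4]) bestL
  else if (bestR[4] > 1.5 * bestL[4]) bestR
  else if (bestR[1] > bestL[1] + 1e-9) bestR
  else if (bestL[1] > bestR[1] + 1e-9) bestL
  else if ((bestR[3] - bestR[2]) <= (bestL[3] - bestL[2])) bestR else bestL
  pick[2:3]
}

# shared window chi-squared scan used by MaxChi and Chimaera
.chiWindowScan <- function(sites, labels, w, alpha, tripletFactor,
                           method, strains) {
  k <- length(sites)
  hits <- .emptyHits()
  if (k < 4 || length(unique(labels)) < 2) {
    attr(hits, "nTests") <- 0L
    attr(hits, "skip") <- "too few informative sites"
    return(hits)
  }
  if (k <= w) {
    starts <- 1L
    wlen <- k
  } else {
    step <- max(1L, w %/% 4L)
    starts <- unique(c(seq(1L, k - w + 1L, by = step), k - w + 1L))
    wlen <- w
  }
  nW <- length(starts)
  recs <- lapply(seq_along(starts), function(wi) {
    s <- starts[wi]; e <- s + wlen - 1L
    lab <- labels[s:e]
    m <- sum(lab == 1L); n <- length(lab) - m
    if (m == 0L || n == 0L)
      return(list(s = s, e = e, stat = 0, p = 1, sat = FALSE))
    res <- cpp_max_chi2(lab)
    # exact permutation p: exhaustive over all site orderings by DP
    p <- cpp_maxchi_scan_pvalue(m, n, res$stat)
    list(s = s, e = e, stat = res$stat, p = p, sat = FALSE)
  })
  pRaw <- vapply(recs, `[[`, numeric(1), "p")
  corr <- pmin(1, pRaw * nW * tripletFactor)
  sig <- which(corr < alpha)
  if (length(sig)) {
    # per significant window, extract the anchored breakpoint-pair
    # segment; overlapping segments (adjacent windows seeing the same
    # tract, or a tract split across windows) are merged into one hit
    segs <- lapply(sig, function(wi) {
      g <- recs[[wi]]
      # anchor at the window's strongest breakpoint, then delimit the
      # tract over the full informative-site sequence (a tract larger
      # than one window is still delimited whole)
      t1 <- g$s - 1L + cpp_max_chi2(labels[g$s:g$e])$breakpoint
      seg <- .tractSegment(labels, t1, sites)
      list(from = sites[seg[1]], to = sites[seg[2]] + 1L,
           bp = sites[t1],
           stat = g$stat, p = g$p, sat = g$sat)
    })
    o <- order(vapply(segs, `[[`, numeric(1), "from"))
    segs <- segs[o]
    merged <- list(segs[[1]])
    for (sgm in segs[-1]) {
      last <- merged[[length(merged)]]
      if (sgm$from < last$to) {  # overlap in columns
        last$to <- max(last$to, sgm$to)
        if (sgm$p < last$p) { last$p <- sgm$p; last$bp <- sgm$bp }
        last$stat <- max(last$stat, sgm$stat)
        last$sat <- last$sat || sgm$sat
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- sgm
    }
    rows <- lapply(merged, function(g) data.frame(
      method = method, child = strains[1],
      parentA = strains[2], parentB = strains[3],
      recombinant = NA_character_,
      startCol = g$from, endCol = g$to, breakpointCol = g$bp,
      stat = g$stat, rawP = g$p,
      correctedP = min(1, g$p * nW * tripletFactor),
      nTests = nW, saturated = g$sat, stringsAsFactors = FALSE))
    hits <- do.call(rbind, rows)
  }
  attr(hits, "nTests") <- nW
  hits
}

#' MaxChi sliding-window scan of a triplet
#'
#' Over windows of `windowSites` consecutive informative sites (columns
#' where the two parents differ and the child matches exactly one), each
#' site is classified as child-matches-parentA or child-matches-parentB;
#' for every internal breakpoint the 2x2 (matches-A/matches-B x left/right)
#' Pearson chi-squared is formed and the window statistic is its maximum.
#' Significance is the proportion of site-order permutations (add-one
#' corrected) whose maximum reaches the observed value; saturated windows
#' fall back to an exact hypergeometric Bonferroni bound over breakpoints.
#' Overlapping significant windows are merged and each merged hit carries
#' the breakpoint-pair interval that maximizes the inside-versus-outside
#' chi-squared, plus the single argmax breakpoint.
#'
#' @param block An [AlignmentBlock-class].
#' @param child,parentA,parentB Strain names forming the triplet.
#' @param windowSites Informative sites per window (default 210).
#' @param alpha Significance threshold on the Bonferroni-corrected p.
#' @param tripletFactor Extra Bonferroni multiplier applied by [scanAll()]
#'   for the number of triplets examined (default 1).
#' @return A `data.frame` of hits (0-based half-open `startCol`/`endCol`),
#'   with attribute `nTests` (windows examined).
#' @export
maxchiScan <- function(block, child, parentA, parentB, windowSites = 210L,
                       alpha = 0.001, tripletFactor = 1) {
  if (windowSites < 4) stop("windowSites must be >= 4")
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  .maxchiScanM(M, P, block, child, parentA, parentB, windowSites, alpha,
               tripletFactor)
}

.maxchiScanM <- function(M, P, block, child, parentA, parentB, windowSites,
                         alpha, tripletFactor) {
  idx <- match(c(child, parentA, parentB), strainNames(block))
  if (anyNA(idx)) stop("triplet strains not all present in block")
  Mp <- M[, P + 1L, drop = FALSE]
  ts <- .tripletSites(Mp, P, idx[1], idx[2], idx[3])
  .chiWindowScan(ts$cols, ts$labels, as.integer(windowSites), alpha,
                 tripletFactor, "MAXCHI", c(child, parentA, parentB))
}

#' Chimaera-style scan of a triplet
#'
#' As [maxchiScan()], but the per-site indicator records which parent the
#' child differs from (restricted to columns where it differs from exactly
#' one), and the default window is the method's conventional 60 variable
#' sites rather than MaxChi's configured 210.
#'
#' @inheritParams maxchiScan
#' @return A `data.frame` of hits with attribute `nTests`.
#' @export
chimaeraScan <- function(block, child, parentA, parentB, windowSites = 60L,
                         alpha = 0.001, tripletFactor = 1) {
  if (windowSites < 4) stop("windowSites must be >= 4")
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  .chimaeraScanM(M, P, block, child, parentA, parentB, windowSites, alpha,
                 tripletFactor)
}

.chimaeraScanM <- function(M, P, block, child, parentA, parentB, windowSites,
                           alpha, tripletFactor) {
  idx <- match(c(child, parentA, parentB), strainNames(block))
  if (anyNA(idx)) stop("triplet strains not all present in block")
  Mp <- M[, P + 1L, drop = FALSE]
  ts <- .tripletSites(Mp, P, idx[1], idx[2], idx[3])
  # differs-from indicator: 1 = differs from parentA (matches B), 2 = from B
  lab <- 3L - ts$labels
  .chiWindowScan(ts$cols, lab, as.integer(windowSites), alpha,
                 tripletFactor, "CHIMAERA", c(child, parentA, parentB))
}

#' RDP-style sliding-window scan of a triplet
#'
#' Slides a window of `windowNt` alignment columns over the triplet's
#' complete-case columns, computes the three pairwise identities per window
#' and flags maximal runs of windows in which the genome-wide closest pair
#' is not the locally closest. Each region's p-value is a two-sided
#' binomial tail for the observed child-parent matches in the region given
#' that pair's genome-wide match probability, Bonferroni-corrected for the
#' windows examined.
#'
#' @inheritParams maxchiScan
#' @param windowNt Window width in alignment columns (default 90).
#' @return A `data.frame` of candidate hits with attribute `nTests`.
#' @export
rdpScan <- function(block, child, parentA, parentB, windowNt = 90L,
                    alpha = 0.001, tripletFactor = 1) {
  if (windowNt < 10) stop("windowNt must be >= 10")
  M <- .blockMatrix(block)
  .rdpScanM(M, block, child, parentA, parentB, windowNt, tripletFactor)
}

.rdpScanM <- function(M, block, child, parentA, parentB, windowNt,
                      tripletFactor) {
  idx <- match(c(child, parentA, parentB), strainNames(block))
  if (anyNA(idx)) stop("triplet strains not all present in block")
  W <- ncol(M)
  hits <- .emptyHits()
  if (windowNt > W) {
    attr(hits, "nTests") <- 0L
    attr(hits, "skip") <- "window longer than block"
    return(hits)
  }
  ci <- M[idx[1], ]; ai <- M[idx[2], ]; bi <- M[idx[3], ]
  ok <- ci > 0L & ai > 0L & bi > 0L
  cumOK <- c(0, cumsum(ok))
  mmCA <- which(ok & ci != ai); mmCB <- which(ok & ci != bi)
  mmAB <- which(ok & ai != bi)
  totOK <- sum(ok)
  if (totOK < windowNt) {
    attr(hits, "nTests") <- 0L
    attr(hits, "skip") <- "too few complete columns"
    return(hits)
  }
  gid <- c(CA = 1 - length(mmCA) / totOK, CB = 1 - length(mmCB) / totOK,
           AB = 1 - length(mmAB) / totOK)
  globalClosest <- which.max(gid)
  step <- max(1L, as.integer(windowNt) %/% 3L)
  starts <- unique(c(seq(0L, W - windowNt, by = step), W - windowNt))
  ends <- starts + as.integer(windowNt)
  nOK <- cumOK[ends + 1L] - cumOK[starts + 1L]
  cnt <- function(pos) findInterval(ends, pos) - findInterval(starts, pos)
  mm <- rbind(CA = cnt(mmCA), CB = cnt(mmCB), AB = cnt(mmAB))
  lid <- 1 - sweep(mm, 2, pmax(nOK, 1), "/")
  localClosest <- apply(lid, 2, which.max)
  discord <- nOK >= 10 & localClosest != globalClosest
  nW <- length(starts)
  attr(hits, "nTests") <- nW
  if (!any(discord)) return(hits)
  r <- rle(discord)
  endsIdx <- cumsum(r$lengths)
  startsIdx <- endsIdx - r$lengths + 1L
  regions <- which(r$values)
  # pair used for the binomial model: the child-parent pair that is
  # genome-wide closest (falling back to child-parentA)
  pairName <- if (globalClosest == 2L) "CB" else "CA"
  q <- gid[pairName]
  mmPos <- if (pairName == "CA") mmCA else mmCB
  lo <- starts[startsIdx[regions]]
  hi <- ends[endsIdx[regions]]
  nReg <- cumOK[hi + 1L] - cumOK[lo + 1L]
  kMis <- findInterval(hi, mmPos) - findInterval(lo, mmPos)
  kMatch <- nReg - kMis
  pLo <- stats::pbinom(kMatch, nReg, q)
  pHi <- stats::pbinom(kMatch - 1, nReg, q, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(pLo, pHi))
  out <- data.frame(method = "RDP", child = child, parentA = parentA,
                    parentB = parentB, recombinant = NA_character_,
                    startCol = lo, endCol = hi, breakpointCol = lo,
                    stat = 1 - kMatch / pmax(1, nReg), rawP = p,
                    correctedP = pmin(1, p * nW * tripletFactor),
                    nTests = nW, saturated = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "nTests") <- nW
  out
}

#' GENECONV-style inner-fragment scan of a strain pair
#'
#' Condenses the block to its polymorphic columns and, for the pair, finds
#' the maximal run of consecutive condensed columns at which the two
#' sequences agree (a mismatch-free inner fragment; g-scale 0). The score
#' is the run length in condensed columns; significance is the permutation
#' tail of the maximum run over random shuffles of condensed column order,
#' extended by an exact union bound over run positions when the observed
#' run exceeds every permutation draw.
#'
#' @param block An [AlignmentBlock-class].
#' @param strain1,strain2 The pair examined.
#' @param nPerm Sets the reported p-value floor `1/(nPerm+1)` for the
#'   degenerate saturated case (pair identical at all polymorphic sites).
#' @param pairFactor Bonferroni multiplier for the number of pairs
#'   examined (default 1).
#' @return A `data.frame` with the maximal-run hit (or no rows), attribute
#'   `nTests`.
#' @export
geneconvScan <- function(block, strain1, strain2, nPerm = 1999L,
                         pairFactor = 1) {
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  .geneconvScanM(M, P, block, strain1, strain2, nPerm, pairFactor)
}

.geneconvScanM <- function(M, P, block, strain1, strain2, nPerm,
                           pairFactor) {
  idx <- match(c(strain1, strain2), strainNames(block))
  if (anyNA(idx)) stop("pair strains not present in block")
  hits <- .emptyHits()
  if (length(P) < 2) {
    attr(hits, "nTests") <- 0L
    return(hits)
  }
  x <- M[idx[1], P + 1L]; y <- M[idx[2], P + 1L]
  keep <- x > 0L & y > 0L
  cols <- P[keep]
  agree <- as.integer(x[keep] == y[keep])
  s <- length(agree)
  if (s < 2) {
    attr(hits, "nTests") <- 0L
    return(hits)
  }
  a <- sum(agree)
  run <- cpp_max_run(agree)
  attr(hits, "nTests") <- 1L
  if (run$len == 0) return(hits)
  saturatedPair <- run$len == s
  p <- if (saturatedPair) 1 / (nPerm + 1)
  else .maxRunPvalue(a, s - a, run$len)
  from <- cols[run$from + 1L]
  to <- cols[run$to]
  out <- data.frame(method = "GENECONV", child = strain1,
                    parentA = strain2, parentB = NA_character_,
                    recombinant = NA_character_,
                    startCol = from, endCol = to + 1L, breakpointCol = from,
                    stat = run$len, rawP = p,
                    correctedP = min(1, p * pairFactor), nTests = 1L,
                    saturated = saturatedPair, stringsAsFactors = FALSE)
  attr(out, "nTests") <- 1L
  out
}

#' 3Seq-style maximum-descent test of a triplet
#'
#' Walks over the triplet's informative sites (+1 when the child matches
#' parentA, -1 when it matches parentB). The statistic is the maximum
#' descent, symmetrized over descent and ascent so parent labelling is
#' immaterial; its p-value is computed exactly by dynamic programming over
#' all orderings of the up- and down-steps (summing the two directional
#' tails), Bonferroni-corrected for the triplets examined.
#'
#' @inheritParams maxchiScan
#' @return A `data.frame` with the maximal-descent hit (or no rows),
#'   attribute `nTests`.
#' @export
threeseqTest <- function(block, child, parentA, parentB, tripletFactor = 1) {
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  .threeseqTestM(M, P, block, child, parentA, parentB, tripletFactor)
}

.threeseqTestM <- function(M, P, block, child, parentA, parentB,
                           tripletFactor) {
  idx <- match(c(child, parentA, parentB), strainNames(block))
  if (anyNA(idx)) stop("triplet strains not all present in block")
  Mp <- M[, P + 1L, drop = FALSE]
  ts <- .tripletSites(Mp, P, idx[1], idx[2], idx[3])
  hits <- .emptyHits()
  attr(hits, "nTests") <- 1L
  if (length(ts$cols) < 1) return(hits)
  steps <- ifelse(ts$labels == 1L, 1L, -1L)
  m <- sum(steps == 1L); n <- sum(steps == -1L)
  # a one-sided walk is pure drift: no descent signal in either direction
  if (m == 0L || n == 0L) return(hits)
  dsc <- cpp_descent(steps)
  asc <- cpp_descent(-steps)
  stat <- max(dsc$stat, asc$stat)
  if (stat <= 0) return(hits)
  # tail of the symmetrized statistic (union bound over both directions);
  # a cheap Monte-Carlo screen avoids the exact DP when the tail is large
  tailP <- function(mu, nd, d) {
    if (d <= 0) return(1)
    if (nd < d) return(0)
    if (d <= nd - mu) return(1)  # every arrangement descends this far
    if (as.numeric(mu) * nd * d > 2e6) {
      exc <- cpp_descent_mc(mu, nd, as.integer(d), 999L,
                            .deriveSeed(mu, nd, d))
      if (exc >= 5) return((1 + exc) / 1000)
    }
    cpp_descent_pvalue(mu, nd, as.integer(d), maxOps = 5e7)$p
  }
  p <- min(1, tailP(m, n, stat) + tailP(n, m, stat))
  use <- if (dsc$stat >= asc$stat) dsc else asc
  # trim the descent's argmax region to its chi-squared-optimal edges
  lo <- use$from + 1L; hi <- use$to + 1L
  if (hi - lo + 1L >= 4L) {
    seg <- cpp_anchored_segment(ts$labels[lo:hi])
    from <- ts$cols[lo + seg$from]
    to <- ts$cols[lo + seg$to - 1L]
  } else {
    from <- ts$cols[lo]
    to <- ts$cols[hi]
  }
  out <- data.frame(method = "3SEQ", child = child, parentA = parentA,
                    parentB = parentB, recombinant = NA_character_,
                    startCol = from, endCol = to + 1L, breakpointCol = from,
                    stat = stat, rawP = p,
                    correctedP = min(1, p * tripletFactor), nTests = 1L,
                    saturated = FALSE, stringsAsFactors = FALSE)
  attr(out, "nTests") <- 1L
  out
}

# genome-wide pairwise divergence matrix (complete-case per pair);
# mismatches can only occur at polymorphic columns, so only those are
# compared directly
.globalDivergence <- function(M, P = .polyCols(M)) {
  n <- nrow(M)
  W <- ncol(M)
  Mp <- M[, P + 1L, drop = FALSE]
  zero <- lapply(seq_len(n), function(i) which(M[i, ] == 0L))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- Mp[i, ] > 0L & Mp[j, ] > 0L
    mm <- sum(Mp[i, ok] != Mp[j, ok])
    nOK <- W - length(union(zero[[i]], zero[[j]]))
    D[i, j] <- D[j, i] <- mm / max(1, nOK)
  }
  D
}

# locally most diverged member of a hit's strain set, relative to its
# genome-wide divergence: the recombinant under an external-donor model
.assignRecombinant <- function(M, block, strains, startCol, endCol,
                               globalDiv = NULL) {
  idx <- match(strains, strainNames(block))
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2) return(strains[1])
  if (is.null(globalDiv)) globalDiv <- .globalDivergence(M)
  Ms <- M[, (startCol + 1L):endCol, drop = FALSE]
  exc <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    rest <- idx[-k]
    mean(vapply(rest, function(j) {
      ok <- Ms[i, ] > 0L & Ms[j, ] > 0L
      if (!sum(ok)) return(NA_real_)
      sum(Ms[i, ok] != Ms[j, ok]) / sum(ok) - globalDiv[i, j]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  strains[which.max(exc)]
}

#' Run all detection methods over a block
#'
#' Enumerates every triplet (each strain as candidate recombinant child
#' with every unordered parent pair) for the triplet methods and every
#' strain pair for GENECONV, applies the configured scans, Bonferroni-
#' corrects p-values across triplets x windows per method, and assigns to
#' each hit a recombinant strain: the member of the examined strain set
#' whose divergence from the others inside the hit interval most exceeds
#' its genome-wide divergence (under an external-donor import the
#' recombinant is locally the odd sequence out).
#'
#' @param block An [AlignmentBlock-class].
#' @param methods Subset of `c("RDP","GENECONV","MAXCHI","CHIMAERA","3SEQ")`.
#' @param settings Named list overriding defaults: `rdpWindowNt` (90),
#'   `maxchiWindowSites` (210), `chimaeraWindowSites` (60), `nPerm` (1999).
#' @param alpha Corrected-p significance threshold (default 0.001).
#' @param seed Integer seed driving all permutation nulls.
#' @return A `data.frame` of method hits with Bonferroni-corrected
#'   p-values; attribute `nTests` holds the per-method test counts.
#' @examples
#' sim <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 5000,
#'                                    mu = 0.01, lambda = 0, seed = 2))
#' hits <- scanAll(sim$block, seed = 2)
#' nrow(hits[hits$correctedP < 0.001, ])
#' @export
scanAll <- function(block,
                    methods = c("RDP", "GENECONV", "MAXCHI", "CHIMAERA",
                                "3SEQ"),
                    settings = list(), alpha = 0.001, seed = 1L) {
  known <- c("RDP", "GENECONV", "MAXCHI", "CHIMAERA", "3SEQ")
  if (!all(methods %in% known))
    stop("unknown method name: ",
         paste(setdiff(methods, known), collapse = ", "))
  set <- list(rdpWindowNt = 90L, maxchiWindowSites = 210L,
              chimaeraWindowSites = 60L, nPerm = 1999L)
  bad <- setdiff(names(settings), names(set))
  if (length(bad)) stop("unknown settings: ", paste(bad, collapse = ", "))
  set[names(settings)] <- settings
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  strains <- strainNames(block)
  n <- length(strains)
  if (n < 3) stop("block must contain at least 3 strains")
  trips <- list()
  for (ci in seq_len(n)) {
    rest <- setdiff(seq_len(n), ci)
    pr <- utils::combn(rest, 2)
    for (j in seq_len(ncol(pr)))
      trips[[length(trips) + 1L]] <- c(ci, pr[1, j], pr[2, j])
  }
  nTrip <- length(trips)
  pairs <- utils::combn(n, 2)
  nPair <- ncol(pairs)
  out <- list()
  for (tvec in trips) {
    cs <- strains[tvec[1]]; as_ <- strains[tvec[2]]; bs <- strains[tvec[3]]
    if ("MAXCHI" %in% methods)
      out[[length(out) + 1L]] <-
        .maxchiScanM(M, P, block, cs, as_, bs, set$maxchiWindowSites,
                     alpha, nTrip)
    if ("CHIMAERA" %in% methods)
      out[[length(out) + 1L]] <-
        .chimaeraScanM(M, P, block, cs, as_, bs, set$chimaeraWindowSites,
                       alpha, nTrip)
    if ("RDP" %in% methods)
      out[[length(out) + 1L]] <-
        .rdpScanM(M, block, cs, as_, bs, set$rdpWindowNt, nTrip)
    if ("3SEQ" %in% methods)
      out[[length(out) + 1L]] <-
        .threeseqTestM(M, P, block, cs, as_, bs, nTrip)
  }
  if ("GENECONV" %in% methods) {
    for (j in seq_len(nPair))
      out[[length(out) + 1L]] <-
        .geneconvScanM(M, P, block, strains[pairs[1, j]],
                       strains[pairs[2, j]], set$nPerm, nPair)
  }
  hits <- do.call(rbind, c(out, list(.emptyHits())))
  rownames(hits) <- NULL
  # the recombinant is judged over all strains, not only the examined
  # pair/triplet: the locally most diverged strain is the imported one
  sig <- which(hits$correctedP < alpha)
  if (length(sig)) {
    D <- .globalDivergence(M, P)
    for (i in sig) {
      hits$recombinant[i] <- .assignRecombinant(M, block, strains,
                                                hits$startCol[i],
                                                hits$endCol[i], D)
    }
  }
  attr(hits, "nTriplets") <- nTrip
  attr(hits, "settings") <- set
  hits
}
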