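# Consensus event calling, breakpoint refinement and event characterization.

.reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Call consensus recombination events from method hits
#'
#' Hits below the corrected-p threshold that share a recombinant strain and
#' reciprocally overlap by at least 50% are clustered (single linkage);
#' clusters supported by at least `minMethods` distinct methods become
#' events. The event interval is the union of the supporting hit
#' intervals; genome coordinates are obtained for the recombinant strain
#' via [columnToGenome()], and the GC fraction of the recombinant's event
#' sequence is recorded.
#'
#' @param hits Hit table from [scanAll()].
#' @param block The scanned [AlignmentBlock-class].
#' @param minMethods Minimum distinct supporting methods (default 3).
#' @param alpha Corrected-p threshold (default 0.001).
#' @return A `data.frame` of events: `recombinant`, alignment interval
#'   (`startCol`/`endCol`, 0-based half-open), genome interval
#'   (`startBp`/`endBp`, 0-based half-open), `sizeBp`, supporting
#'   `methods` (comma-separated), `nMethods`, the best-supported triplet,
#'   the worst supporting corrected p (`pMax`), GC fraction, and a
#'   `refined` flag.
#' @export
callEvents <- function(hits, block, minMethods = 3L, alpha = 0.001) {
  empty <- data.frame(recombinant = character(0), startCol = integer(0),
                      endCol = integer(0), startBp = integer(0),
                      endBp = integer(0), sizeBp = integer(0),
                      methods = character(0), nMethods = integer(0),
                      pMax = numeric(0), child = character(0),
                      parentA = character(0), parentB = character(0),
                      gc = numeric(0), refined = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(empty)
  h <- hits[hits$correctedP < alpha & !is.na(hits$recombinant), ,
            drop = FALSE]
  if (!nrow(h)) return(empty)
  out <- list()
  for (rec in unique(h$recombinant)) {
    hr <- h[h$recombinant == rec, , drop = FALSE]
    k <- nrow(hr)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j && .reciprocalOverlap(hr$startCol[i], hr$endCol[i],
                                      hr$startCol[j], hr$endCol[j]) >= 0.5) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    for (cl in unique(comp)) {
      m <- hr[comp == cl, , drop = FALSE]
      meths <- sort(unique(m$method))
      if (length(meths) < minMethods) next
      # robust consensus interval: median of supporting hit edges (one
      # method's overlong segment cannot inflate the event)
      sc <- as.integer(round(stats::median(m$startCol)))
      ec <- as.integer(round(stats::median(m$endCol)))
      if (ec <= sc) { sc <- min(m$startCol); ec <- max(m$endCol) }
      # triplet for refinement: prefer hits that view the recombinant as
      # a parent (the child's allegiance switch delimits the tract)
      best <- m[!is.na(m$parentB), , drop = FALSE]
      pref <- best[best$child != rec &
                     (best$parentA == rec | best$parentB == rec), ,
                   drop = FALSE]
      if (nrow(pref)) best <- pref
      best <- if (nrow(best)) best[which.min(best$correctedP), ] else
        m[which.min(m$correctedP), ]
      if (!is.na(best$parentB) && best$parentB == rec) {
        tmp <- best$parentA
        best$parentA <- best$parentB
        best$parentB <- tmp
      }
      # worst per-method support: max over methods of that method's best p
      pm <- vapply(meths, function(mm)
        min(m$correctedP[m$method == mm]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        recombinant = rec, startCol = sc, endCol = ec,
        startBp = NA_integer_, endBp = NA_integer_, sizeBp = NA_integer_,
        methods = paste(meths, collapse = ","),
        nMethods = length(meths), pMax = max(pm),
        child = best$child, parentA = best$parentA, parentB = best$parentB,
        gc = NA_real_, refined = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  .eventCoords(ev, block)
}

# fill genome coordinates, size and GC for event rows
.eventCoords <- function(ev, block) {
  for (i in seq_len(nrow(ev))) {
    rec <- ev$recombinant[i]
    s0 <- columnToGenome(block, rec, ev$startCol[i])
    e0 <- columnToGenome(block, rec, ev$endCol[i] - 1L) + 1L
    lo <- min(s0, e0 - 1L); hi <- max(s0 + 1L, e0)
    ev$startBp[i] <- lo
    ev$endBp[i] <- hi
    ev$sizeBp[i] <- hi - lo
    seq <- Biostrings::subseq(block@seqs[[match(rec, strainNames(block))]],
                              ev$startCol[i] + 1L, ev$endCol[i])
    fr <- Biostrings::alphabetFrequency(seq)
    acgt <- sum(fr[c("A", "C", "G", "T")])
    ev$gc[i] <- if (acgt > 0) sum(fr[c("G", "C")]) / acgt else NA_real_
  }
  rownames(ev) <- NULL
  ev
}

#' Refine event breakpoints by MaxChi maximization
#'
#' Re-runs the MaxChi breakpoint-pair maximization for each unrefined
#' event within its interval padded by 10% of the interval length on each
#' side, using the event's best-supported triplet, and replaces the event
#' interval with the two argmax breakpoints. Events with no usable
#' informative sites in the padded window are returned unrefined with
#' `refineFlag = "unrefined"`. Refinement is idempotent: already refined
#' events are returned unchanged.
#'
#' @param events Event table from [callEvents()].
#' @param block The [AlignmentBlock-class] the events were called on.
#' @return The event table with updated intervals and a `refineFlag`
#'   column.
#' @export
refineBreakpoints <- function(events, block) {
  if (!nrow(events)) {
    events$refineFlag <- character(0)
    return(events)
  }
  if (is.null(events$refineFlag)) events$refineFlag <- NA_character_
  M <- .blockMatrix(block)
  P <- .polyCols(M)
  W <- alnWidth(block)
  for (i in seq_len(nrow(events))) {
    if (isTRUE(events$refined[i])) next
    if (is.na(events$parentB[i])) {
      events$refineFlag[i] <- "unrefined"
      next
    }
    span <- events$endCol[i] - events$startCol[i]
    pad <- as.integer(ceiling(0.1 * span))
    lo <- max(0L, events$startCol[i] - pad)
    hi <- min(W, events$endCol[i] + pad)
    idx <- match(c(events$child[i], events$parentA[i], events$parentB[i]),
                 strainNames(block))
    # informative sites over the whole block; the breakpoint anchor is
    # maximized inside the padded event window, the second edge over the
    # full site sequence (flank context is needed to delimit the tract)
    Mp <- M[, P + 1L, drop = FALSE]
    ts <- .tripletSites(Mp, P, idx[1], idx[2], idx[3])
    inWin <- which(ts$cols >= lo & ts$cols < hi)
    if (length(inWin) < 4 ||
        length(unique(ts$labels[inWin])) < 2) {
      events$refineFlag[i] <- "unrefined"
      next
    }
    bpWin <- cpp_max_chi2(ts$labels[inWin])$breakpoint
    t1 <- inWin[1] - 1L + bpWin
    seg <- .tractSegment(ts$labels, t1, ts$cols)
    from <- ts$cols[seg[1]]
    to <- ts$cols[seg[2]]
    # a refined interval that abandons the consensus interval indicates a
    # degenerate maximization (e.g. a flank segment); keep the consensus
    ok <- to > from &&
      .reciprocalOverlap(from, to + 1L, events$startCol[i],
                         events$endCol[i]) >= 0.2
    if (!ok) {
      events$refineFlag[i] <- "unrefined"
      next
    }
    events$startCol[i] <- from
    events$endCol[i] <- to + 1L
    events$refined[i] <- TRUE
    events$refineFlag[i] <- "refined"
  }
  .eventCoords(events, block)
}

#' Summarize recombination events for a species
#'
#' Computes the characterization variables: events per strain, the
#' percentage of the core alignment affected by recombination (the union
#' over strains of recombined columns by default; the per-strain mean is
#' also reported), the event size spectrum binned at 2, 10 and 80 kb, and
#' GC content of event sequences versus whole genomes.
#'
#' @param events Event table from [callEvents()] / [refineBreakpoints()].
#' @param block The core [AlignmentBlock-class].
#' @return A list with `nEvents`, `eventsPerStrain`,
#'   `fractionRecombined` (percent, union), `fractionRecombinedMean`
#'   (percent, per-strain mean), `sizeHist`, `gcEvents`, `gcGenome`,
#'   `perStrainEvents`.
#' @export
summarizeSpecies <- function(events, block) {
  if (alnWidth(block) == 0)
    stop("undefined summary: empty alignment")
  strains <- strainNames(block)
  n <- length(strains)
  W <- alnWidth(block)
  nEv <- nrow(events)
  unionCols <- function(ev) {
    if (!nrow(ev)) return(0L)
    ir <- IRanges::reduce(IRanges::IRanges(ev$startCol + 1L, ev$endCol))
    sum(IRanges::width(ir))
  }
  perStrain <- vapply(strains, function(s)
    unionCols(events[events$recombinant == s, , drop = FALSE]), integer(1))
  fracUnion <- 100 * unionCols(events) / W
  fracMean <- 100 * mean(perStrain / W)
  bins <- c(`<2kb` = 0, `2-10kb` = 0, `10-80kb` = 0, `>80kb` = 0)
  if (nEv) {
    cutp <- cut(events$sizeBp, c(-Inf, 2000, 10000, 80000, Inf),
                labels = names(bins), right = FALSE)
    bins <- table(factor(cutp, levels = names(bins)))
    bins <- stats::setNames(as.integer(bins), names(bins))
  }
  fr <- Biostrings::alphabetFrequency(block@seqs, collapse = TRUE)
  acgt <- sum(fr[c("A", "C", "G", "T")])
  list(nEvents = nEv,
       eventsPerStrain = nEv / n,
       fractionRecombined = fracUnion,
       fractionRecombinedMean = fracMean,
       sizeHist = bins,
       gcEvents = if (nEv) mean(events$gc, na.rm = TRUE) else NA_real_,
       gcGenome = if (acgt > 0) sum(fr[c("G", "C")]) / acgt else NA_real_,
       perStrainEvents = vapply(strains, function(s)
         sum(events$recombinant == s), integer(1)))
}

#' Compare GC content of events against matched background windows
#'
#' Draws, for each event, a random background window of the same length
#' from the recombinant strain's row and compares per-event GC against the
#' background GC with a two-sided Wilcoxon rank-sum test.
#'
#' @param events Event table (>= 1 row).
#' @param block The [AlignmentBlock-class].
#' @param nBackground Background windows per event (default 10).
#' @param seed Integer seed.
#' @return A list with `gcEvents`, `gcBackground` and the rank-test `p`.
#' @export
gcCompare <- function(events, block, nBackground = 10L, seed = 1L) {
  if (!nrow(events)) stop("gcCompare requires at least one event")
  set.seed(as.integer(seed))
  W <- alnWidth(block)
  gcOf <- function(strain, s0, e0) {
    seq <- Biostrings::subseq(block@seqs[[match(strain,
                                                strainNames(block))]],
                              s0 + 1L, e0)
    fr <- Biostrings::alphabetFrequency(seq)
    acgt <- sum(fr[c("A", "C", "G", "T")])
    if (acgt > 0) sum(fr[c("G", "C")]) / acgt else NA_real_
  }
  bg <- unlist(lapply(seq_len(nrow(events)), function(i) {
    len <- events$endCol[i] - events$startCol[i]
    len <- min(len, W)
    vapply(seq_len(nBackground), function(j) {
      s <- sample.int(W - len + 1L, 1) - 1L
      gcOf(events$recombinant[i], s, s + len)
    }, numeric(1))
  }))
  p <- stats::wilcox.test(events$gc, bg, exact = FALSE)$p.value
  list(gcEvents = mean(events$gc, na.rm = TRUE),
       gcBackground = mean(bg, na.rm = TRUE), p = p)
}

#' Rarefaction of event counts over strain subsets
#'
#' Repeats detection and consensus calling on random strain subsets of the
#' requested sizes, mimicking the subset analysis used to assess sampling
#' sensitivity.
#'
#' @param block The full [AlignmentBlock-class].
#' @param subsetSizes Integer vector of subset sizes (each >= 3 and <=
#'   number of strains).
#' @param nDraws Random subsets per size (a size equal to the full strain
#'   count is evaluated once).
#' @param seed Integer seed.
#' @param minMethods,alpha Consensus parameters, as [callEvents()].
#' @param ... Passed to [scanAll()] (e.g. `settings`).
#' @return A `data.frame` with `size`, `meanEvents`, `sdEvents`.
#' @export
rarefaction <- function(block, subsetSizes, nDraws = 3L, seed = 1L,
                        minMethods = 3L, alpha = 0.001, ...) {
  n <- length(strainNames(block))
  if (any(subsetSizes < 3L) || any(subsetSizes > n))
    stop("subset sizes must be >= 3 and <= number of strains")
  set.seed(as.integer(seed))
  rows <- lapply(subsetSizes, function(sz) {
    draws <- if (sz == n) 1L else nDraws
    counts <- vapply(seq_len(draws), function(d) {
      sel <- sort(sample.int(n, sz))
      sub <- alignmentBlock(block@seqs[sel],
                            start = block@anchor$start[sel],
                            strand = block@anchor$strand[sel])
      hits <- scanAll(sub, seed = .deriveSeed(seed, sz, d), alpha = alpha,
                      ...)
      nrow(callEvents(hits, sub, minMethods = minMethods, alpha = alpha))
    }, numeric(1))
    data.frame(size = sz, meanEvents = mean(counts),
               sdEvents = if (draws > 1) stats::sd(counts) else NA_real_)
  })
  do.call(rbind, rows)
}
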