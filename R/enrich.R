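# Functional-category enrichment of genes inside events vs the genomic
# background, and enrichment-profile clustering across species.

#' Genes overlapping recombination events
#'
#' Returns the ortholog groups whose gene copy overlaps (by at least 1 bp)
#' any event of the matching strain, de-duplicated across strains.
#' Coordinates are 0-based half-open on both sides.
#'
#' @param events Event table with `recombinant`, `startBp`, `endBp`.
#' @param genes Gene table with `strain`, `gene`, `ortholog`, `start`,
#'   `end` (0-based half-open), e.g. from [simulateGeneTable()] or
#'   [readGeneTable()].
#' @return Character vector of ortholog identifiers.
#' @export
genesInEvents <- function(events, genes) {
  if (!nrow(events)) return(character(0))
  if (!any(events$recombinant %in% genes$strain))
    stop("lookup error: no event strain present in the gene table")
  hits <- character(0)
  for (st in unique(events$recombinant)) {
    g <- genes[genes$strain == st, , drop = FALSE]
    if (!nrow(g)) next
    ev <- events[events$recombinant == st, , drop = FALSE]
    gi <- IRanges::IRanges(g$start + 1L, g$end)        # to 1-based closed
    ei <- IRanges::IRanges(ev$startBp + 1L, ev$endBp)
    ov <- IRanges::countOverlaps(gi, ei, minoverlap = 1L) > 0
    hits <- c(hits, g$ortholog[ov])
  }
  unique(hits)
}

#' Build a category count table for enrichment testing
#'
#' Counts ortholog groups per functional category among event genes and
#' among the genomic background (all annotated ortholog groups not in
#' events, so the two margins are disjoint).
#'
#' @param genes Gene table (see [genesInEvents()]); each ortholog takes
#'   the category of its first-listed copy.
#' @param eventOrthologs Character vector from [genesInEvents()].
#' @param category Column holding the category label (default `"cog"`).
#' @return A `data.frame` with `category`, `eventCount`, `bgCount`, and
#'   attributes `totalEvent`, `totalBg`.
#' @export
buildCategoryTable <- function(genes, eventOrthologs, category = "cog") {
  og <- genes[!duplicated(genes$ortholog), , drop = FALSE]
  inEv <- og$ortholog %in% eventOrthologs
  cats <- sort(unique(og[[category]]))
  tab <- data.frame(
    category = cats,
    eventCount = vapply(cats, function(cc)
      sum(inEv & og[[category]] == cc), integer(1)),
    bgCount = vapply(cats, function(cc)
      sum(!inEv & og[[category]] == cc), integer(1)),
    stringsAsFactors = FALSE)
  attr(tab, "totalEvent") <- sum(inEv)
  attr(tab, "totalBg") <- sum(!inEv)
  tab
}

#' Fisher enrichment of categories in event genes
#'
#' Two-sided Fisher exact test per category on the 2x2 table
#' (in-events vs background) x (in-category vs not), with
#' Benjamini-Hochberg q-values. A category is flagged significant when
#' `p < alphaP` and `q < fdrQ` (defaults 0.05 and 0.10); direction is
#' over- or under-representation by the sample odds ratio.
#'
#' @param tab Category table from [buildCategoryTable()] (or any
#'   `data.frame` with `category`, `eventCount`, `bgCount` plus
#'   `totalEvent`/`totalBg` attributes or columns).
#' @param alphaP p-value threshold (default 0.05).
#' @param fdrQ FDR threshold (default 0.10).
#' @return The table with added `odds`, `p`, `q`, `direction`
#'   (`"over"`/`"under"`/`"none"`), `significant` and `degenerate`
#'   columns.
#' @export
fisherEnrichment <- function(tab, alphaP = 0.05, fdrQ = 0.10) {
  totalEvent <- attr(tab, "totalEvent")
  totalBg <- attr(tab, "totalBg")
  if (is.null(totalEvent)) totalEvent <- sum(tab$eventCount)
  if (is.null(totalBg)) totalBg <- sum(tab$bgCount)
  n <- nrow(tab)
  p <- odds <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    a <- tab$eventCount[i]; b <- totalEvent - a
    c2 <- tab$bgCount[i]; d <- totalBg - c2
    m <- matrix(c(a, b, c2, d), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      p[i] <- 1; odds[i] <- NA_real_; degen[i] <- TRUE
    } else {
      p[i] <- stats::fisher.test(m)$p.value
      odds[i] <- (a * d) / max(1e-12, b * c2)
      if (b == 0 || c2 == 0) odds[i] <- Inf
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  tab$odds <- odds
  tab$p <- p
  tab$q <- q
  tab$direction <- ifelse(degen | is.na(odds) | odds == 1, "none",
                          ifelse(odds > 1, "over", "under"))
  tab$significant <- !degen & p < alphaP & q < fdrQ
  tab$degenerate <- degen
  tab
}

#' Cluster species by signed enrichment profiles
#'
#' Pairwise similarity between species is the simple matching coefficient
#' of their signed enrichment profiles (entries -1/0/+1 for
#' under/none/over per category); species are grouped by average-linkage
#' hierarchical clustering of 1 - similarity. Rows are pre-sorted by label
#' so ties break deterministically.
#'
#' @param profiles Numeric matrix, species x categories, entries in
#'   \{-1, 0, 1\}, with rownames.
#' @return A list with `similarity` (matrix), `hclust`, `order` (leaf
#'   labels in dendrogram order) and `heat` (profile matrix in leaf
#'   order).
#' @export
clusterProfiles <- function(profiles) {
  if (nrow(profiles) < 2 || ncol(profiles) < 2)
    stop("need >= 2 species and >= 2 categories")
  if (!all(profiles %in% c(-1, 0, 1)))
    stop("profile entries must be -1, 0 or 1")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  n <- nrow(profiles)
  sim <- matrix(1, n, n, dimnames = list(rownames(profiles),
                                         rownames(profiles)))
  for (i in seq_len(n)) for (j in seq_len(n))
    sim[i, j] <- mean(profiles[i, ] == profiles[j, ])
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  list(similarity = sim, hclust = hc,
       order = rownames(profiles)[hc$order],
       heat = profiles[hc$order, , drop = FALSE])
}
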