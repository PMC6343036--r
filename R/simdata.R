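# Genome-evolution simulator: coalescent clonal frame, point mutations,
# imported donor tracts with recorded ground truth.

#' Simulate a neutral coalescent clonal genealogy
#'
#' Draws a standard Kingman coalescent over `nStrains` lineages: while k
#' lineages are active the waiting time to the next coalescence is
#' exponential with rate k(k-1)/2, and the coalescing pair is uniform.
#' Time is measured in coalescent units; branch lengths multiply the
#' per-unit rates `mu` and `lambda` of [simulateAlignment()].
#'
#' @param nStrains Number of lineages (>= 3). Tips are labelled
#'   `s1 ... sN`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so callers can embed the draw in a larger seeded stream).
#' @return A rooted binary [ape::phylo] tree with branch lengths.
#' @examples
#' tr <- simulateGenealogy(5, seed = 1)
#' sum(tr$edge.length)
#' @export
simulateGenealogy <- function(nStrains, seed = NULL) {
  nStrains <- as.integer(nStrains)
  if (nStrains < 3)
    stop("invalid config: nStrains must be >= 3")
  if (!is.null(seed)) set.seed(as.integer(seed))
  # active lineages as newick fragments with their heights
  lab <- paste0("s", seq_len(nStrains))
  frag <- as.list(lab)
  height <- rep(0, nStrains)
  t <- 0
  k <- nStrains
  while (k > 1) {
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2)
    i <- min(pick); j <- max(pick)
    merged <- sprintf("(%s:%.10f,%s:%.10f)",
                      frag[[i]], t - height[i], frag[[j]], t - height[j])
    frag[[i]] <- merged
    height[i] <- t
    frag[[j]] <- NULL
    height <- height[-j]
    k <- k - 1
  }
  ape::read.tree(text = paste0(frag[[1]], ";"))
}

# tips (1..n) below each node of a phylo tree, as a list indexed by node id
.tipsUnder <- function(tree) {
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- i
  # postorder: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

#' Evolve a multi-strain core alignment with recombinant imports
#'
#' Simulates sequence evolution along a coalescent clonal genealogy. The
#' ancestral sequence is uniform over \{A,C,G,T\}. On each branch of length
#' t, `Poisson(mu * t * L)` substitutions hit uniform sites (the new base is
#' uniform over the three alternatives), and `Poisson(lambda * t)`
#' recombination imports are planted: each has a uniform start, a geometric
#' tract length of mean `delta` truncated at the sequence end, and replaces
#' the tract by the current sequence independently substituted per site with
#' probability `nu` (an external-donor import carrying fresh divergence).
#' Descendant lineages inherit imported tracts. The alignment is gapless;
#' the returned [SimTruth-class] registry records every event with its
#' affected strains and realized coordinates plus a per-strain, per-site
#' origin mask.
#'
#' @param config A [SimConfig-class].
#' @return A list with elements `block` ([AlignmentBlock-class]) and
#'   `truth` ([SimTruth-class]).
#' @examples
#' sim <- simulateAlignment(simConfig(nStrains = 4, genomeLength = 2000,
#'                                    lambda = 2, seed = 3))
#' truthEvents(sim$truth)
#' @export
simulateAlignment <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  n <- config@nStrains
  L <- config@genomeLength
  tree <- simulateGenealogy(n, seed = NULL)
  below <- .tipsUnder(tree)
  eo <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  root <- n + 1L

  seqs <- vector("list", n + tree$Nnode)
  orig <- vector("list", n + tree$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  orig[[root]] <- integer(L)
  nClonal <- 0L
  ev <- list()

  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    len <- eo$edge.length[e]
    s <- seqs[[p]]
    o <- orig[[p]]
    nmut <- stats::rpois(1, config@mu * len * L)
    if (nmut > 0) {
      pos <- sample.int(L, nmut, replace = TRUE)
      s[pos] <- 1L + (s[pos] - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L
      nClonal <- nClonal + nmut
    }
    isTerminalEdge <- ch <= n
    nimp <- if (config@importScope == "terminal" && !isTerminalEdge) 0L
      else stats::rpois(1, config@lambda * len)
    if (nimp > 0) {
      for (i in seq_len(nimp)) {
        start <- sample.int(L, 1)
        tlen <- stats::rgeom(1, 1 / config@delta) + 1L
        end <- min(L, start + tlen - 1L)
        idx <- start:end
        flip <- idx[stats::runif(length(idx)) < config@nu]
        if (length(flip))
          s[flip] <- 1L + (s[flip] - 1L +
                             sample.int(3L, length(flip), replace = TRUE)) %% 4L
        id <- length(ev) + 1L
        o[idx] <- id
        ev[[id]] <- data.frame(
          event = id,
          strains = paste(sort(tree$tip.label[below[[ch]]]),
                          collapse = ","),
          start = start - 1L, end = end, length = end - start + 1L,
          nu = config@nu, stringsAsFactors = FALSE)
      }
    }
    seqs[[ch]] <- s
    orig[[ch]] <- o
    # free internal-node storage once all children are emitted
  }

  tipOrder <- order(as.integer(sub("^s", "", tree$tip.label)))
  bases <- c("A", "C", "G", "T")
  rows <- vapply(tipOrder, function(i)
    paste(bases[seqs[[i]]], collapse = ""), character(1))
  names(rows) <- tree$tip.label[tipOrder]
  block <- alignmentBlock(rows)

  mask <- do.call(rbind, lapply(tipOrder, function(i) orig[[i]]))
  rownames(mask) <- tree$tip.label[tipOrder]
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(event = integer(0), strains = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               nu = numeric(0), stringsAsFactors = FALSE)
  truth <- methods::new("SimTruth", events = events, originMask = mask,
                        nClonalMutations = as.integer(nClonal),
                        genealogy = tree, config = config)
  list(block = block, truth = truth)
}

#' Realized per-strain truth intervals
#'
#' Collapses the origin mask into the realized imported regions: for each
#' strain, maximal runs of imported sites become one interval (overlapping
#' or nested planted events are thereby unified), and identical
#' (strain-set independent) intervals shared by several strains are
#' reported once with the carrying strains listed.
#'
#' @param truth A [SimTruth-class].
#' @return A `data.frame` with `start`, `end` (0-based half-open),
#'   `strains` (comma-separated carriers of the identical interval).
#' @export
truthIntervals <- function(truth) {
  mask <- truth@originMask
  out <- list()
  for (st in rownames(mask)) {
    r <- rle(mask[st, ] != 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep)
      out[[length(out) + 1L]] <- data.frame(start = starts[k] - 1L,
                                            end = ends[k], strain = st,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strains = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  agg <- stats::aggregate(strain ~ start + end, data = df,
                          FUN = function(s) paste(sort(s), collapse = ","))
  names(agg)[3] <- "strains"
  agg[order(agg$start), , drop = FALSE]
}

#' Match called events against simulation truth
#'
#' An event matches a truth interval when the two intervals reciprocally
#' overlap by at least `minOverlap` (50% by default) in alignment
#' coordinates. Sensitivity is the fraction of truth intervals matched by
#' some event; positive predictive value is the fraction of events
#' matching some truth interval.
#'
#' @param events Event table from [callEvents()].
#' @param truth A [SimTruth-class] or the table from [truthIntervals()].
#' @param minOverlap Reciprocal-overlap threshold (default 0.5).
#' @param requireStrain Additionally require the event's recombinant to be
#'   one of the truth interval's carriers (default `FALSE`).
#' @return A list with `sensitivity`, `ppv`, `nTruth`, `nEvents`,
#'   `truthMatched` and `eventMatched` logical vectors.
#' @export
matchEvents <- function(events, truth, minOverlap = 0.5,
                        requireStrain = FALSE) {
  ti <- if (methods::is(truth, "SimTruth")) truthIntervals(truth) else truth
  nT <- nrow(ti); nE <- nrow(events)
  tm <- rep(FALSE, nT); em <- rep(FALSE, nE)
  if (nT && nE) {
    for (i in seq_len(nE)) for (j in seq_len(nT)) {
      ro <- .reciprocalOverlap(events$startCol[i], events$endCol[i],
                               ti$start[j], ti$end[j])
      okStrain <- !requireStrain ||
        events$recombinant[i] %in% strsplit(ti$strains[j], ",")[[1]]
      if (ro >= minOverlap && okStrain) {
        tm[j] <- TRUE
        em[i] <- TRUE
      }
    }
  }
  list(sensitivity = if (nT) mean(tm) else NA_real_,
       ppv = if (nE) mean(em) else NA_real_,
       nTruth = nT, nEvents = nE, truthMatched = tm, eventMatched = em)
}

#' Generate a gene-annotation fixture tied to simulation truth
#'
#' Tiles genes at fixed spacing along the simulated core alignment and
#' assigns each a COG-style functional letter. Genes overlapping a planted
#' recombination event (for the strains that carry it) receive the focal
#' category with odds multiplied by the configured enrichment odds `w`;
#' `w = 1` makes category assignment independent of the events.
#'
#' @param truth A [SimTruth-class].
#' @param geneLength Gene length in bp.
#' @param spacing Distance between consecutive gene starts in bp.
#' @param categories COG letters to draw from; the first is the focal one.
#' @param baseP Baseline probability of the focal category.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `strain`, `gene`, `ortholog`,
#'   `start`, `end` (0-based half-open), `cog`, `go`.
#' @export
simulateGeneTable <- function(truth, geneLength = 900L, spacing = 1000L,
                              categories = c("V", "J", "K", "L", "M", "N",
                                             "O", "T", "P", "G"),
                              baseP = 0.15, seed = 1L) {
  stopifnot(methods::is(truth, "SimTruth"))
  set.seed(as.integer(seed))
  L <- ncol(truth@originMask)
  strains <- rownames(truth@originMask)
  w <- truth@config@w
  starts <- seq(0L, L - geneLength, by = spacing)
  ng <- length(starts)
  ev <- truth@events
  focal <- categories[1]
  pOver <- (baseP / (1 - baseP) * w) / (1 + baseP / (1 - baseP) * w)
  # an ortholog group has one functional category shared by all copies;
  # the enrichment odds apply when any strain's copy overlaps one of that
  # strain's planted events
  hit <- logical(ng)
  if (nrow(ev)) {
    gi <- IRanges::IRanges(starts + 1L, starts + geneLength)
    for (st in strains) {
      mine <- ev[vapply(strsplit(ev$strains, ","), function(z) st %in% z,
                        logical(1)), , drop = FALSE]
      if (!nrow(mine)) next
      evi <- IRanges::IRanges(mine$start + 1L, mine$end)
      hit <- hit | IRanges::countOverlaps(gi, evi) > 0
    }
  }
  p <- ifelse(hit, pOver, baseP)
  isFocal <- stats::runif(ng) < p
  cog <- ifelse(isFocal, focal, sample(categories[-1], ng, replace = TRUE))
  out <- lapply(strains, function(st) data.frame(
    strain = st, gene = sprintf("%s_g%04d", st, seq_len(ng)),
    ortholog = sprintf("og%04d", seq_len(ng)),
    start = starts, end = starts + geneLength, cog = cog,
    go = sprintf("GO:%07d", 1000L + match(cog, categories)),
    stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.provenance <- function(config = NULL) {
  v <- as.character(utils::packageVersion("coreHR"))
  h <- if (is.null(config)) "" else
    sprintf(" seed=%d config=n%d:L%d:mu%g:lambda%g:delta%g:nu%g:w%g",
            config@seed, config@nStrains, config@genomeLength, config@mu,
            config@lambda, config@delta, config@nu, config@w)
  sprintf("# coreHR %s%s", v, h)
}

#' Write simulation fixtures to disk
#'
#' Emits the simulated alignment as a single-block XMFA (Mauve dialect) and
#' as aligned FASTA, the planted-event truth table, a gene-annotation table
#' (via [simulateGeneTable()]) and a one-row species-metadata table, all as
#' plain text with a provenance header. Coordinates in the TSV files are
#' 1-based inclusive.
#'
#' @param block An [AlignmentBlock-class].
#' @param truth The matching [SimTruth-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeFixtures <- function(block, truth, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  cfg <- truth@config
  paths <- c(
    xmfa = file.path(dir, "alignment.xmfa"),
    fasta = file.path(dir, "alignment.fasta"),
    truth = file.path(dir, "truth.tsv"),
    genes = file.path(dir, "genes.tsv"),
    species = file.path(dir, "species.tsv"),
    config = file.path(dir, "config.yaml"))
  writeXMFA(list(block), paths["xmfa"], provenance = .provenance(cfg))
  Biostrings::writeXStringSet(block@seqs, paths["fasta"], width = 80)
  tt <- truth@events
  tt1 <- transform(tt, start = start + 1L)  # 1-based inclusive on disk
  .writeTSV(tt1, paths["truth"], .provenance(cfg))
  gt <- simulateGeneTable(truth, seed = cfg@seed)
  gt1 <- transform(gt, start = start + 1L)
  .writeTSV(gt1, paths["genes"], .provenance(cfg))
  sp <- data.frame(species = "simulated", lifestyle = "commensal/free-living",
                   competent = 1L, rm_count = 4L, crispr = 1L, com_genes = 10L,
                   hgt_fraction = 0.05, n_strains = length(strainNames(block)),
                   stringsAsFactors = FALSE)
  .writeTSV(sp, paths["species"], .provenance(cfg))
  yaml::write_yaml(list(nStrains = cfg@nStrains,
                        genomeLength = cfg@genomeLength, mu = cfg@mu,
                        lambda = cfg@lambda, delta = cfg@delta, nu = cfg@nu,
                        w = cfg@w, seed = cfg@seed,
                        importScope = cfg@importScope), paths["config"])
  invisible(paths)
}

.writeTSV <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a coordinate-table fixture with controlled overlaps
#'
#' Builds a tab-delimited pairwise-alignment coordinate table (show-coords
#' dialect: ref start/end, query start/end, lengths, percent identity) whose
#' fragment geometry is controlled by `overlapSpec`, for exercising the
#' ANIb merge rules. Fragment indices in directives are 0-based.
#'
#' @param nFragments Number of fragments (>= 1).
#' @param overlapSpec Character vector of directives: `"disjoint"` (the
#'   base layout), `"contained(i in j)"` (fragment i placed strictly inside
#'   fragment j), `"overlap(i,j,bp)"` (fragment i moved to overlap fragment
#'   j by `bp` bases). A fragment may be repositioned at most once.
#' @param seed Integer seed.
#' @param path Optional output path; when given the table is written as TSV.
#' @return A `data.frame` with columns `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end`, `ref_len`, `qry_len`, `pct_identity` (1-based inclusive).
#' @export
writeCoordsFixture <- function(nFragments, overlapSpec = "disjoint",
                               seed = 1L, path = NULL) {
  if (nFragments < 1) stop("invalid config: nFragments must be >= 1")
  set.seed(as.integer(seed))
  len <- sample(300:1200, nFragments, replace = TRUE)
  gap <- sample(50:500, nFragments, replace = TRUE)
  start <- cumsum(c(1L, (len + gap)[-nFragments]))
  end <- start + len - 1L
  id <- round(stats::runif(nFragments, 80, 100), 2)
  moved <- logical(nFragments)
  for (d in overlapSpec) {
    d <- trimws(d)
    if (d == "disjoint") next
    m <- regmatches(d, regexec("^contained\\((\\d+) in (\\d+)\\)$", d))[[1]]
    if (length(m)) {
      i <- as.integer(m[2]) + 1L; j <- as.integer(m[3]) + 1L
      if (i > nFragments || j > nFragments || i == j)
        stop("invalid config: bad fragment indices in '", d, "'")
      if (moved[i]) stop("invalid config: fragment ", i - 1L,
                         " repositioned twice")
      if (end[j] - start[j] < 4L)
        stop("invalid config: container fragment too short")
      start[i] <- start[j] + 1L
      end[i] <- min(end[j] - 1L, start[i] + len[i] - 1L)
      len[i] <- end[i] - start[i] + 1L
      moved[i] <- TRUE
      next
    }
    m <- regmatches(d, regexec("^overlap\\((\\d+),(\\d+),(\\d+)\\)$", d))[[1]]
    if (length(m)) {
      i <- as.integer(m[2]) + 1L; j <- as.integer(m[3]) + 1L
      ov <- as.integer(m[4])
      if (i > nFragments || j > nFragments || i == j || ov < 1)
        stop("invalid config: bad directive '", d, "'")
      if (moved[i]) stop("invalid config: fragment ", i - 1L,
                         " repositioned twice")
      start[i] <- end[j] - ov + 1L
      end[i] <- start[i] + len[i] - 1L
      moved[i] <- TRUE
      next
    }
    stop("invalid config: unknown overlapSpec directive '", d, "'")
  }
  df <- data.frame(ref_start = start, ref_end = end, qry_start = 1L,
                   qry_end = len, ref_len = len, qry_len = len,
                   pct_identity = id)
  if (!is.null(path)) .writeTSV(df, path, "# coreHR coords fixture")
  df
}
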