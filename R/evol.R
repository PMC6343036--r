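# Moment estimators of r/m and rho/theta, and NG86 pairwise dN/dS.

#' Moment estimates of rho/theta and r/m from consensus events
#'
#' Given a core alignment and its consensus events, counts clonal
#' mutations as the complete-case polymorphic columns falling outside all
#' event intervals (m-hat), and estimates: `rhoTheta` = events per clonal
#' mutation, `nuHat` = polymorphic-site density inside event intervals,
#' `deltaHat` = mean event genome span (bp), and
#' `rM = rhoTheta * deltaHat * nuHat` (recombination-derived substitutions
#' per clonal mutation). These are moment estimates, not ClonalFrame
#' posterior estimates; they are validated by simulation recovery only.
#'
#' @param block Core [AlignmentBlock-class].
#' @param events Event table from [callEvents()].
#' @return A list with `rhoTheta`, `rM`, `deltaHat`, `nuHat`, `mHat`,
#'   `nEvents` and a `saturated` flag (`TRUE` when no clonal mutations
#'   remain and the ratios are infinite).
#' @export
estimateRecombParams <- function(block, events) {
  M <- .blockMatrix(block)
  complete <- colSums(M > 0L) == nrow(M)
  P <- .polyCols(M)
  P <- P[complete[P + 1L]]
  nEv <- nrow(events)
  if (nEv == 0) {
    return(list(rhoTheta = 0, rM = 0, deltaHat = 0, nuHat = 0,
                mHat = length(P), nEvents = 0L, saturated = FALSE))
  }
  ir <- IRanges::reduce(IRanges::IRanges(events$startCol + 1L,
                                         events$endCol))
  inside <- IRanges::countOverlaps(IRanges::IRanges(P + 1L, P + 1L),
                                   ir) > 0
  unionLen <- sum(IRanges::width(ir))
  mHat <- sum(!inside)
  nuHat <- if (unionLen > 0) sum(inside) / unionLen else 0
  deltaHat <- mean(events$sizeBp)
  saturated <- mHat == 0
  if (saturated) {
    warning("no clonal polymorphic sites outside events; ",
            "rho/theta and r/m are saturated (infinite)")
    rhoTheta <- Inf
    rM <- Inf
  } else {
    rhoTheta <- nEv / mHat
    rM <- rhoTheta * deltaHat * nuHat
  }
  list(rhoTheta = rhoTheta, rM = rM, deltaHat = deltaHat, nuHat = nuHat,
       mHat = mHat, nEvents = nEv, saturated = saturated)
}

# per-codon NG86 site counts and pairwise difference counts --------------

.ng86Env <- new.env(parent = emptyenv())

.ng86Tables <- function() {
  if (!is.null(.ng86Env$tab)) return(.ng86Env$tab)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  syn <- numeric(length(codons))
  names(syn) <- codons
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn[cd] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      nSyn <- 0; nValid <- 0
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- b
        if (gc[[alt]] == "*") next  # mutations to stops excluded
        nValid <- nValid + 1
        if (gc[[alt]] == gc[[cd]]) nSyn <- nSyn + 1
      }
      if (nValid > 0) s <- s + nSyn / nValid
    }
    syn[cd] <- s
  }
  .ng86Env$tab <- list(code = gc, syn = syn)
  .ng86Env$tab
}

# classify the single-step change c1 -> c2 (differ at one position):
# returns c(sd, nd)
.stepClass <- function(c1, c2, code) {
  if (code[[c1]] == code[[c2]]) c(1, 0) else c(0, 1)
}

# average (Sd, Nd) over all minimal mutational pathways between two codons,
# excluding pathways through stop codons (all paths through stops: fall
# back to including them)
.pathCounts <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(0, 0))
  perms <- .allPerms(k)
  paths <- list()
  for (ord in perms) {
    cur <- c1
    chain <- character(0)
    for (p in pos[ord]) {
      substr(cur, p, p) <- substr(c2, p, p)
      chain <- c(chain, cur)
    }
    paths[[length(paths) + 1L]] <- chain
  }
  viable <- vapply(paths, function(ch)
    !any(code[ch[-length(ch)]] == "*"), logical(1))
  if (!any(viable)) viable <- rep(TRUE, length(paths))
  acc <- c(0, 0)
  nv <- 0
  for (i in seq_along(paths)) {
    if (!viable[i]) next
    chain <- c(c1, paths[[i]])
    sdnd <- c(0, 0)
    for (s in seq_len(length(chain) - 1))
      sdnd <- sdnd + .stepClass(chain[s], chain[s + 1], code)
    acc <- acc + sdnd
    nv <- nv + 1
  }
  acc / nv
}

.allPerms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .allPerms(k - 1)
    for (r in rest) out[[length(out) + 1L]] <-
        c(i, ifelse(r >= i, r + 1L, r))
  }
  out
}

#' NG86 pairwise dN/dS for a codon alignment
#'
#' Nei-Gojobori (1986) pathway counting: potential synonymous sites per
#' codon are the per-position fractions of non-stop single-nucleotide
#' neighbours that preserve the amino acid; observed differences at
#' multi-step codons are averaged over all minimal mutational pathways
#' that avoid stop codons. Proportions are Jukes-Cantor corrected,
#' `dX = -3/4 log(1 - 4/3 pX)`. Codons containing a gap, `N`, or a stop in
#' either sequence are excluded.
#'
#' @param seq1,seq2 Equal-length coding sequences (character strings,
#'   length divisible by 3).
#' @return A list with `N`, `S` (potential sites, averaged over the two
#'   sequences), `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `dNdS` (`NA` when
#'   `dS` is 0 or undefined) and `codons` used.
#' @examples
#' ng86Pairwise("GTTGCT", "GTAGCT")  # one synonymous difference
#' @export
ng86Pairwise <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2) || nchar(seq1) %% 3 != 0)
    stop("sequences must have equal length divisible by 3")
  tab <- .ng86Tables()
  nc <- nchar(seq1) / 3
  N <- S <- Nd <- Sd <- 0
  used <- 0
  for (i in seq_len(nc)) {
    c1 <- substr(seq1, 3 * i - 2, 3 * i)
    c2 <- substr(seq2, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (tab$code[[c1]] == "*" || tab$code[[c2]] == "*") next
    used <- used + 1
    s1 <- tab$syn[[c1]]; s2 <- tab$syn[[c2]]
    S <- S + (s1 + s2) / 2
    N <- N + 3 - (s1 + s2) / 2
    if (c1 != c2) {
      sdnd <- .pathCounts(c1, c2, tab$code)
      Sd <- Sd + sdnd[1]
      Nd <- Nd + sdnd[2]
    }
  }
  if (used == 0) stop("no comparable codons")
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  dNdS <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS, dN = dN, dS = dS,
       dNdS = dNdS, codons = used)
}

#' Mean pairwise dN/dS across ortholog pairs
#'
#' @param ratios Either a numeric vector of per-gene dN/dS ratios (NA =
#'   undefined) or a list of [ng86Pairwise()] results.
#' @return A list with `meanDnds` (mean over defined ratios; `NA` if none)
#'   and `nUndefined`.
#' @export
speciesDnds <- function(ratios) {
  if (is.list(ratios) && !is.null(ratios[[1]]$dNdS))
    ratios <- vapply(ratios, `[[`, numeric(1), "dNdS")
  ratios <- as.numeric(ratios)
  def <- ratios[!is.na(ratios)]
  list(meanDnds = if (length(def)) mean(def) else NA_real_,
       nUndefined = sum(is.na(ratios)))
}
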