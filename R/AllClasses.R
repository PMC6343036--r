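#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @useDynLib coreHR, .registration = TRUE
NULL

#' AlignmentBlock: a gap-aware multi-strain aligned region
#'
#' An `AlignmentBlock` holds one locally colinear block (LCB) of a
#' multi-strain whole-genome alignment: equal-length aligned rows over
#' \{A,C,G,T,-,N\} stored as a [Biostrings::DNAStringSet], plus a per-strain
#' anchor giving the 1-based genome start and strand of the ungapped
#' sequence. Rows are stored in alignment orientation; minus-strand rows are
#' reverse-complemented relative to the genome.
#'
#' Internally all column arithmetic is 0-based half-open; file readers and
#' writers convert to/from the 1-based inclusive conventions of XMFA and
#' coordinate files.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width aligned rows,
#'   named by strain identifier.
#' @slot anchor A `data.frame` with columns `strain`, `start` (1-based
#'   genome coordinate of the first aligned base) and `strand` (`"+"` or
#'   `"-"`), one row per strain in row order of `seqs`.
#' @export
setClass("AlignmentBlock",
  representation(seqs = "DNAStringSet", anchor = "data.frame"))

setValidity("AlignmentBlock", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character(0)
  if (length(w) > 0 && length(unique(w)) != 1)
    msg <- c(msg, "all aligned rows must have equal length")
  nm <- names(object@seqs)
  if (length(object@seqs) > 0 && (is.null(nm) || anyDuplicated(nm)))
    msg <- c(msg, "rows must carry unique strain names")
  if (!all(c("strain", "start", "strand") %in% names(object@anchor)))
    msg <- c(msg, "anchor must have columns strain, start, strand")
  else {
    if (!identical(as.character(object@anchor$strain), as.character(nm)))
      msg <- c(msg, "anchor strains must match row names in order")
    if (!all(object@anchor$strand %in% c("+", "-")))
      msg <- c(msg, "anchor strand must be '+' or '-'")
    if (any(object@anchor$start < 1))
      msg <- c(msg, "anchor start must be >= 1 (1-based)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentBlock
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   equal-length aligned rows.
#' @param start Integer vector of 1-based genome start positions, recycled.
#' @param strand Character vector of `"+"`/`"-"`, recycled.
#' @return An [AlignmentBlock-class] object.
#' @examples
#' b <- alignmentBlock(c(s1 = "ACGT", s2 = "A-GT"))
#' alnWidth(b)
#' @export
alignmentBlock <- function(seqs, start = 1L, strand = "+") {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  anchor <- data.frame(
    strain = as.character(names(seqs)),
    start = as.integer(rep_len(start, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE)
  methods::new("AlignmentBlock", seqs = seqs, anchor = anchor)
}

#' @describeIn alignmentBlock Strain identifiers of a block.
#' @param x An `AlignmentBlock`.
#' @export
strainNames <- function(x) names(x@seqs)

#' @describeIn alignmentBlock Alignment width (number of columns).
#' @export
alnWidth <- function(x) {
  if (length(x@seqs) == 0) 0L else Biostrings::width(x@seqs)[1]
}

#' @describeIn alignmentBlock Per-strain anchor table.
#' @export
blockAnchor <- function(x) x@anchor

#' @describeIn alignmentBlock Aligned rows as a DNAStringSet.
#' @export
blockSeqs <- function(x) x@seqs

setMethod("show", "AlignmentBlock", function(object) {
  cat("AlignmentBlock:", length(object@seqs), "strains x",
      alnWidth(object), "columns\n")
  if (length(object@seqs)) {
    cat("  strains:", paste(utils::head(strainNames(object), 6),
                            collapse = ", "),
        if (length(object@seqs) > 6) "..." else "", "\n")
  }
})

# integer-coded alignment matrix: A,C,G,T -> 1..4; gap/N/other -> 0
.blockMatrix <- function(block) {
  m <- as.matrix(block@seqs)
  code <- matrix(0L, nrow(m), ncol(m))
  code[m == "A"] <- 1L
  code[m == "C"] <- 2L
  code[m == "G"] <- 3L
  code[m == "T"] <- 4L
  rownames(code) <- rownames(m)
  code
}

#' SimConfig: parameters of the genome-evolution simulator
#'
#' Holds the parameters of the clonal-frame simulator: a neutral coalescent
#' genealogy over `nStrains` lineages, point mutations at rate `mu` per site
#' per unit branch length, recombination imports at rate `lambda` per unit
#' branch length with geometric tract lengths of mean `delta`, donor
#' divergence `nu` (per-site substitution probability applied to imported
#' tracts), and functional-category enrichment odds `w` used when gene
#' annotation fixtures are generated.
#'
#' @slot nStrains Integer number of strains (>= 3).
#' @slot genomeLength Integer alignment length in bp.
#' @slot mu Mutation rate per site per unit branch length.
#' @slot lambda Recombination import rate per unit branch length.
#' @slot delta Mean imported tract length in bp (geometric).
#' @slot nu Per-site substitution probability inside imported tracts.
#' @slot w Relative odds that an import-overlapping gene carries the focal
#'   functional category.
#' @slot seed Integer seed; identical configs give byte-identical output.
#' @export
setClass("SimConfig",
  representation(nStrains = "integer", genomeLength = "integer",
                 mu = "numeric", lambda = "numeric", delta = "numeric",
                 nu = "numeric", w = "numeric", seed = "integer",
                 importScope = "character"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nStrains < 3) msg <- c(msg, "nStrains must be >= 3")
  if (object@genomeLength <= 0) msg <- c(msg, "genomeLength must be > 0")
  if (object@mu < 0 || object@lambda < 0)
    msg <- c(msg, "mu and lambda must be >= 0")
  if (object@nu < 0 || object@nu > 0.75)
    msg <- c(msg, "nu must lie in [0, 0.75]")
  if (object@delta < 1) msg <- c(msg, "delta must be >= 1")
  if (object@w <= 0) msg <- c(msg, "w must be > 0")
  if (!object@importScope %in% c("branch", "terminal"))
    msg <- c(msg, "importScope must be 'branch' or 'terminal'")
  if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' Defaults describe the package's reference simulation: 8 strains, a
#' 100 kb core alignment, low clonal mutation rate, and imported tracts of
#' mean 2 kb carrying 8% donor divergence.
#'
#' @param nStrains Number of strains (>= 3).
#' @param genomeLength Alignment length in bp.
#' @param mu Substitutions per site per unit branch length.
#' @param lambda Imports per unit branch length.
#' @param delta Mean tract length (bp) of the geometric tract-length law.
#' @param nu Per-site divergence of imported tracts, in [0, 0.75].
#' @param w Category-enrichment odds for annotation fixtures (1 = none).
#' @param seed Integer seed.
#' @param importScope `"branch"` (imports occur on every branch of the
#'   genealogy and are inherited by whole clades) or `"terminal"` (imports
#'   are planted on terminal branches only, so each event affects a single
#'   strain). Clade-level imports on deep branches are statistically
#'   confounded with clonal divergence and are largely unrecoverable by
#'   triplet scans; terminal planting is the controlled setting used to
#'   benchmark event recovery.
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(nStrains = 4, genomeLength = 1000, seed = 7)
#' @export
simConfig <- function(nStrains = 8L, genomeLength = 100000L, mu = 0.002,
                      lambda = 1, delta = 2000, nu = 0.08, w = 1,
                      seed = 1L, importScope = c("branch", "terminal")) {
  importScope <- match.arg(importScope)
  methods::new("SimConfig", nStrains = as.integer(nStrains),
               genomeLength = as.integer(genomeLength), mu = as.numeric(mu),
               lambda = as.numeric(lambda), delta = as.numeric(delta),
               nu = as.numeric(nu), w = as.numeric(w),
               seed = as.integer(seed), importScope = importScope)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d strains, %d bp | mu=%g lambda=%g delta=%g nu=%g w=%g seed=%d\n",
    object@nStrains, object@genomeLength, object@mu, object@lambda,
    object@delta, object@nu, object@w, object@seed))
})

#' SimTruth: ground-truth registry of a simulation
#'
#' Records every planted recombination event (affected strains, 0-based
#' half-open coordinates, realized length, donor divergence), the per-strain
#' per-site origin mask (0 = clonal, k = imported by event k; later events on
#' the same lineage overwrite earlier ones site-wise), the number of clonal
#' substitutions drawn, and the clonal genealogy.
#'
#' @slot events `data.frame` with columns `event`, `strains`
#'   (comma-separated), `start`, `end` (0-based half-open), `length`, `nu`.
#' @slot originMask Integer matrix (strains x sites); 0 marks clonal sites.
#' @slot nClonalMutations Integer count of clonal substitution draws.
#' @slot genealogy An [ape::phylo] rooted binary tree with branch lengths.
#' @slot config The generating [SimConfig-class].
#' @export
setClass("SimTruth",
  representation(events = "data.frame", originMask = "matrix",
                 nClonalMutations = "integer", genealogy = "ANY",
                 config = "SimConfig"))

#' @describeIn simulateAlignment Planted-event table of a [SimTruth-class].
#' @param truth A `SimTruth`.
#' @export
truthEvents <- function(truth) truth@events

#' @describeIn simulateAlignment Per-strain per-site origin mask
#'   (0 = clonal, k = event id).
#' @export
originMask <- function(truth) truth@originMask

#' @describeIn simulateAlignment Clonal genealogy (`phylo`).
#' @export
truthGenealogy <- function(truth) truth@genealogy

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@events), "planted events,",
      object@nClonalMutations, "clonal mutations,",
      nrow(object@originMask), "strains x", ncol(object@originMask),
      "sites\n")
})
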