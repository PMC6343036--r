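# Alignment and table I/O: XMFA (Mauve dialect), aligned FASTA,
# show-coords-style coordinate tables, gene presence/absence tables.

#' Read an XMFA alignment
#'
#' Parses the Mauve XMFA dialect: blocks of FASTA records with headers
#' `> seqid:start-end strand [comment]`, each block terminated by a line
#' starting with `=`. Rows whose header strand is `-` are stored in genome
#' orientation in the file and are reverse-complemented into alignment
#' orientation on reading; anchors (1-based genome start, strand) are
#' preserved.
#'
#' @param path Path to an XMFA file.
#' @return A list of [AlignmentBlock-class] objects, one per block.
#' @seealso [writeXMFA()]
#' @export
readXMFA <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- list()   # per-row: id, start, end, strand, seq chunks
  flushRow <- function(state) state
  rows <- list()
  rowOpen <- FALSE
  id <- start <- end <- strand <- NULL
  chunks <- character(0)
  closeRow <- function() {
    if (rowOpen)
      rows[[length(rows) + 1L]] <<- list(id = id, start = start,
                                         strand = strand,
                                         seq = paste(chunks, collapse = ""))
    rowOpen <<- FALSE
    chunks <<- character(0)
  }
  closeBlock <- function(lineno) {
    closeRow()
    if (!length(rows)) return()
    ids <- vapply(rows, `[[`, character(1), "id")
    if (anyDuplicated(ids))
      stop("XMFA format error at line ", lineno,
           ": duplicate strain in one block")
    seqs <- vapply(rows, `[[`, character(1), "seq")
    if (length(unique(nchar(seqs))) != 1)
      stop("XMFA format error at line ", lineno,
           ": rows of unequal length in block")
    strands <- vapply(rows, `[[`, character(1), "strand")
    starts <- vapply(rows, `[[`, numeric(1), "start")
    aln <- Biostrings::DNAStringSet(seqs)
    names(aln) <- ids
    neg <- strands == "-"
    if (any(neg))
      aln[neg] <- Biostrings::reverseComplement(aln[neg])
    blocks[[length(blocks) + 1L]] <<-
      alignmentBlock(aln, start = as.integer(starts), strand = strands)
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    if (grepl("^=", ln)) { closeBlock(i); next }
    if (grepl("^>", ln)) {
      closeRow()
      m <- regexec("^>\\s*(\\S+):(\\d+)-(\\d+)\\s+(\\S+)", ln)
      g <- regmatches(ln, m)[[1]]
      if (length(g) != 5)
        stop("XMFA format error at line ", i, ": malformed header '",
             ln, "'")
      if (!g[5] %in% c("+", "-"))
        stop("XMFA format error at line ", i, ": unknown strand token '",
             g[5], "'")
      id <- g[2]; start <- as.numeric(g[3]); end <- as.numeric(g[4])
      strand <- g[5]
      rowOpen <- TRUE
    } else {
      if (!rowOpen)
        stop("XMFA format error at line ", i, ": sequence outside a record")
      chunks <- c(chunks, gsub("\\s", "", ln))
    }
  }
  closeBlock(length(lines))
  blocks
}

#' Write a list of AlignmentBlocks as XMFA
#'
#' Inverse of [readXMFA()]: minus-strand rows are reverse-complemented back
#' into genome orientation before writing.
#'
#' @param blocks List of [AlignmentBlock-class] objects.
#' @param path Output path.
#' @param provenance Optional `#` comment line(s) written at the top.
#' @export
writeXMFA <- function(blocks, path, provenance = .provenance()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  for (b in blocks) {
    a <- b@anchor
    seqs <- b@seqs
    for (i in seq_along(seqs)) {
      nlen <- alnWidth(b) - Biostrings::vcountPattern("-", seqs[i])
      end <- a$start[i] + nlen - 1L
      writeLines(sprintf("> %s:%d-%d %s", a$strain[i], a$start[i], end,
                         a$strand[i]), con)
      s <- seqs[i]
      if (a$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      writeLines(as.character(s), con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Extract the core alignment
#'
#' Keeps the blocks that are aligned for all genomes over at least
#' `minLen` bp: every strain of the full strain universe is present, every
#' row contributes at least one non-gap character and is at most 50% gaps
#' (a guard against sparsely aligned rows), and the block alignment length
#' is `>= minLen`.
#'
#' @param blocks List of [AlignmentBlock-class] objects.
#' @param minLen Minimum alignment length in bp (default 500).
#' @param maxGapFrac Maximum per-row gap fraction (default 0.5).
#' @return The retained blocks (possibly an empty list).
#' @export
extractCore <- function(blocks, minLen = 500L, maxGapFrac = 0.5) {
  if (minLen < 1) stop("minLen must be >= 1")
  if (!length(blocks)) return(list())
  universe <- unique(unlist(lapply(blocks, strainNames)))
  keep <- vapply(blocks, function(b) {
    if (!all(universe %in% strainNames(b))) return(FALSE)
    w <- alnWidth(b)
    if (w < minLen) return(FALSE)
    gaps <- Biostrings::vcountPattern("-", b@seqs)
    all(gaps < w) && all(gaps / w <= maxGapFrac)
  }, logical(1))
  blocks[keep]
}

#' Map an alignment column to a genome coordinate
#'
#' Returns the 0-based genome position, for `strain`, of the non-gap
#' character at (or immediately left of) 0-based alignment `column`.
#' Strand-aware: on `-` rows positions decrease as columns increase.
#'
#' @param block An [AlignmentBlock-class].
#' @param strain Strain identifier.
#' @param column 0-based alignment column (scalar or vector).
#' @return 0-based genome position(s).
#' @export
columnToGenome <- function(block, strain, column) {
  i <- match(strain, strainNames(block))
  if (is.na(i)) stop("strain '", strain, "' not present in block")
  w <- alnWidth(block)
  if (any(column < 0 | column >= w)) stop("column out of range")
  chars <- strsplit(as.character(block@seqs[[i]]), "")[[1]]
  nonGap <- cumsum(chars != "-")
  cnt <- pmax(nonGap[column + 1L], 1L)  # left-fill before first residue
  start0 <- block@anchor$start[i] - 1L
  ungapped <- nonGap[w]
  if (block@anchor$strand[i] == "+") start0 + cnt - 1L
  else start0 + ungapped - cnt
}

#' Read a tab-delimited coordinate table
#'
#' Parses show-coords-style tab-separated tables with columns ref start/end,
#' query start/end, ref/query lengths and percent identity. Leading header
#' or comment lines (anything whose first field is not numeric) are
#' skipped; strand is normalized so `ref_end >= ref_start`.
#'
#' @param path Path to the coords file.
#' @return A `data.frame` with columns `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end`, `ref_len`, `qry_len`, `pct_identity` (1-based inclusive).
#' @export
readCoords <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^#", ln)) next
    f <- strsplit(ln, "\t|\\s+")[[1]]
    if (!grepl("^-?[0-9]", f[1])) next  # header line
    if (length(f) < 7)
      stop("coords format error at line ", i, ": expected >= 7 fields")
    v <- suppressWarnings(as.numeric(f[1:7]))
    if (any(is.na(v)))
      stop("coords format error at line ", i, ": malformed numeric field")
    out[[length(out) + 1L]] <- v
  }
  m <- if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 7)
  df <- data.frame(ref_start = m[, 1], ref_end = m[, 2], qry_start = m[, 3],
                   qry_end = m[, 4], ref_len = m[, 5], qry_len = m[, 6],
                   pct_identity = m[, 7])
  flip <- df$ref_end < df$ref_start
  if (any(flip)) {
    tmp <- df$ref_start[flip]
    df$ref_start[flip] <- df$ref_end[flip]
    df$ref_end[flip] <- tmp
  }
  if (any(df$pct_identity < 0 | df$pct_identity > 100))
    stop("coords error: pct_identity outside [0, 100]")
  df
}

#' Partition a gene presence matrix into core and accessory sets
#'
#' @param presence Logical matrix, genes x strains.
#' @return A list with character vectors `core` (genes present in all
#'   strains) and `accessory` (the complement).
#' @export
partitionPangenome <- function(presence) {
  if (!is.matrix(presence) || !nrow(presence))
    stop("presence must be a non-empty genes x strains matrix")
  if (any(rowSums(presence) == 0))
    stop("every gene must be present in at least one strain")
  core <- rownames(presence)[rowSums(presence) == ncol(presence)]
  list(core = core,
       accessory = setdiff(rownames(presence), core))
}

#' Read a gene-annotation table
#'
#' Reads the TSV emitted by [writeFixtures()] (strain, gene, ortholog,
#' 1-based inclusive coordinates, COG letter, GO terms), converting
#' coordinates to the internal 0-based half-open convention.
#'
#' @param path Path to the gene TSV.
#' @return A `data.frame` with 0-based half-open `start`/`end`.
#' @export
readGeneTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("strain", "gene", "start", "end", "cog")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df$start <- df$start - 1L  # to 0-based half-open
  df
}
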