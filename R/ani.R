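# ANIb from pairwise alignment coordinate tables: fragment containment
# filter, >10% overlap join, size-weighted identity.

#' Merge alignment fragments by the ANIb rules
#'
#' Applies, on the reference frame and until a fixpoint is reached:
#' (1) fragments wholly contained in a larger fragment are removed;
#' (2) two fragments whose overlap exceeds `overlapFrac` (default 10%) of
#' the shorter fragment's length (set `frame = "longer"` for the laxer
#' reading) are joined into one spanning fragment whose identity is the
#' length-weighted mean of the two, overlap bases counted once. Fragments
#' are processed left-to-right by start coordinate.
#'
#' @param fragments A `data.frame` with columns `ref_start`, `ref_end`
#'   (1-based inclusive) and `pct_identity`, e.g. from [readCoords()].
#' @param overlapFrac Overlap fraction triggering a join (default 0.10).
#' @param frame Whether the fraction refers to the `"shorter"` (default)
#'   or `"longer"` fragment of the pair.
#' @return The merged fragment table, sorted by `ref_start`.
#' @export
mergeFragments <- function(fragments, overlapFrac = 0.10,
                           frame = c("shorter", "longer")) {
  frame <- match.arg(frame)
  df <- fragments[order(fragments$ref_start, -fragments$ref_end), ,
                  drop = FALSE]
  repeat {
    n <- nrow(df)
    if (n < 2) break
    len <- df$ref_end - df$ref_start + 1
    # containment filter
    drop <- rep(FALSE, n)
    for (i in seq_len(n - 1)) {
      if (drop[i]) next
      for (j in seq_len(n)) {
        if (i == j || drop[j]) next
        if (df$ref_start[j] >= df$ref_start[i] &&
            df$ref_end[j] <= df$ref_end[i] && len[j] < len[i])
          drop[j] <- TRUE
      }
    }
    if (any(drop)) {
      df <- df[!drop, , drop = FALSE]
      next
    }
    # left-to-right join of the first qualifying overlap
    joined <- FALSE
    for (i in seq_len(n - 1)) {
      j <- i + 1
      ov <- min(df$ref_end[i], df$ref_end[j]) -
        max(df$ref_start[i], df$ref_start[j]) + 1
      if (ov <= 0) next
      ref <- if (frame == "shorter") min(len[i], len[j]) else
        max(len[i], len[j])
      if (ov > overlapFrac * ref) {
        id <- (len[i] * df$pct_identity[i] + len[j] * df$pct_identity[j]) /
          (len[i] + len[j])
        df$ref_end[i] <- max(df$ref_end[i], df$ref_end[j])
        df$ref_start[i] <- min(df$ref_start[i], df$ref_start[j])
        df$pct_identity[i] <- id
        df <- df[-j, , drop = FALSE]
        joined <- TRUE
        break
      }
    }
    if (!joined) break
    df <- df[order(df$ref_start, -df$ref_end), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' ANIb: size-weighted average nucleotide identity
#'
#' Computes the average of the fragment identities weighted by fragment
#' length, after applying the [mergeFragments()] join/containment rules.
#'
#' @param fragments Fragment table as in [mergeFragments()].
#' @param merge Apply the merge rules first (default `TRUE`).
#' @param ... Passed to [mergeFragments()].
#' @return Percent identity (scalar).
#' @examples
#' anib(data.frame(ref_start = c(1, 2001), ref_end = c(100, 2300),
#'                 pct_identity = c(90, 98)))
#' @export
anib <- function(fragments, merge = TRUE, ...) {
  df <- if (merge) mergeFragments(fragments, ...) else fragments
  if (!nrow(df)) stop("undefined ANI: no fragments after merging")
  len <- df$ref_end - df$ref_start + 1
  sum(len * df$pct_identity) / sum(len)
}

#' Pairwise ANIb matrix from per-pair coordinate tables
#'
#' @param coords A `data.frame` with columns `ref`, `qry` and either
#'   `path` (coords file read via [readCoords()]) or a list-column
#'   `fragments` of fragment tables; one row per directional comparison.
#' @param ... Passed to [anib()].
#' @return A symmetric matrix of ANIb values; a pair with both directions
#'   available gets the mean of the two, a pair with no data is `NA`.
#' @export
anibMatrix <- function(coords, ...) {
  strains <- sort(unique(c(coords$ref, coords$qry)))
  m <- matrix(NA_real_, length(strains), length(strains),
              dimnames = list(strains, strains))
  diag(m) <- 100
  vals <- vapply(seq_len(nrow(coords)), function(i) {
    fr <- if (!is.null(coords$fragments)) coords$fragments[[i]] else
      readCoords(coords$path[i])
    anib(fr, ...)
  }, numeric(1))
  for (a in strains) for (b in strains) {
    if (a >= b) next
    v <- vals[(coords$ref == a & coords$qry == b) |
                (coords$ref == b & coords$qry == a)]
    if (length(v)) m[a, b] <- m[b, a] <- mean(v)
  }
  m
}

#' Write an ANIb matrix as TSV
#' @param m Matrix from [anibMatrix()].
#' @param path Output path.
#' @export
writeAnibMatrix <- function(m, path) {
  df <- data.frame(strain = rownames(m), m, check.names = FALSE)
  .writeTSV(df, path, .provenance())
  invisible(path)
}
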