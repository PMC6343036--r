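# shared fixture builders (everything is generated in code)

# an AlignmentBlock from plain character rows
mkBlock <- function(..., start = 1L, strand = "+") {
  rows <- c(...)
  if (is.null(names(rows)))
    names(rows) <- paste0("s", seq_along(rows))
  alignmentBlock(rows, start = start, strand = strand)
}

# a triplet block whose polymorphic columns carry prescribed alleles:
# parents differ at every listed column; the child matches parentA where
# childMatchesA is TRUE. Padding columns are monomorphic 'A'.
mkTripletBlock <- function(childMatchesA, spacing = 5L, extraRows = 0L) {
  k <- length(childMatchesA)
  W <- (k + 1L) * spacing
  a <- rep("A", W); b <- rep("A", W); cc <- rep("A", W)
  cols <- seq_len(k) * spacing
  a[cols] <- "C"
  b[cols] <- "G"
  cc[cols] <- ifelse(childMatchesA, "C", "G")
  rows <- c(child = paste(cc, collapse = ""),
            pa = paste(a, collapse = ""),
            pb = paste(b, collapse = ""))
  if (extraRows > 0)
    rows <- c(rows, stats::setNames(rep(paste(rep("A", W), collapse = ""),
                                        extraRows),
                                    paste0("x", seq_len(extraRows))))
  list(block = alignmentBlock(rows), cols = cols - 1L)  # 0-based
}

# brute-force max chi-squared over breakpoints of a 1/2 label vector
bruteMaxChi <- function(lab) {
  k <- length(lab)
  chi <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
    (r1 + r2) * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  }
  m <- sum(lab == 1)
  best <- 0
  for (t in 1:(k - 1)) {
    a <- sum(lab[1:t] == 1); b <- t - a
    best <- max(best, chi(a, b, m - a, (k - t) - (m - a)))
  }
  best
}

# brute-force maximum descent of a +/-1 step vector
bruteDescent <- function(steps) {
  h <- cumsum(steps)
  best <- 0
  runmax <- 0
  for (i in seq_along(h)) {
    runmax <- max(runmax, h[i])
    best <- max(best, runmax - h[i])
  }
  best
}

# all arrangements of m ones and n twos (for exhaustive nulls)
allLabelings <- function(m, n) {
  pos <- utils::combn(m + n, m)
  lapply(seq_len(ncol(pos)), function(j) {
    lab <- rep(2L, m + n)
    lab[pos[, j]] <- 1L
    lab
  })
}
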