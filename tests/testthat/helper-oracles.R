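# Independent brute-force oracles used to freeze expected values.

# Smith-Waterman local alignment (match +2, mismatch -3, gap open -5,
# gap extend -2, affine), returning the best score and the subject end
# coordinate of the best cell. O(nm) dynamic programming, independent of the
# package's alignment path.
local_align_oracle <- function(query, subject) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)     # gap in subject (consume query)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in query (consume subject)
  best <- 0; best_j <- NA_integer_
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (q[i - 1] == s[j - 1]) 2 else -3
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - 5 - 2, X[i - 1, j] - 2)
      Y[i, j] <- max(M[i, j - 1] - 5 - 2, Y[i, j - 1] - 2)
      sc <- max(M[i, j], X[i, j], Y[i, j])
      if (sc > best) { best <- sc; best_j <- j - 1 }
    }
  }
  list(score = best, subject_end = best_j)
}

# Column-majority consensus oracle: per column, the most frequent non-gap
# base (ties alphabetical, recorded); gap-majority columns dropped.
consensus_oracle <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- character(0); ties <- integer(0); kept <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (sum(col == "-") > length(col) / 2) next
    counts <- vapply(c("A", "C", "G", "U"), function(b) sum(col == b), numeric(1))
    w <- names(counts)[counts == max(counts)]
    keep <- c(keep, w[1]); kept <- c(kept, j)
    if (length(w) > 1) ties <- c(ties, j)
  }
  list(representative = paste(keep, collapse = ""), ties = ties, kept = kept)
}

# Textbook sums of squares for a balanced two-way layout.
ss_oracle <- function(y, A, B) {
  gm <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(y, interaction(A, B), mean)
  nc <- tapply(y, interaction(A, B), length)
  ssCells <- sum(nc * (cell - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - ave(y, interaction(A, B)))^2)
  list(A = ssA, B = ssB, AB = ssAB, E = ssE)
}
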