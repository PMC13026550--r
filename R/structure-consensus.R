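#' Build a family-representative consensus sequence from an alignment
#'
#' At each alignment column the most frequent non-gap nucleotide is selected.
#' Columns in which gaps hold a strict majority are dropped from the
#' representative. Ties between nucleotides are broken alphabetically
#' (A < C < G < U) and the tied columns are recorded, mirroring the black-dot
#' convention used when displaying family representatives.
#'
#' @param aligned Character vector of aligned sequences (equal length, RNA
#'   alphabet, `-` for gaps), or a character matrix (rows = members).
#' @return A `consensus_result`: list with `representative` (string),
#'   `ties` (integer vector of original alignment columns with ties),
#'   `kept_columns` (original column indices retained) and `freq` (symbol x
#'   column count matrix).
#' @export
build_consensus <- function(aligned) {
  if (is.matrix(aligned)) {
    mat <- toupper(aligned)
  } else {
    if (!length(aligned)) stop("empty alignment", call. = FALSE)
    widths <- nchar(aligned)
    if (length(unique(widths)) != 1L) stop("alignment rows differ in length", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  }
  if (!nrow(mat) || !ncol(mat)) stop("empty alignment", call. = FALSE)
  mat[mat == "T"] <- "U"
  symbols <- c("A", "C", "G", "U", "-")
  n <- nrow(mat)
  freq <- apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = symbols), nbins = length(symbols))
  })
  rownames(freq) <- symbols

  gap_major <- unname(freq["-", ] > n / 2)
  kept <- which(!gap_major)
  rep_chars <- character(length(kept))
  ties <- integer(0)
  base_freq <- freq[RNA_BASES, , drop = FALSE]
  for (i in seq_along(kept)) {
    col <- kept[i]
    counts <- base_freq[, col]
    m <- max(counts)
    winners <- RNA_BASES[counts == m]
    rep_chars[i] <- winners[1L] # alphabetical tie-break (A < C < G < U)
    if (length(winners) > 1L) ties <- c(ties, col)
  }
  structure(
    list(
      representative = chars_seq(rep_chars),
      ties = ties, kept_columns = kept, freq = freq
    ),
    class = "consensus_result"
  )
}
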