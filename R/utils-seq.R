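# Low-level sequence helpers. Introns are handled internally as RNA strings
# (A/C/G/U), genomes as DNA; conversion happens at I/O boundaries.

RNA_BASES <- c("A", "C", "G", "U")

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_seq <- function(v) paste(v, collapse = "")

#' @noRd
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

rc_map <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Reverse complement of an RNA string
#' @noRd
revcomp_rna <- function(x) {
  chars_seq(rev(unname(rc_map[seq_chars(toupper(x))])))
}

comp_rna <- function(x) {
  chars_seq(unname(rc_map[seq_chars(toupper(x))]))
}

# Watson-Crick (optionally G.U wobble) pairing test, vectorised over bases.
pairs_with <- function(a, b, wobble = FALSE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (wobble) {
    wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  }
  wc
}

#' Match a sequence against an IUPAC degenerate pattern of the same length
#' @noRd
iupac_match <- function(seq, pattern) {
  s <- seq_chars(toupper(seq))
  p <- seq_chars(toupper(pattern))
  if (length(s) != length(p)) return(FALSE)
  all(vapply(seq_along(s), function(i) s[i] %in% IUPAC_RNA[[p[i]]], logical(1L)))
}

# Random RNA string drawn from the current RNG stream.
rand_rna <- function(n, bases = RNA_BASES) {
  chars_seq(sample(bases, n, replace = TRUE))
}

# Jukes-Cantor-like point substitution: every site flips with probability p
# to one of the three other bases, uniformly. Positions in `protect` use
# p * protect_factor (purifying selection on constrained sites).
mutate_rna <- function(x, p, protect = integer(0), protect_factor = 0.1) {
  if (p <= 0 || nchar(x) == 0L) return(x)
  v <- seq_chars(x)
  pp <- rep(p, length(v))
  if (length(protect)) pp[protect] <- p * protect_factor
  hit <- which(runif(length(v)) < pp)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(RNA_BASES, b), 1L), character(1L))
  }
  chars_seq(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards, so seeded operations never perturb each other.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
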