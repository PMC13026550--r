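# Rule-based annotation of intron secondary structure from dot-bracket.

# Pairing partner for every position of a dot-bracket string (NA = unpaired).
pair_map <- function(dot_bracket) {
  v <- seq_chars(dot_bracket)
  n <- length(v)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i, call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (v[i] != ".") {
      stop("dot-bracket contains illegal character '", v[i], "'", call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('", call. = FALSE)
  partner
}

# Intervals [start, end] of the top-level helices (children of the exterior loop).
top_level_helices <- function(partner, dot_bracket) {
  v <- seq_chars(dot_bracket)
  out <- NULL
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (v[i] == "(") {
      j <- partner[i]
      out <- rbind(out, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Parse the domain layout of a group II intron from its dot-bracket structure
#'
#' Enumerates the top-level helices of the structure (the stems radiating from
#' the exterior "wheel" between the terminal motifs) 5' to 3'. Six helices are
#' labelled DI..DVI. Seven helices with the extra element in fourth position
#' (between DIII and DIV) yield the non-canonical seven-domain layout and the
#' extra stem-loop is labelled DIIIa. For five or eight helices the 5' and 3'
#' anchors (DI, DII and DV, DVI) are assigned positionally from the ends and
#' the middle elements are labelled in order, on the rationale that DV/DVI are
#' positionally invariant; such layouts are flagged `noncanonical`.
#'
#' @param sequence Intron RNA string.
#' @param dot_bracket Dot-bracket string, same length, balanced.
#' @return An object of class `domain_layout`: list with `domains` (data.frame
#'   of domain, start, end), `linker` (interval or NULL), `accessory` (named
#'   list of intervals, filled by the caller or generator truth), `partner`
#'   (pairing map), `dot_bracket`, `noncanonical` flag.
#' @export
parse_domains <- function(sequence, dot_bracket) {
  if (nchar(sequence) != nchar(dot_bracket)) {
    stop("sequence and dot-bracket lengths differ", call. = FALSE)
  }
  partner <- pair_map(dot_bracket)
  hel <- top_level_helices(partner, dot_bracket)
  k <- if (is.null(hel)) 0L else nrow(hel)
  if (k < 5L || k > 8L) {
    stop("layout error: ", k, " top-level helices (expected 5-8)", call. = FALSE)
  }
  noncanonical <- FALSE
  labels <- switch(as.character(k),
    "6" = c("DI", "DII", "DIII", "DIV", "DV", "DVI"),
    "7" = c("DI", "DII", "DIII", "DIIIa", "DIV", "DV", "DVI"),
    "5" = {
      noncanonical <- TRUE
      c("DI", "DII", "DIII", "DV", "DVI")
    },
    "8" = {
      noncanonical <- TRUE
      c("DI", "DII", "DIII", "DIIIa", "DIV", "extra", "DV", "DVI")
    }
  )
  domains <- data.frame(
    domain = labels, start = hel[, 1L], end = hel[, 2L],
    stringsAsFactors = FALSE
  )
  # Linker: unpaired prefix before the first helix, beyond the 5' hexamer.
  term <- detect_terminal_elements(sequence)
  linker <- if (!is.na(term$linker_len) && term$linker_len > 0L) {
    c(1L, term$linker_len)
  } else NULL
  structure(
    list(
      domains = domains, linker = linker, accessory = list(),
      partner = partner, dot_bracket = dot_bracket,
      noncanonical = noncanonical
    ),
    class = "domain_layout"
  )
}

#' @export
print.domain_layout <- function(x, ...) {
  cat("domain_layout:", nrow(x$domains), "top-level elements\n")
  print(x$domains, row.names = FALSE)
  if (!is.null(x$linker)) cat("5' linker:", x$linker[1L], "-", x$linker[2L], "\n")
  if (length(x$accessory)) cat("accessory:", paste(names(x$accessory), collapse = ", "), "\n")
  invisible(x)
}

domain_interval <- function(layout, domain) {
  d <- layout$domains
  row <- d[d$domain == domain, , drop = FALSE]
  if (!nrow(row)) return(NULL)
  c(row$start[1L], row$end[1L])
}

#' Detect the conserved 5'/3' terminal elements of a group II intron
#'
#' The canonical boundary motif is GUGCGA at the 5' end and a terminal AY
#' dinucleotide (A followed by a pyrimidine) at the 3' end. Some degenerated
#' lineages carry a short linker between the upstream exon and the 5' motif:
#' the motif is therefore searched (allowing one mismatch, reported as
#' `variant`) within the first 15 nt and its offset is the linker length.
#'
#' @param sequence Intron RNA string, length >= 50.
#' @return List with `five_prime_motif` (`"canonical"`, `"variant"` or
#'   `"absent"`), `motif_seq`, `linker_len` (integer, NA when the motif is
#'   absent) and `three_prime_AY` (logical).
#' @export
detect_terminal_elements <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 50L) stop("sequence too short (< 50 nt)", call. = FALSE)
  motif <- "GUGCGA"
  mchars <- seq_chars(motif)
  best <- list(mism = Inf, off = NA_integer_, seq = NA_character_)
  for (off in 0:9) { # motif must lie within the first 15 nt
    win <- substr(sequence, off + 1L, off + 6L)
    mism <- sum(seq_chars(win) != mchars)
    if (mism < best$mism) best <- list(mism = mism, off = off, seq = win)
    if (mism == 0L) break
  }
  if (best$mism > 1L) {
    five <- "absent"
    linker_len <- NA_integer_
    mseq <- NA_character_
  } else {
    five <- if (best$mism == 0L) "canonical" else "variant"
    linker_len <- best$off
    mseq <- best$seq
  }
  last2 <- substr(sequence, nchar(sequence) - 1L, nchar(sequence))
  ay <- iupac_match(last2, "AY")
  list(
    five_prime_motif = five, motif_seq = mseq,
    linker_len = linker_len, three_prime_AY = ay
  )
}

#' Detect the branch-point adenosine in DVI
#'
#' The lariat branch point is a bulged (unpaired) adenosine in the DVI helix
#' close to the intron 3' end. It is called present iff an unpaired A lies
#' within the DVI interval at a distance of 6-10 nt from the 3' terminus
#' (distance 1 = last nucleotide); when several qualify, the one closest to
#' the canonical position (8 nt from the end) is reported.
#'
#' @param layout A `domain_layout`.
#' @param sequence The intron RNA string the layout was computed from.
#' @return List with `status` (`"present"`, `"absent"` or `"not_assessable"`)
#'   and `position` (1-based intron coordinate, NA unless present).
#' @export
detect_branchpoint <- function(layout, sequence) {
  dvi <- domain_interval(layout, "DVI")
  if (is.null(dvi)) {
    return(list(status = "not_assessable", position = NA_integer_))
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  v <- seq_chars(sequence)
  db <- seq_chars(layout$dot_bracket)
  cand <- seq(dvi[1L], dvi[2L])
  dist3 <- n - cand + 1L
  ok <- v[cand] == "A" & db[cand] == "." & dist3 >= 6L & dist3 <= 10L
  if (!any(ok)) {
    return(list(status = "absent", position = NA_integer_))
  }
  hits <- cand[ok]
  pos <- hits[which.min(abs((n - hits + 1L) - 8L))]
  list(status = "present", position = pos)
}
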