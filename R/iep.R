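# Intron-encoded protein (IEP) annotation: ORF finding within DIV, RT/M vs
# LHE typing by motif evidence, and intactness grading.

#' Motif models used for IEP classification
#'
#' The models are shipped as a versioned data file
#' (`extdata/iep_motifs.tsv`). The LHE diagnostic is the LAGLIDADG
#' nonapeptide, required in two copies 80-150 aa apart (up to 3 mismatches
#' each). The RT/M diagnostic is the reverse-transcriptase catalytic motif
#' `[YF]xDD` supported by at least one conserved RT block pentapeptide
#' (up to 1 mismatch). The RT block patterns are the conserved blocks of the
#' synthetic protein model (see the methods vignette); on real proteins a
#' profile-based annotation would replace them.
#'
#' @param file Path to a motif table (tab-separated: name, type, pattern,
#'   max_mismatch, min_copies, spacing_min, spacing_max).
#' @return A data.frame of motif models.
#' @export
iep_motif_models <- function(file = system.file("extdata", "iep_motifs.tsv",
                                                package = "intronscape")) {
  read.delim(file, stringsAsFactors = FALSE)
}

# Parse a simple amino-acid pattern ("[YF].DD", "LAGLIDADG") into a list of
# per-position allowed residue sets; "." = any residue (never a stop).
parse_aa_pattern <- function(pattern) {
  out <- list()
  chars <- seq_chars(pattern)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      set <- character(0)
      while (chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1L
      }
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  out
}

# All matches of a positional pattern in a protein, allowing max_mm mismatched
# positions; '*' (stop) always counts as a mismatch.
scan_aa_pattern <- function(protein, pattern, max_mm = 0L) {
  sets <- parse_aa_pattern(pattern)
  len <- length(sets)
  v <- seq_chars(protein)
  n <- length(v)
  hits <- NULL
  if (n >= len) {
    ok <- matrix(FALSE, nrow = n - len + 1L, ncol = len)
    for (k in seq_len(len)) {
      seg <- v[k:(n - len + k)]
      if (identical(sets[[k]], ".")) {
        ok[, k] <- seg != "*"
      } else {
        ok[, k] <- seg %in% sets[[k]] # '*' never in a residue set
      }
    }
    mism <- len - rowSums(ok)
    idx <- which(mism <= max_mm)
    if (length(idx)) {
      hits <- data.frame(start = idx, end = idx + len - 1L,
                         mismatches = mism[idx], score = len - mism[idx])
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(start = integer(0), end = integer(0),
                       mismatches = integer(0), score = integer(0))
  }
  hits
}

# Translate an RNA string in a given forward frame (1-3) using an NCBI genetic
# code table; stops are '*'. Uses the Biostrings code tables.
translate_frame <- function(rna, frame = 1L, translation_table = 1L) {
  dna <- rna_to_dna(rna)
  n <- nchar(dna)
  start <- frame
  ncod <- (n - start + 1L) %/% 3L
  if (ncod <= 0L) return("")
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  starts <- start + 3L * (seq_len(ncod) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  chars_seq(aa)
}

#' Find open reading frames within domain IV of an intron
#'
#' Enumerates, in each of the three forward frames, the stop-to-stop spans of
#' at least `min_codons` codons. Each span is reported in `span` mode
#' (starting at the first in-frame codon after the DIV 5' boundary or the
#' previous stop) and additionally in `aug` mode from its first AUG when one
#' leaves at least `min_codons` codons.
#'
#' @param div_sequence RNA sequence of DIV.
#' @param translation_table NCBI genetic code table id (default 1; organellar
#'   codes can be substituted).
#' @param min_codons Minimum ORF length in codons (default 100).
#' @return data.frame with columns `frame`, `mode`, `start`, `end`
#'   (nucleotide coordinates within DIV), `aa_start`, `aa_end` (coordinates in
#'   the frame translation), `n_codons`, `protein`; longest first.
#' @export
find_div_orfs <- function(div_sequence, translation_table = 1L, min_codons = 100L) {
  empty <- data.frame(frame = integer(0), mode = character(0), start = integer(0),
                      end = integer(0), aa_start = integer(0), aa_end = integer(0),
                      n_codons = integer(0), protein = character(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (frame in 1:3) {
    aa <- translate_frame(div_sequence, frame, translation_table)
    if (!nchar(aa)) next
    v <- seq_chars(aa)
    isstop <- v == "*"
    r <- rle(!isstop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a0 <- starts[k]; a1 <- ends[k]
      ncod <- a1 - a0 + 1L
      if (ncod < min_codons) next
      prot <- chars_seq(v[a0:a1])
      nt0 <- frame + 3L * (a0 - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frame, mode = "span", start = nt0, end = nt0 + 3L * ncod - 1L,
        aa_start = a0, aa_end = a1, n_codons = ncod, protein = prot,
        stringsAsFactors = FALSE
      )
      m <- regexpr("M", prot, fixed = TRUE)
      if (m > 0L) {
        am <- a0 + as.integer(m) - 1L
        ncod_m <- a1 - am + 1L
        if (ncod_m >= min_codons) {
          ntm <- frame + 3L * (am - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            frame = frame, mode = "aug", start = ntm, end = ntm + 3L * ncod_m - 1L,
            aa_start = am, aa_end = a1, n_codons = ncod_m,
            protein = substr(prot, as.integer(m), nchar(prot)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$n_codons), , drop = FALSE]
}

# Motif evidence for one protein (or frame translation): LHE pair and RT/M
# catalytic+support hits. Returns per-type scores and hit tables.
iep_motif_evidence <- function(protein, models = iep_motif_models()) {
  lhe_model <- models[models$type == "LHE", , drop = FALSE][1L, ]
  lhe_hits <- scan_aa_pattern(protein, lhe_model$pattern, lhe_model$max_mismatch)
  lhe_pair <- NULL
  lhe_score <- 0
  if (nrow(lhe_hits) >= 2L) {
    best <- NULL
    for (i in seq_len(nrow(lhe_hits) - 1L)) {
      for (j in (i + 1L):nrow(lhe_hits)) {
        gap <- lhe_hits$start[j] - lhe_hits$start[i]
        if (gap >= lhe_model$spacing_min && gap <= lhe_model$spacing_max) {
          sc <- lhe_hits$score[i] + lhe_hits$score[j]
          if (is.null(best) || sc > best$score) best <- list(i = i, j = j, score = sc)
        }
      }
    }
    if (!is.null(best)) {
      lhe_pair <- lhe_hits[c(best$i, best$j), , drop = FALSE]
      lhe_score <- best$score
    }
  }

  cat_model <- models[models$type == "RTM", , drop = FALSE][1L, ]
  cat_hits <- scan_aa_pattern(protein, cat_model$pattern, cat_model$max_mismatch)
  sup_models <- models[models$type == "RTM_support", , drop = FALSE]
  sup_hits <- NULL
  for (k in seq_len(nrow(sup_models))) {
    h <- scan_aa_pattern(protein, sup_models$pattern[k], sup_models$max_mismatch[k])
    if (nrow(h)) {
      h$motif <- sup_models$name[k]
      sup_hits <- rbind(sup_hits, h)
    }
  }
  rtm_ok <- nrow(cat_hits) >= 1L && !is.null(sup_hits) && nrow(sup_hits) >= 1L
  rtm_score <- if (rtm_ok) max(cat_hits$score) + max(sup_hits$score) else 0

  list(
    lhe_ok = !is.null(lhe_pair), lhe_score = lhe_score, lhe_hits = lhe_pair,
    rtm_ok = rtm_ok, rtm_score = rtm_score,
    cat_hits = cat_hits, sup_hits = sup_hits,
    any_partial = nrow(cat_hits) >= 1L || (!is.null(sup_hits) && nrow(sup_hits) >= 1L) ||
      nrow(lhe_hits) >= 1L
  )
}

#' Classify an intron-encoded protein as RT/M, LHE or neither
#'
#' LHE requires two LAGLIDADG motif copies (up to 3 mismatches each) spaced
#' 80-150 aa apart. RT/M requires the catalytic `[YF]xDD` motif plus at least
#' one supporting RT block. If both patterns match, the higher-scoring type
#' wins and a conflict flag is raised.
#'
#' @param protein Amino-acid string (length >= 50).
#' @param models Motif models, see [iep_motif_models()].
#' @return List with `type` (`"RTM"`, `"LHE"` or `"none"`), `evidence`
#'   (data.frame of motif, position, score) and `conflict` (logical).
#' @export
classify_iep <- function(protein, models = iep_motif_models()) {
  if (is.na(protein) || nchar(protein) < 50L) {
    return(list(type = "none", evidence = NULL, conflict = FALSE))
  }
  ev <- iep_motif_evidence(toupper(protein), models)
  conflict <- ev$lhe_ok && ev$rtm_ok
  type <- if (ev$lhe_ok && (!ev$rtm_ok || ev$lhe_score >= ev$rtm_score)) {
    "LHE"
  } else if (ev$rtm_ok) {
    "RTM"
  } else {
    "none"
  }
  evidence <- NULL
  if (type == "LHE") {
    evidence <- data.frame(motif = "LAGLIDADG", position = ev$lhe_hits$start,
                           score = ev$lhe_hits$score, stringsAsFactors = FALSE)
  } else if (type == "RTM") {
    evidence <- rbind(
      data.frame(motif = "RT_catalytic", position = ev$cat_hits$start,
                 score = ev$cat_hits$score, stringsAsFactors = FALSE),
      data.frame(motif = ev$sup_hits$motif, position = ev$sup_hits$start,
                 score = ev$sup_hits$score, stringsAsFactors = FALSE)
    )
  }
  list(type = type, evidence = evidence, conflict = conflict)
}

#' Grade IEP intactness against an expected core span
#'
#' An IEP is intact if a single continuous ORF covers the conserved core
#' region without internal stop codons; degenerated if motif evidence exists
#' but no single ORF covers the core; absent when there is neither an ORF of
#' minimum length nor motif evidence.
#'
#' @param orfs ORF table from [find_div_orfs()] (span-mode rows are used).
#' @param expected_core Integer interval `c(start, end)` in frame-translation
#'   amino-acid coordinates, or NULL when no motif anchor exists.
#' @param has_evidence Logical: was any motif evidence observed?
#' @return `"intact"`, `"degenerated"` or `"absent"`.
#' @export
assess_intactness <- function(orfs, expected_core, has_evidence = FALSE) {
  spans <- orfs[orfs$mode == "span", , drop = FALSE]
  if (!nrow(spans) && !has_evidence) return("absent")
  if (!is.null(expected_core) && nrow(spans)) {
    covered <- any(spans$aa_start <= expected_core[1L] & spans$aa_end >= expected_core[2L])
    if (covered) return("intact")
  }
  if (has_evidence) "degenerated" else "absent"
}

#' Annotate the intron-encoded protein of one intron
#'
#' Locates DIV from the layout, enumerates ORFs, collects motif evidence from
#' the full frame translations (so remnants interrupted by premature stops
#' still count as evidence), types the IEP, anchors the expected core region
#' on the motif hits (+/- `core_pad` aa) and grades intactness.
#'
#' @param intron_sequence Intron RNA string.
#' @param layout A `domain_layout`.
#' @param translation_table NCBI genetic code table id (default 1).
#' @param min_codons Minimum ORF length in codons (default 100).
#' @param core_pad Padding around the motif-anchored core (default 20 aa).
#' @param models Motif models.
#' @return An `iep_annotation`: list with `type`, `status`, `orf` (best ORF
#'   row with intron-coordinate `start`/`end`, or NULL), `protein`,
#'   `evidence`, `conflict`, `remnant_candidates` (motif hits present while no
#'   qualifying ORF exists).
#' @export
annotate_iep <- function(intron_sequence, layout, translation_table = 1L,
                         min_codons = 100L, core_pad = 20L,
                         models = iep_motif_models()) {
  div <- domain_interval(layout, "DIV")
  if (is.null(div)) {
    warning("no DIV interval in layout; IEP reported absent")
    return(structure(list(type = "none", status = "absent", orf = NULL,
                          protein = NA_character_, evidence = NULL,
                          conflict = FALSE, remnant_candidates = FALSE),
                     class = "iep_annotation"))
  }
  div_seq <- substr(intron_sequence, div[1L], div[2L])
  orfs <- find_div_orfs(div_seq, translation_table, min_codons)

  # Evidence per frame on the full translation (stops included as '*').
  best <- list(score = -1, frame = NA_integer_, ev = NULL, aa = NULL)
  for (frame in 1:3) {
    aa <- translate_frame(div_seq, frame, translation_table)
    if (nchar(aa) < 10L) next
    ev <- iep_motif_evidence(aa, models)
    sc <- max(ev$lhe_score, ev$rtm_score,
              if (ev$any_partial) 0.5 else 0)
    if (sc > best$score) best <- list(score = sc, frame = frame, ev = ev, aa = aa)
  }
  ev <- best$ev
  type <- "none"
  core <- NULL
  anchors <- NULL
  evidence <- NULL
  conflict <- FALSE
  if (!is.null(ev)) {
    conflict <- ev$lhe_ok && ev$rtm_ok
    if (ev$lhe_ok && (!ev$rtm_ok || ev$lhe_score >= ev$rtm_score)) {
      type <- "LHE"
      anchors <- c(ev$lhe_hits$start, ev$lhe_hits$end)
      evidence <- data.frame(motif = "LAGLIDADG", position = ev$lhe_hits$start,
                             score = ev$lhe_hits$score, stringsAsFactors = FALSE)
    } else if (ev$rtm_ok) {
      type <- "RTM"
      anchors <- c(ev$cat_hits$start, ev$cat_hits$end,
                   ev$sup_hits$start, ev$sup_hits$end)
      evidence <- rbind(
        data.frame(motif = "RT_catalytic", position = ev$cat_hits$start,
                   score = ev$cat_hits$score, stringsAsFactors = FALSE),
        data.frame(motif = ev$sup_hits$motif, position = ev$sup_hits$start,
                   score = ev$sup_hits$score, stringsAsFactors = FALSE)
      )
    }
  }
  if (!is.null(anchors)) {
    core <- c(max(1L, min(anchors) - core_pad),
              min(max(anchors) + core_pad, nchar(best$aa)))
    # the conserved core cannot extend upstream of the reading frame's own
    # boundary: clip the 5' pad at the last stop preceding the first anchor
    stops_pos <- which(seq_chars(best$aa) == "*")
    prev <- stops_pos[stops_pos < min(anchors)]
    if (length(prev)) core[1L] <- max(core[1L], max(prev) + 1L)
  }

  frame_orfs <- orfs[orfs$frame == best$frame, , drop = FALSE]
  status <- assess_intactness(frame_orfs, core, has_evidence = type != "none")
  if (type == "none" && nrow(orfs) == 0L) status <- "absent"

  orf <- NULL
  protein <- NA_character_
  if (nrow(frame_orfs)) {
    orf <- frame_orfs[frame_orfs$mode == "span", , drop = FALSE]
    if (nrow(orf)) {
      orf <- orf[1L, , drop = FALSE]
      orf$start <- orf$start + div[1L] - 1L # intron coordinates
      orf$end <- orf$end + div[1L] - 1L
      protein <- orf$protein
    } else {
      orf <- NULL
    }
  }
  remnant <- type != "none" && status != "intact" ||
    (!is.null(ev) && ev$any_partial && type == "none")
  structure(
    list(type = type, status = status, orf = orf, protein = protein,
         evidence = evidence, conflict = conflict, remnant_candidates = remnant),
    class = "iep_annotation"
  )
}
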