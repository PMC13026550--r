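# EBS-IBS recognition interface: the exon-binding sites are single-stranded
# loops in DI that base-pair (antiparallel) with the intron-binding sites in
# the flanking exons, defining the splice site and the retrohoming target.

# Maximal single-stranded stretches (runs of '.') within [from, to].
ss_stretches <- function(dot_bracket, from, to) {
  db <- seq_chars(dot_bracket)
  idx <- seq(from, to)
  isdot <- db[idx] == "."
  r <- rle(isdot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = idx[starts[keep]], end = idx[ends[keep]])
}

# Antiparallel complementarity score between an EBS window and an IBS, both
# given 5'->3': EBS position i pairs with IBS position (len - i + 1).
ebs_score <- function(ebs, ibs, wobble = FALSE) {
  e <- seq_chars(ebs)
  b <- rev(seq_chars(ibs))
  sum(pairs_with(e, b, wobble = wobble))
}

#' Detect the EBS1/EBS2/EBS3 exon-binding sites of a group II intron
#'
#' IBS1 is the last 6 nt of the upstream exon (positions -6..-1 relative to
#' the 5' splice site), IBS2 the 6 nt upstream of it (-12..-7), and IBS3 the
#' first nucleotide of the downstream exon (+1). Each single-stranded stretch
#' within DI is scanned for the best antiparallel complement of the IBS
#' (Watson-Crick only, or with G.U wobble when `allow_wobble`). EBS1 requires
#' at least 5/6 complementary positions, EBS2 at least 4/6; EBS3 is an exact
#' single-nucleotide complement searched in the 3'-most single-stranded
#' stretch of DI. Below threshold the site is reported `lost`.
#'
#' @param layout A `domain_layout`.
#' @param intron_sequence Intron RNA string.
#' @param upstream_flank Upstream exon flank (>= 12 nt for a full report).
#' @param downstream_flank Downstream exon flank (>= 1 nt).
#' @param allow_wobble Allow G.U pairs when scoring complementarity.
#' @return An `ebs_report`: per site a list with `status` ("found", "lost" or
#'   "not_assessable"), `interval` (intron coordinates), `seq`, `ibs_seq`,
#'   `ibs_positions` (splice-site-relative) and `score`; plus `wobble_used`.
#' @export
detect_ebs_ibs <- function(layout, intron_sequence, upstream_flank,
                           downstream_flank, allow_wobble = FALSE) {
  intron_sequence <- dna_to_rna(intron_sequence)
  upstream_flank <- dna_to_rna(upstream_flank)
  downstream_flank <- dna_to_rna(downstream_flank)
  di <- domain_interval(layout, "DI")
  if (is.null(di)) stop("layout has no DI interval", call. = FALSE)
  stretches <- ss_stretches(layout$dot_bracket, di[1L], di[2L])
  nu <- nchar(upstream_flank)

  wobble_seen <- FALSE
  scan_best <- function(ibs, min_score) {
    len <- nchar(ibs)
    best <- list(score = -1L, start = NA_integer_)
    if (!is.null(stretches) && nrow(stretches)) {
      for (k in seq_len(nrow(stretches))) {
        s <- stretches[k, 1L]; e <- stretches[k, 2L]
        if (e - s + 1L < len) next
        for (st in s:(e - len + 1L)) {
          w <- substr(intron_sequence, st, st + len - 1L)
          sc <- ebs_score(w, ibs, wobble = allow_wobble)
          if (sc > best$score) best <- list(score = sc, start = st)
        }
      }
    }
    if (best$score >= min_score) {
      seq <- substr(intron_sequence, best$start, best$start + len - 1L)
      if (allow_wobble) {
        e <- seq_chars(seq); b <- rev(seq_chars(ibs))
        if (any(pairs_with(e, b, wobble = TRUE) & !pairs_with(e, b, wobble = FALSE))) {
          wobble_seen <<- TRUE
        }
      }
      list(status = "found", interval = c(best$start, best$start + len - 1L),
           seq = seq, score = best$score)
    } else {
      list(status = "lost", interval = NULL, seq = NA_character_, score = best$score)
    }
  }

  # EBS1 vs IBS1 (upstream -6..-1)
  if (nu >= 6L) {
    ibs1 <- substr(upstream_flank, nu - 5L, nu)
    ebs1 <- scan_best(ibs1, 5L)
    ebs1$ibs_seq <- ibs1; ebs1$ibs_positions <- c(-6L, -1L)
  } else {
    ebs1 <- list(status = "not_assessable", interval = NULL, seq = NA_character_,
                 score = NA_integer_, ibs_seq = NA_character_, ibs_positions = NULL)
  }
  # EBS2 vs IBS2 (upstream -12..-7)
  if (nu >= 12L) {
    ibs2 <- substr(upstream_flank, nu - 11L, nu - 6L)
    ebs2 <- scan_best(ibs2, 4L)
    ebs2$ibs_seq <- ibs2; ebs2$ibs_positions <- c(-12L, -7L)
  } else {
    ebs2 <- list(status = "not_assessable", interval = NULL, seq = NA_character_,
                 score = NA_integer_, ibs_seq = NA_character_, ibs_positions = NULL)
  }
  # EBS3 vs IBS3 (+1): exact single-nt complement in the 3'-most stretch of DI.
  if (nchar(downstream_flank) >= 1L) {
    ibs3 <- substr(downstream_flank, 1L, 1L)
    ebs3 <- list(status = "lost", interval = NULL, seq = NA_character_,
                 score = 0L, ibs_seq = ibs3, ibs_positions = c(1L, 1L))
    if (!is.null(stretches) && nrow(stretches)) {
      last <- stretches[nrow(stretches), , drop = FALSE]
      for (p in seq(last[1L, 1L], last[1L, 2L])) {
        b <- substr(intron_sequence, p, p)
        if (pairs_with(b, ibs3, wobble = allow_wobble)) {
          if (allow_wobble && !pairs_with(b, ibs3, wobble = FALSE)) wobble_seen <- TRUE
          ebs3 <- list(status = "found", interval = c(p, p), seq = b, score = 1L,
                       ibs_seq = ibs3, ibs_positions = c(1L, 1L))
          break
        }
      }
    }
  } else {
    ebs3 <- list(status = "not_assessable", interval = NULL, seq = NA_character_,
                 score = NA_integer_, ibs_seq = NA_character_, ibs_positions = NULL)
  }

  structure(
    list(EBS1 = ebs1, EBS2 = ebs2, EBS3 = ebs3, wobble_used = wobble_seen),
    class = "ebs_report"
  )
}

#' Extract the subgroup-diagnostic junction motifs from a domain layout
#'
#' The DII-DIII junction tetramer is taken as the 4 unpaired nucleotides
#' immediately 3' of the DII closing pair; the DIV-DV junction dimer as the 2
#' unpaired nucleotides immediately 5' of the DV helix.
#'
#' @param layout A `domain_layout`.
#' @param sequence Intron RNA string.
#' @return List with `tetramer` (DII-DIII) and `dimer` (DIV-DV); NA when the
#'   flanking domain is missing or the junction is shorter than the motif.
#' @export
extract_junction_motifs <- function(layout, sequence) {
  sequence <- toupper(sequence)
  d2 <- domain_interval(layout, "DII")
  dv <- domain_interval(layout, "DV")
  db <- seq_chars(layout$dot_bracket)
  tetramer <- NA_character_
  if (!is.null(d2) && d2[2L] + 4L <= nchar(sequence)) {
    idx <- (d2[2L] + 1L):(d2[2L] + 4L)
    if (all(db[idx] == ".")) tetramer <- substr(sequence, idx[1L], idx[4L])
  }
  dimer <- NA_character_
  if (!is.null(dv) && dv[1L] - 2L >= 1L) {
    idx <- (dv[1L] - 2L):(dv[1L] - 1L)
    if (all(db[idx] == ".")) dimer <- substr(sequence, idx[1L], idx[2L])
  }
  list(tetramer = tetramer, dimer = dimer)
}

#' Classify a group II intron into a structural subgroup
#'
#' Decision order: (1) the DII-DIII junction tetramer is tested against the
#' IIA diagnostics BVGA (IIA1) and RRGA (IIA2); a match to exactly one decides,
#' a match to both yields `ambiguous-IIA`, resolvable by a caller-supplied
#' `clade_prior`. (2) Otherwise the DIV-DV junction dimer is tested: YW gives
#' IIB1, RG gives IIB2 (disjoint at the first position). (3) Otherwise, an
#' intron with no IEP, total length below `iib_like_max_len` and at least two
#' core features absent (canonical 5' motif, branch-point A, EBS1, EBS2) is
#' called IIB-like, the highly degenerated scaffold class. (4) Else
#' unclassified. Presence of domain Ia is recorded as supporting (not
#' deciding) evidence for IIB2.
#'
#' @param features List of structure features as returned by
#'   [annotate_intron()]: needs `junction_DII_DIII`, `junction_DIV_DV`,
#'   `five_prime_motif`, `branchpoint`, `ebs1`, `ebs2`, `length`.
#' @param layout A `domain_layout` (used for the Ia supporting flag).
#' @param iep Optional `iep_annotation` (type/status) for the IIB-like rule.
#' @param clade_prior Optional `"IIA1"` or `"IIA2"` used to resolve
#'   ambiguous-IIA calls from external (e.g. IEP clade) evidence.
#' @param iib_like_max_len Length ceiling for the IIB-like rule (default 800).
#' @return List with `subgroup` and `evidence` (character).
#' @export
classify_subgroup <- function(features, layout = NULL, iep = NULL,
                              clade_prior = NULL, iib_like_max_len = 800L) {
  tet <- features$junction_DII_DIII
  if (!is.null(tet) && !is.na(tet)) {
    a1 <- iupac_match(tet, "BVGA")
    a2 <- iupac_match(tet, "RRGA")
    if (a1 && a2) {
      if (!is.null(clade_prior) && clade_prior %in% c("IIA1", "IIA2")) {
        return(list(subgroup = clade_prior,
                    evidence = paste0("tetramer ", tet, " ambiguous; resolved by clade prior")))
      }
      return(list(subgroup = "ambiguous-IIA",
                  evidence = paste0("tetramer ", tet, " matches both BVGA and RRGA")))
    }
    if (a1) return(list(subgroup = "IIA1", evidence = paste0("tetramer ", tet, " matches BVGA")))
    if (a2) return(list(subgroup = "IIA2", evidence = paste0("tetramer ", tet, " matches RRGA")))
  }
  dim2 <- features$junction_DIV_DV
  ia_support <- !is.null(layout) && "ia" %in% names(layout$accessory)
  if (!is.null(dim2) && !is.na(dim2)) {
    if (iupac_match(dim2, "YW")) {
      return(list(subgroup = "IIB1", evidence = paste0("dimer ", dim2, " matches YW")))
    }
    if (iupac_match(dim2, "RG")) {
      ev <- paste0("dimer ", dim2, " matches RG",
                   if (ia_support) "; domain Ia present (supporting)" else "")
      return(list(subgroup = "IIB2", evidence = ev))
    }
  }
  no_iep <- is.null(iep) || identical(iep$type, "none") || identical(iep$status, "absent")
  absent_core <- sum(
    !identical(features$five_prime_motif, "canonical"),
    !identical(features$branchpoint, "present"),
    !identical(features$ebs1, "found"),
    !identical(features$ebs2, "found")
  )
  if (no_iep && !is.null(features$length) && features$length < iib_like_max_len &&
      absent_core >= 2L) {
    return(list(subgroup = "IIB-like",
                evidence = paste0("no IEP, length ", features$length, " < ",
                                  iib_like_max_len, ", ", absent_core,
                                  " core features absent")))
  }
  list(subgroup = "unclassified", evidence = "no diagnostic motif matched")
}
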