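# Intron templates are ordered lists of named "parts", each carrying its own
# sequence, dot-bracket, substitution-rate class (normal / conserved / orf)
# and protected positions. Evolution mutates part sequences; structural edits
# (degenerations, insertions, motif overwrites) drop, insert or rewrite parts.
# The assembled template is the emitted sequence + structure + truth record.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

new_part <- function(name, domain, seq, db, rate = "normal", core = FALSE,
                     protect = integer(0), meta = list()) {
  stopifnot(nchar(seq) == nchar(db))
  list(name = name, domain = domain, seq = seq, db = db, rate = rate,
       core = core, protect = protect, meta = meta)
}

# Hairpin part: stem, loop, reverse-complement stem. meta records the loop
# position so diagnostic loops (EBS) can be rewritten later.
hairpin_part <- function(name, domain, stem_len, loop, rate = "normal",
                         core = FALSE) {
  stem <- rand_rna(stem_len)
  loop_seq <- if (is.character(loop)) loop else rand_rna(loop)
  seq <- paste0(stem, loop_seq, revcomp_rna(stem))
  db <- paste0(strrep("(", stem_len), strrep(".", nchar(loop_seq)),
               strrep(")", stem_len))
  new_part(name, domain, seq, db, rate = rate, core = core,
           meta = list(stem_len = stem_len, loop_len = nchar(loop_seq)))
}

set_hairpin_loop <- function(part, loop_seq, protect_loop = FALSE) {
  sl <- part$meta$stem_len
  stopifnot(nchar(loop_seq) == part$meta$loop_len)
  substr(part$seq, sl + 1L, sl + nchar(loop_seq)) <- loop_seq
  if (protect_loop) {
    part$protect <- union(part$protect, seq(sl + 1L, sl + nchar(loop_seq)))
  }
  part
}

ss_part <- function(name, domain, seq, rate = "normal", core = FALSE,
                    protect = integer(0)) {
  new_part(name, domain, seq, strrep(".", nchar(seq)), rate = rate,
           core = core, protect = protect)
}

# Fixed canonical DV (catalytic core, 34 nt: 14 bp stem + 6 nt loop), shared
# across all templates.
DV_STEM <- "GGUACGCAGGAUCC"
DV_LOOP <- "GUAAGC"
dv_part <- function() {
  seq <- paste0(DV_STEM, DV_LOOP, revcomp_rna(DV_STEM))
  db <- paste0(strrep("(", 14L), strrep(".", 6L), strrep(")", 14L))
  new_part("dV", "DV", seq, db, rate = "conserved", core = TRUE,
           meta = list(stem_len = 14L, loop_len = 6L))
}

# DVI: 5-bp outer stem, 3-bp inner stem, 4-nt loop, bulged branch-point A
# between the stems on the 3' side (8 nt from the intron 3' end once the AY
# tail is appended).
dvi_part <- function(branchpoint = TRUE) {
  s1 <- rand_rna(5L)
  s2 <- rand_rna(3L)
  loop <- rand_rna(4L)
  bulge <- if (branchpoint) "A" else "G"
  seq <- paste0(s1, s2, loop, revcomp_rna(s2), bulge, revcomp_rna(s1))
  db <- paste0(strrep("(", 8L), "....", strrep(")", 3L), ".", strrep(")", 5L))
  # the branch point itself is under strong purifying selection
  new_part("dVI", "DVI", seq, db, rate = "conserved", core = TRUE,
           protect = 16L,
           meta = list(bulge_offset = 16L, branchpoint = branchpoint))
}

# Base that pairs with b neither by Watson-Crick nor by G.U wobble.
nonpairing_base <- function(b) {
  partners <- switch(b, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  setdiff(RNA_BASES, c(partners, b))[1L]
}

# Codon table helpers -------------------------------------------------------

rna_code <- function(translation_table = 1L) {
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  names(code) <- dna_to_rna(names(code))
  code
}

codons_for <- function(aa, code) names(code)[code == aa]

encode_protein <- function(aa_vec, code) {
  vapply(aa_vec, function(a) {
    cands <- codons_for(a, code)
    cands[sample.int(length(cands), 1L)]
  }, character(1L))
}

# Build an ORF part for DIV: RT/M (450 codons; RT blocks + [Y]ADD catalytic
# motif) or LHE (200 codons; two LAGLIDADG copies 105 aa apart). Motif codons
# and the stop are protected positions.
make_orf_part <- function(type = c("RTM", "LHE"), translation_table = 1L) {
  type <- match.arg(type)
  code <- rna_code(translation_table)
  if (type == "RTM") {
    n_aa <- 450L
    aa <- sample(AA20, n_aa, replace = TRUE)
    aa[1L] <- "M"
    motifs <- list(c(100L, "GLSQG"), c(300L, "YADD"), c(350L, "PRKHS"))
  } else {
    n_aa <- 200L
    aa <- sample(AA20, n_aa, replace = TRUE)
    aa[1L] <- "M"
    motifs <- list(c(15L, "LAGLIDADG"), c(120L, "LAGLIDADG"))
  }
  protect_aa <- integer(0)
  for (m in motifs) {
    at <- as.integer(m[[1L]])
    res <- seq_chars(m[[2L]])
    aa[at:(at + length(res) - 1L)] <- res
    protect_aa <- c(protect_aa, at:(at + length(res) - 1L))
  }
  codons <- encode_protein(aa, code)
  seq <- paste0(paste(codons, collapse = ""), "UAA")
  protect_nt <- c(unlist(lapply(protect_aa, function(a) (3L * (a - 1L) + 1L):(3L * a))),
                  (nchar(seq) - 2L):nchar(seq))
  ss_part("div_core", "DIV", seq, rate = "orf", protect = protect_nt)
}

# Subgroup-diagnostic junction motifs -----------------------------------------

TET_IIA1 <- c("CAGA", "CCGA", "CGGA", "UAGA", "UCGA", "UGGA", "GCGA")
TET_IIA2 <- c("AAGA", "AGGA")

sample_tetramer <- function(subgroup) {
  if (subgroup == "IIA1") return(sample(TET_IIA1, 1L))
  if (subgroup == "IIA2") return(sample(TET_IIA2, 1L))
  repeat { # anything matching neither BVGA nor RRGA
    t <- rand_rna(4L)
    if (!iupac_match(t, "BVGA") && !iupac_match(t, "RRGA")) return(t)
  }
}

sample_dimer <- function(subgroup) {
  if (subgroup == "IIB1") {
    return(paste0(sample(c("C", "U"), 1L), sample(c("A", "U"), 1L))) # YW
  }
  if (subgroup == "IIB2") {
    return(paste0(sample(c("A", "G"), 1L), "G")) # RG
  }
  repeat { # matches neither YW nor RG
    d <- rand_rna(2L)
    if (!iupac_match(d, "YW") && !iupac_match(d, "RG")) return(d)
  }
}

# Scaffold superset ----------------------------------------------------------

# Canonical scaffold containing every part any family may retain. Families are
# derived from this by dropping/inserting parts and rewriting diagnostic
# content. `extra_scaffold` nt of conserved-core DI hairpins (4-nt loops so
# they never enter EBS scans) carry alignable phylogenetic signal.
build_scaffold_parts <- function(extra_scaffold = 600L) {
  parts <- list()
  add <- function(p) parts[[p$name]] <<- p
  conn <- function(name) ss_part(name, "DI", rand_rna(2L))

  add(new_part("m5", "m5", "GUGCGA", "......", rate = "conserved"))
  di_stem <- rand_rna(6L)
  add(new_part("di_open", "DI", di_stem, "((((((", core = TRUE))
  n_fill <- ceiling(extra_scaffold / 150)
  if (extra_scaffold > 0L) {
    for (k in seq_len(n_fill)) {
      add(hairpin_part(paste0("cf", k), "DI", 73L, 4L, core = TRUE))
    }
  }
  add(hairpin_part("ia", "DI", 4L, 4L))
  add(conn("c1"))
  add(hairpin_part("ic1", "DI", 4L, 4L, core = TRUE))
  add(conn("c2"))
  add(hairpin_part("ic2", "DI", 4L, 4L))
  add(conn("c3"))
  add(hairpin_part("ebs2", "DI", 4L, 6L))
  add(conn("c4"))
  add(hairpin_part("id1", "DI", 4L, 4L, core = TRUE))
  add(conn("c5"))
  add(hairpin_part("id2", "DI", 4L, 4L))
  add(conn("c6"))
  add(hairpin_part("ebs1", "DI", 4L, 6L))
  add(conn("c7"))
  add(ss_part("ebs3r", "DI", rand_rna(3L)))
  add(new_part("di_close", "DI", revcomp_rna(di_stem), "))))))", core = TRUE))
  add(ss_part("j12", "j", rand_rna(2L)))
  add(hairpin_part("dII", "DII", 8L, 6L, core = TRUE))
  add(ss_part("j23", "j", "NNNN", rate = "conserved")) # tetramer, set per family
  add(hairpin_part("dIII", "DIII", 6L, 4L, core = TRUE))
  add(ss_part("j34", "j", rand_rna(2L)))
  div_stem <- rand_rna(8L)
  add(new_part("div_open", "DIV", div_stem, "((((((((", core = TRUE))
  add(ss_part("div_pre", "DIV", rand_rna(3L)))
  add(ss_part("div_core", "DIV", rand_rna(14L))) # replaced when an IEP is present
  add(ss_part("div_post", "DIV", rand_rna(3L)))
  add(new_part("div_close", "DIV", revcomp_rna(div_stem), "))))))))", core = TRUE))
  add(ss_part("j45", "j", "NN", rate = "conserved")) # dimer, set per family
  add(dv_part())
  add(ss_part("j56", "j", rand_rna(2L)))
  add(dvi_part(branchpoint = TRUE))
  add(new_part("tail", "tail", "AU", "..", rate = "conserved"))
  parts
}

PART_ORDER <- c(
  "linker", "m5", "di_open", paste0("cf", 1:40), "ia", "c1", "ic1", "c2",
  "ic2", "c3", "ebs2", "c4", "id1", "c5", "id2", "id2a", "c6", "ie", "c7",
  "ebs1", "c8", "ebs3r", "di_close", "j12", "dII", "j23", "dIII", "j3a",
  "diiia", "j34", "div_open", "div_pre", "div_core", "div_post", "div_close",
  "j45", "dV", "j56", "dVI", "tail"
)

order_parts <- function(parts) {
  parts[intersect(PART_ORDER, names(parts))]
}

assemble_parts <- function(parts) {
  parts <- order_parts(parts)
  seqs <- vapply(parts, `[[`, character(1L), "seq")
  dbs <- vapply(parts, `[[`, character(1L), "db")
  w <- nchar(seqs)
  end <- cumsum(w)
  start <- end - w + 1L
  index <- data.frame(
    name = names(parts),
    domain = vapply(parts, `[[`, character(1L), "domain"),
    start = start, end = end, stringsAsFactors = FALSE, row.names = NULL
  )
  list(sequence = paste(seqs, collapse = ""),
       dot_bracket = paste(dbs, collapse = ""),
       index = index)
}

part_interval <- function(index, name) {
  r <- index[index$name == name, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  c(r$start[1L], r$end[1L])
}

# Apply a family spec to scaffold parts: subgroup-dependent presence of
# domain Ia, degenerations, diagnostic junction motifs, EBS loops matching the
# exon context, and the DIV ORF. `orf_part` is the (possibly evolved) ORF to
# install; insertions (linker, ID2a, IE, DIIIa) are drawn fresh from the
# current RNG stream.
apply_family_spec <- function(parts, spec, ibs_context, orf_part = NULL) {
  deg <- spec$degenerations
  if (spec$subgroup != "IIB2") parts$ia <- NULL # Ia is the IIB2 diagnostic
  if ("lose_IC2" %in% deg) parts$ic2 <- NULL
  if ("lose_ID2" %in% deg) parts$id2 <- NULL
  if ("add_ID2a" %in% deg) parts$id2a <- hairpin_part("id2a", "DI", 4L, 4L)
  if ("add_IE" %in% deg) parts$ie <- hairpin_part("ie", "DI", 4L, 4L)
  if ("add_DIIIa" %in% deg) {
    parts$j3a <- ss_part("j3a", "j", rand_rna(2L))
    parts$diiia <- hairpin_part("diiia", "DIIIa", 5L, 4L)
  }
  if ("linker" %in% deg) {
    repeat { # linker must not pre-empt the 5' motif search
      lk <- rand_rna(sample(2:10, 1L))
      probe <- paste0(lk, "GUGCGA")
      pre_hit <- FALSE
      for (off in 0:(nchar(lk) - 1L)) {
        win <- substr(probe, off + 1L, off + 6L)
        if (sum(seq_chars(win) != seq_chars("GUGCGA")) <= 1L) pre_hit <- TRUE
      }
      if (!pre_hit) break
    }
    parts$linker <- ss_part("linker", "linker", lk)
  }
  if ("no_branchpoint_A" %in% deg) {
    p <- parts$dVI
    substr(p$seq, p$meta$bulge_offset, p$meta$bulge_offset) <- "G"
    p$meta$branchpoint <- FALSE
    parts$dVI <- p
  }

  # Diagnostic junction motifs (conserved within the family).
  parts$j23$seq <- sample_tetramer(spec$subgroup)
  parts$j45$seq <- sample_dimer(spec$subgroup)

  # EBS loops complementary to the exon IBS windows.
  ibs1 <- substr(ibs_context$up12, 7L, 12L)
  ibs2 <- substr(ibs_context$up12, 1L, 6L)
  ibs3 <- substr(ibs_context$down2, 1L, 1L)
  parts$ebs1 <- set_hairpin_loop(parts$ebs1, revcomp_rna(ibs1), protect_loop = TRUE)
  ebs2_loop <- if ("lose_EBS2" %in% deg) {
    # guaranteed non-complementary (even with wobble) to IBS2
    chars_seq(vapply(rev(seq_chars(ibs2)), nonpairing_base, character(1L)))
  } else {
    revcomp_rna(ibs2)
  }
  parts$ebs2 <- set_hairpin_loop(parts$ebs2, ebs2_loop, protect_loop = TRUE)
  pad <- nonpairing_base(ibs3)
  parts$ebs3r$seq <- paste0(comp_rna(ibs3), pad, pad)
  parts$ebs3r$protect <- 1L

  # DIV content.
  if (spec$iep != "none" && !"orf_absent" %in% deg) {
    stopifnot(!is.null(orf_part))
    if ("orf_premature_stop" %in% deg) {
      k <- if (spec$iep == "RTM") 200L else 70L
      at <- 3L * (k - 1L) + 1L
      substr(orf_part$seq, at, at + 2L) <- "UAA"
      orf_part$db <- strrep(".", nchar(orf_part$seq))
      orf_part$protect <- union(orf_part$protect, at:(at + 2L))
    }
    parts$div_core <- orf_part
  }
  parts
}

# Ground truth for an assembled family template.
template_truth <- function(parts, spec, ibs_context) {
  asm <- assemble_parts(parts)
  idx <- asm$index
  dom_iv <- function(d) {
    rows <- idx[idx$domain == d, , drop = FALSE]
    if (!nrow(rows)) return(c(NA_integer_, NA_integer_))
    c(min(rows$start), max(rows$end))
  }
  ebs_iv <- function(name) {
    p <- parts[[name]]
    iv <- part_interval(idx, name)
    if (is.null(iv)) return(NULL)
    if (!is.null(p$meta$stem_len)) {
      c(iv[1L] + p$meta$stem_len, iv[1L] + p$meta$stem_len + p$meta$loop_len - 1L)
    } else iv
  }
  e1 <- ebs_iv("ebs1")
  e2 <- ebs_iv("ebs2")
  e3s <- part_interval(idx, "ebs3r")[1L]
  dvi_iv <- part_interval(idx, "dVI")
  bp <- if (parts$dVI$meta$branchpoint) dvi_iv[1L] + parts$dVI$meta$bulge_offset - 1L else NA_integer_
  deg <- spec$degenerations
  iep_status <- if (spec$iep == "none" || "orf_absent" %in% deg) {
    "absent"
  } else if ("orf_premature_stop" %in% deg) {
    "degenerated"
  } else "intact"
  list(
    family = spec$id, host_gene = spec$host_gene, site = spec$site,
    subgroup = spec$subgroup,
    iep_type = if (iep_status == "absent") "none" else spec$iep,
    iep_planted = spec$iep,
    iep_status = iep_status,
    length = nchar(asm$sequence),
    linker_len = if (!is.null(parts$linker)) nchar(parts$linker$seq) else 0L,
    branchpoint_pos = bp,
    tetramer = parts$j23$seq, dimer = parts$j45$seq,
    domains = list(DI = dom_iv("DI"), DII = dom_iv("DII"), DIII = dom_iv("DIII"),
                   DIIIa = dom_iv("DIIIa"), DIV = dom_iv("DIV"),
                   DV = dom_iv("DV"), DVI = dom_iv("DVI")),
    accessory = list(
      ia = part_interval(idx, "ia"), ic2 = part_interval(idx, "ic2"),
      id2 = part_interval(idx, "id2"), id2a = part_interval(idx, "id2a"),
      ie = part_interval(idx, "ie"), diiia = part_interval(idx, "diiia")
    ),
    ebs1 = list(interval = e1, seq = substr(asm$sequence, e1[1L], e1[2L]),
                present = TRUE), # EBS1 is always planted
    ebs2 = list(interval = e2, seq = substr(asm$sequence, e2[1L], e2[2L]),
                present = !"lose_EBS2" %in% deg),
    ebs3 = list(interval = c(e3s, e3s), seq = substr(asm$sequence, e3s, e3s)),
    ibs = list(ibs1 = substr(ibs_context$up12, 7L, 12L),
               ibs2 = substr(ibs_context$up12, 1L, 6L),
               ibs3 = substr(ibs_context$down2, 1L, 1L)),
    orf_interval = if (iep_status != "absent") part_interval(idx, "div_core") else NULL,
    index = idx
  )
}

#' Build one synthetic group II intron template
#'
#' Constructs the canonical architecture for a family spec: optional 5'
#' linker, the GUGCGA 5' motif, six top-level stem-loop domains (seven with
#' `add_DIIIa`), a fixed 34-nt DV, a DVI with the bulged branch-point A 8 nt
#' from the 3' end (unless degenerated), the AY 3' tail, subgroup-diagnostic
#' junction motifs, EBS loops complementary to the exon IBS windows, and the
#' RT/M or LHE ORF inside DIV.
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed.
#' @param ibs_context Optional list with `up12` (12 nt of upstream exon ending
#'   at the splice site) and `down2` (first 2 nt of the downstream exon); when
#'   NULL a random context is drawn.
#' @param extra_scaffold Extra conserved DI scaffold in nt (default 0 for a
#'   compact standalone template).
#' @param translation_table Genetic code for the ORF (default 1).
#' @return List with `sequence`, `dot_bracket`, `truth` (the ground-truth
#'   record), `parts` and `ibs_context`.
#' @export
build_intron_template <- function(spec, seed = 1L, ibs_context = NULL,
                                  extra_scaffold = 0L, translation_table = 1L) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(seed, {
    if (is.null(ibs_context)) {
      ibs_context <- list(up12 = rand_rna(12L), down2 = rand_rna(2L))
    }
    parts <- build_scaffold_parts(extra_scaffold)
    orf_part <- if (spec$iep != "none") {
      make_orf_part(spec$iep, translation_table)
    } else NULL
    parts <- apply_family_spec(parts, spec, ibs_context, orf_part)
    asm <- assemble_parts(parts)
    list(sequence = asm$sequence, dot_bracket = asm$dot_bracket,
         truth = template_truth(parts, spec, ibs_context),
         parts = parts, ibs_context = ibs_context)
  })
}
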